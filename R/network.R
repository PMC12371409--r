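GLOBAL_SPECIES <- c("RNAP_native", "RNAP_T7", "Ribo", "RNase", "NTP", "AA", "toxin")

# reaction-kind codes shared with the C++ evaluator
RK_BIMOL <- 1L   # k * [i1] * [i2]
RK_UNI   <- 2L   # k * [i1]
RK_ELONG <- 3L   # k * [i1] * max([pool],0)/(K + max([pool],0))
RK_GATE  <- 4L   # k * (1 + tanh([toxin] - threshold)) * [i1]
RK_CONST <- 5L   # k

#' Compile transcription units into a mass-action TXTL reaction network
#'
#' Builds the full species list, stoichiometry (stored as triplets), and
#' rate-law table for a set of transcription units competing for shared
#' polymerase, ribosome, and ribonuclease pools, plus the lumped toxin
#' mechanism. Per unit `i` the default scheme is:
#'
#' * `DNA_i + Pol <-> Ctx_i` (kf_tx / kr_tx)
#' * `Ctx_i -> DNA_i + Pol + mRNA_i` at `(k_tx_elong/L) [Ctx_i] [NTP]/(K_NTP+[NTP])`,
#'   consuming `L` units of NTP
#' * translatable only: `mRNA_i + Ribo <-> Ctl_i` (kf_rbs / kr_rbs) and
#'   `Ctl_i -> mRNA_i + Ribo + P_i` at `(k_tl_elong/l) [Ctl_i] [AA]/(K_AA+[AA])`,
#'   consuming `l` units of AA (this is the translation rate `v_tl,i`)
#' * `mRNA_i + RNase <-> Cdeg_i` (kf_nuc / kr_nuc); `Cdeg_i -> RNase` at `k_deg`
#'   (the transcript is destroyed; only free mRNA binds the nuclease)
#' * `P_i -> F_i` at `k_mat` when the protein matures into a fluorophore
#'
#' The toxin state variable gains +1 per event of every transcription (TX
#' variants) or translation (TL variants) reaction, drains at the constant
#' buffering rate `b`, and once past its threshold degrades the free target
#' pool(s) (ribosomes for `*_TL`, both polymerase classes for `*_TX`) at
#' `k_toxin * (1 + tanh([toxin] - threshold)) * [target]`. The toxin is never
#' clipped at zero and may go negative.
#'
#' @param units List of [transcription_unit()] objects with unique ids.
#' @param resources A [resource_spec()].
#' @param toxin A [toxin_config()].
#' @return An object of class `txtl_network` with elements `species`,
#'   `reactions` (rate-law table), `stoich` (triplet list), `units`,
#'   `resources`, `toxin`, and bookkeeping indices.
#' @export
build_network <- function(units = default_registry(),
                          resources = resource_spec(),
                          toxin = toxin_config()) {
  stopifnot(inherits(resources, "resource_spec"), inherits(toxin, "toxin_config"))
  if (length(units)) {
    ids <- vapply(units, function(u) u$id, character(1))
    if (anyDuplicated(ids)) stop("duplicate unit id: ", ids[duplicated(ids)][1])
    names(units) <- ids
  }

  species <- GLOBAL_SPECIES
  unit_species <- list()
  for (u in units) {
    sp <- c(DNA = paste0("DNA_", u$id), Ctx = paste0("Ctx_", u$id),
            mRNA = paste0("mRNA_", u$id))
    if (u$translatable) sp <- c(sp, Ctl = paste0("Ctl_", u$id))
    sp <- c(sp, Cdeg = paste0("Cdeg_", u$id))
    if (u$translatable) sp <- c(sp, P = paste0("P_", u$id))
    has_mat <- is.character(u$k_mat) || (is.numeric(u$k_mat) && u$k_mat > 0)
    if (u$translatable && has_mat) sp <- c(sp, F = paste0("F_", u$id))
    unit_species[[u$id]] <- sp
    species <- c(species, unname(sp))
  }
  sidx <- stats::setNames(seq_along(species), species)

  # rate-law table accumulated row-wise; stoichiometry as triplets
  rxn <- list()
  trip <- list()
  add_rxn <- function(label, kind, k_ref, k_scale = 1, i1 = NA, i2 = NA,
                      sat_K_ref = NA, stoich = list()) {
    j <- length(rxn) + 1L
    rxn[[j]] <<- list(label = label, kind = kind, k_ref = k_ref,
                      k_scale = k_scale, i1 = i1, i2 = i2,
                      sat_K_ref = sat_K_ref)
    for (sp in names(stoich)) {
      trip[[length(trip) + 1L]] <<- c(r = j, s = sidx[[sp]], v = stoich[[sp]])
    }
    j
  }

  tl_rxns <- integer(0)  # translation-step reaction indices (v_tl)
  tx_rxns <- integer(0)  # transcription-step reaction indices

  for (u in units) {
    sp <- unit_species[[u$id]]
    pol <- if (u$promoter$polymerase_class == "T7") "RNAP_T7" else "RNAP_native"
    L <- u$transcript_length
    add_rxn(paste0("tx_bind_", u$id), RK_BIMOL, u$promoter$kf_tx,
            i1 = sidx[[sp[["DNA"]]]], i2 = sidx[[pol]],
            stoich = stats::setNames(list(-1, -1, +1),
                                     c(sp[["DNA"]], pol, sp[["Ctx"]])))
    add_rxn(paste0("tx_unbind_", u$id), RK_UNI, u$promoter$kr_tx,
            i1 = sidx[[sp[["Ctx"]]]],
            stoich = stats::setNames(list(+1, +1, -1),
                                     c(sp[["DNA"]], pol, sp[["Ctx"]])))
    j <- add_rxn(paste0("tx_elong_", u$id), RK_ELONG, "k_tx_elong",
                 k_scale = 1 / L, i1 = sidx[[sp[["Ctx"]]]], i2 = sidx[["NTP"]],
                 sat_K_ref = "K_NTP",
                 stoich = stats::setNames(list(-1, +1, +1, +1, -L),
                                          c(sp[["Ctx"]], sp[["DNA"]], pol,
                                            sp[["mRNA"]], "NTP")))
    tx_rxns <- c(tx_rxns, j)
    if (u$translatable) {
      l <- u$protein_length
      add_rxn(paste0("tl_bind_", u$id), RK_BIMOL, u$kf_rbs,
              i1 = sidx[[sp[["mRNA"]]]], i2 = sidx[["Ribo"]],
              stoich = stats::setNames(list(-1, -1, +1),
                                       c(sp[["mRNA"]], "Ribo", sp[["Ctl"]])))
      add_rxn(paste0("tl_unbind_", u$id), RK_UNI, u$kr_rbs,
              i1 = sidx[[sp[["Ctl"]]]],
              stoich = stats::setNames(list(+1, +1, -1),
                                       c(sp[["mRNA"]], "Ribo", sp[["Ctl"]])))
      j <- add_rxn(paste0("tl_elong_", u$id), RK_ELONG, "k_tl_elong",
                   k_scale = 1 / l, i1 = sidx[[sp[["Ctl"]]]], i2 = sidx[["AA"]],
                   sat_K_ref = "K_AA",
                   stoich = stats::setNames(list(-1, +1, +1, +1, -l),
                                            c(sp[["Ctl"]], sp[["mRNA"]], "Ribo",
                                              sp[["P"]], "AA")))
      tl_rxns <- c(tl_rxns, j)
    }
    add_rxn(paste0("nuc_bind_", u$id), RK_BIMOL, u$kf_nuc,
            i1 = sidx[[sp[["mRNA"]]]], i2 = sidx[["RNase"]],
            stoich = stats::setNames(list(-1, -1, +1),
                                     c(sp[["mRNA"]], "RNase", sp[["Cdeg"]])))
    add_rxn(paste0("nuc_unbind_", u$id), RK_UNI, u$kr_nuc,
            i1 = sidx[[sp[["Cdeg"]]]],
            stoich = stats::setNames(list(+1, +1, -1),
                                     c(sp[["mRNA"]], "RNase", sp[["Cdeg"]])))
    add_rxn(paste0("deg_", u$id), RK_UNI, u$k_deg,
            i1 = sidx[[sp[["Cdeg"]]]],
            stoich = stats::setNames(list(+1, -1), c("RNase", sp[["Cdeg"]])))
    if ("F" %in% names(sp)) {
      add_rxn(paste0("mat_", u$id), RK_UNI, u$k_mat,
              i1 = sidx[[sp[["P"]]]],
              stoich = stats::setNames(list(-1, +1), c(sp[["P"]], sp[["F"]])))
    }
  }

  # toxin coupling: +1 toxin per source event, constant drain, gated targets
  src <- switch(toxin$variant,
                TL_TL = tl_rxns, TL_TX = tl_rxns,
                TX_TX = tx_rxns, TX_TL = tx_rxns,
                off = integer(0))
  for (j in src) trip[[length(trip) + 1L]] <- c(r = j, s = sidx[["toxin"]], v = 1)
  add_rxn("toxin_drain", RK_CONST, toxin$b,
          stoich = list(toxin = -1))
  if (toxin$variant != "off" && length(units)) {
    targets <- switch(toxin$variant,
                      TL_TL = "Ribo", TX_TL = "Ribo",
                      TX_TX = c("RNAP_native", "RNAP_T7"),
                      TL_TX = c("RNAP_native", "RNAP_T7"))
    for (tg in targets) {
      add_rxn(paste0("toxin_deg_", tg), RK_GATE, toxin$k_toxin,
              i1 = sidx[[tg]],
              stoich = stats::setNames(list(-1), tg))
    }
  }

  tripm <- do.call(rbind, trip)
  structure(list(
    species = species,
    species_index = sidx,
    reactions = rxn,
    stoich = tripm,
    units = units,
    unit_species = unit_species,
    resources = resources,
    toxin = toxin,
    tl_rxns = tl_rxns,
    tx_rxns = tx_rxns
  ), class = "txtl_network")
}

#' @export
print.txtl_network <- function(x, ...) {
  cat("TXTL reaction network:", length(x$units), "transcription units,",
      length(x$species), "species,", length(x$reactions), "reactions;",
      "toxin variant", x$toxin$variant, "\n")
  invisible(x)
}

# resolve a rate reference (number or parameter name) against a parameter set
resolve_ref <- function(ref, params, what = "parameter") {
  if (is.numeric(ref)) return(ref)
  if (!ref %in% names(params)) stop("missing ", what, " '", ref, "'")
  unname(params[[ref]])
}

# flatten the network + parameter set into the numeric arrays the RHS
# evaluators consume; cached per (network, params) by simulate()
compile_network <- function(network, params) {
  rxn <- network$reactions
  n <- length(rxn)
  kind <- integer(n); k <- numeric(n); i1 <- integer(n); i2 <- integer(n)
  satK <- numeric(n)
  for (j in seq_len(n)) {
    r <- rxn[[j]]
    kind[j] <- r$kind
    k[j] <- resolve_ref(r$k_ref, params) * r$k_scale
    i1[j] <- if (is.na(r$i1)) 0L else r$i1
    i2[j] <- if (is.na(r$i2)) 0L else r$i2
    satK[j] <- if (is.na(r$sat_K_ref) || !is.character(r$sat_K_ref)) 0
               else resolve_ref(r$sat_K_ref, params)
  }
  thr <- if (network$toxin$variant == "off") 0
         else resolve_ref(network$toxin$toxin_threshold, params)
  list(kind = kind, k = k, i1 = i1, i2 = i2, satK = satK,
       tox_idx = network$species_index[["toxin"]], thr = thr,
       trip_r = as.integer(network$stoich[, "r"]),
       trip_s = as.integer(network$stoich[, "s"]),
       trip_v = as.numeric(network$stoich[, "v"]),
       n_species = length(network$species))
}

# reference R implementation of the compiled rate laws
compiled_rates_r <- function(comp, state) {
  n <- length(comp$kind)
  rate <- numeric(n)
  tox <- state[comp$tox_idx]
  for (j in seq_len(n)) {
    rate[j] <- switch(comp$kind[j],
      comp$k[j] * state[comp$i1[j]] * state[comp$i2[j]],
      comp$k[j] * state[comp$i1[j]],
      { p <- max(state[comp$i2[j]], 0)
        comp$k[j] * state[comp$i1[j]] * p / (comp$satK[j] + p) },
      comp$k[j] * (1 + tanh(tox - comp$thr)) * state[comp$i1[j]],
      comp$k[j])
  }
  rate
}

#' Evaluate the network right-hand side
#'
#' Computes species time-derivatives as the stoichiometry matrix times the
#' rate-law vector, including the toxin coupling (source events minus the
#' buffering drain; no clipping of the toxin at zero). This is the reference
#' R implementation; [simulate_network()] uses an equivalent compiled
#' evaluator.
#'
#' @param network A `txtl_network`.
#' @param state Named or unnamed numeric vector of species concentrations in
#'   network species order. Entries may be negative (the toxin in particular);
#'   they must be finite.
#' @param params Parameter set resolving every named rate in the network.
#' @return Named numeric vector of time-derivatives (nM/s).
#' @export
evaluate_rhs <- function(network, state, params) {
  if (length(state) != length(network$species))
    stop("state length ", length(state), " != species count ",
         length(network$species))
  if (any(!is.finite(state))) stop("non-finite state entries")
  comp <- compile_network(network, params)
  rate <- compiled_rates_r(comp, state)
  dy <- numeric(comp$n_species)
  for (t in seq_along(comp$trip_r)) {
    dy[comp$trip_s[t]] <- dy[comp$trip_s[t]] + comp$trip_v[t] * rate[comp$trip_r[t]]
  }
  stats::setNames(dy, network$species)
}

#' Toxin gate multiplier
#'
#' The smooth near-step factor `1 + tanh(toxin - threshold)` scaling
#' toxin-driven resource degradation: ~0 far below threshold, exactly 1 at
#' threshold, ~2 far above. Continuously differentiable, strictly increasing,
#' bounded in (0, 2).
#'
#' @param toxin_level Toxin concentration (nM); may be negative.
#' @param config A [toxin_config()] (variant must not be `"off"`); its
#'   threshold must be numeric (pass a resolved value or use `threshold`).
#' @param params Optional parameter set used to resolve a named threshold.
#' @return Dimensionless multiplier in (0, 2).
#' @export
toxin_gate <- function(toxin_level, config, params = NULL) {
  stopifnot(inherits(config, "toxin_config"))
  if (config$variant == "off") stop("toxin_gate undefined for variant 'off'")
  thr <- if (is.numeric(config$toxin_threshold)) config$toxin_threshold
         else resolve_ref(config$toxin_threshold, params, "toxin threshold")
  1 + tanh(toxin_level - thr)
}

#' Resource conservation totals
#'
#' Sums the free pool plus every complex containing each machinery resource:
#' polymerases are additionally bound in transcription complexes, ribosomes
#' in translation complexes, nucleases in degradation complexes. With the
#' toxin coefficient at zero each total is a conserved quantity of the
#' dynamics, which is the basis of the conservation test suite and of
#' resource-utilization accounting.
#'
#' @param network A `txtl_network`.
#' @param state Species concentration vector in network order.
#' @return Named numeric vector with totals for `RNAP_native`, `RNAP_T7`,
#'   `Ribo`, `RNase`.
#' @export
conservation_totals <- function(network, state) {
  state <- stats::setNames(as.numeric(state), network$species)
  tot <- c(RNAP_native = state[["RNAP_native"]],
           RNAP_T7 = state[["RNAP_T7"]],
           Ribo = state[["Ribo"]], RNase = state[["RNase"]])
  for (u in network$units) {
    sp <- network$unit_species[[u$id]]
    pol <- if (u$promoter$polymerase_class == "T7") "RNAP_T7" else "RNAP_native"
    tot[[pol]] <- tot[[pol]] + state[[sp[["Ctx"]]]]
    if (u$translatable) tot[["Ribo"]] <- tot[["Ribo"]] + state[[sp[["Ctl"]]]]
    tot[["RNase"]] <- tot[["RNase"]] + state[[sp[["Cdeg"]]]]
  }
  tot
}
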