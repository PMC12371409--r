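#' Bolus dose schedule
#'
#' Plasmid (DNA) and mRNA amounts added at reaction start. DNA doses set the
#' initial free-template concentration of the named unit; mRNA doses set its
#' initial free-transcript concentration, which is how translation-only
#' experiments (purified mRNA added to the lysate, no DNA) are represented.
#'
#' @param dna Named numeric vector, unit id -> DNA concentration (nM).
#' @param rna Named numeric vector, unit id -> mRNA concentration (nM).
#' @return Object of class `dose_schedule`.
#' @export
dose_schedule <- function(dna = numeric(0), rna = numeric(0)) {
  chk <- function(x, what) {
    if (length(x) && (is.null(names(x)) || any(!nzchar(names(x)))))
      stop(what, " doses must be named by unit id")
    if (any(x < 0)) stop(what, " doses must be >= 0")
    x
  }
  structure(list(dna = chk(dna, "DNA"), rna = chk(rna, "RNA")),
            class = "dose_schedule")
}

# assemble the t = 0 state: resources from params (fall back to the network's
# resource_spec), doses into free DNA / free mRNA, everything else zero
initial_state <- function(network, params, doses) {
  res <- network$resources
  getp <- function(nm) if (nm %in% names(params)) unname(params[[nm]]) else res[[nm]]
  y <- stats::setNames(numeric(length(network$species)), network$species)
  y["RNAP_native"] <- getp("RNAP0_native")
  y["RNAP_T7"] <- getp("RNAP0_T7")
  y["Ribo"] <- getp("Ribo0")
  y["RNase"] <- getp("RNase0")
  y["NTP"] <- getp("NTP0")
  y["AA"] <- getp("AA0")
  for (nm in names(doses$dna)) {
    if (!nm %in% names(network$units)) stop("unknown unit id in doses: ", nm)
    y[paste0("DNA_", nm)] <- y[paste0("DNA_", nm)] + doses$dna[[nm]]
  }
  for (nm in names(doses$rna)) {
    if (!nm %in% names(network$units)) stop("unknown unit id in doses: ", nm)
    y[paste0("mRNA_", nm)] <- y[paste0("mRNA_", nm)] + doses$rna[[nm]]
  }
  y
}

#' Simulate a dosed TXTL reaction
#'
#' Integrates the compiled network from the bolus-dosed initial state with a
#' stiff-capable solver (`deSolve::lsoda`) and reports concentrations on a
#' uniform grid. Default reporting mirrors the plate reader: every 5 min over
#' 3 h (37 points including t = 0); resource-utilization analyses may extend
#' `t_end` to 6 h.
#'
#' @param network A `txtl_network` from [build_network()].
#' @param params Named parameter set (see [default_parameters()]).
#' @param doses A [dose_schedule()].
#' @param t_end End time (s). Default 3 h.
#' @param t_step Reporting interval (s). Default 300 (5 min).
#' @param rtol,atol Integrator tolerances (relative / absolute, nM).
#' @param y0 Optional named vector of initial-state overrides (species name
#'   -> concentration) applied after dosing; useful for isolating
#'   subsystems.
#' @return Object of class `txtl_timecourse`: `times` (s), `trajectories`
#'   (species x time matrix), and `readouts` (named list of derived series:
#'   one per unit with a declared readout, plus `toxin`, `total_mRNA`, and
#'   per-resource bound fractions).
#' @export
simulate_network <- function(network, params, doses = dose_schedule(),
                             t_end = 10800, t_step = 300,
                             rtol = 1e-6, atol = 1e-12, y0 = NULL) {
  stopifnot(t_end > 0, t_step > 0, rtol > 0, atol > 0)
  comp <- compile_network(network, params)
  state0 <- initial_state(network, params, doses)
  if (!is.null(y0)) {
    unknown <- setdiff(names(y0), network$species)
    if (length(unknown)) stop("unknown species in y0: ",
                              paste(unknown, collapse = ", "))
    state0[names(y0)] <- y0
  }
  times <- seq(0, t_end, by = t_step)
  if (times[length(times)] < t_end) times <- c(times, t_end)
  func <- function(t, y, p) {
    list(rhs_core(y, comp$kind, comp$k, comp$i1, comp$i2, comp$satK,
                  comp$tox_idx, comp$thr, comp$n_species,
                  comp$trip_r, comp$trip_s, comp$trip_v))
  }
  out <- deSolve::lsoda(y = unname(state0), times = times, func = func,
                        parms = NULL, rtol = rtol, atol = atol, maxsteps = 50000)
  diagn <- attributes(out)$istate
  if (!is.null(diagn) && diagn[1] < 0)
    stop("integration failed (lsoda istate ", diagn[1], ")")
  traj <- t(out[, -1, drop = FALSE])
  rownames(traj) <- network$species
  tc <- structure(list(times = out[, 1], trajectories = traj,
                       network_species = network$species),
                  class = "txtl_timecourse")
  tc$readouts <- build_readouts(network, tc)
  tc
}

# derived series: declared unit readouts, toxin, total mRNA, bound fractions
build_readouts <- function(network, tc) {
  traj <- tc$trajectories
  rd <- list()
  total_mrna <- numeric(ncol(traj))
  for (u in network$units) {
    sp <- network$unit_species[[u$id]]
    m <- traj[sp[["mRNA"]], ] + traj[sp[["Cdeg"]], ]
    if (u$translatable) m <- m + traj[sp[["Ctl"]], ]
    total_mrna <- total_mrna + m
    if (u$readout == "mature_protein") rd[[u$id]] <- traj[sp[["F"]], ]
    if (u$readout == "free_rna") rd[[u$id]] <- traj[sp[["mRNA"]], ]
  }
  rd$toxin <- traj["toxin", ]
  rd$total_mRNA <- total_mrna
  tot0 <- conservation_totals(network, traj[, 1])
  for (res in c("RNAP_native", "RNAP_T7", "Ribo", "RNase")) {
    if (tot0[[res]] > 0) {
      bound <- vapply(seq_len(ncol(traj)), function(i) {
        conservation_totals(network, traj[, i])[[res]] - traj[res, i]
      }, numeric(1))
      rd[[paste0("bound_frac_", res)]] <- bound / tot0[[res]]
    }
  }
  rd
}

#' @export
print.txtl_timecourse <- function(x, ...) {
  cat("TXTL time course:", length(x$times), "timepoints over",
      round(max(x$times) / 3600, 2), "h;", nrow(x$trajectories), "species;",
      "readouts:", paste(names(x$readouts), collapse = ", "), "\n")
  invisible(x)
}

#' Interpolate a readout at an arbitrary time
#'
#' Linear interpolation between report points; times exactly on the grid
#' return the stored value.
#'
#' @param tc A `txtl_timecourse`.
#' @param readout Readout name (a key of `tc$readouts`) or a species name.
#' @param t Time (s) within the simulated range.
#' @return Concentration (nM).
#' @export
readout_at <- function(tc, readout, t) {
  if (readout %in% names(tc$readouts)) {
    y <- tc$readouts[[readout]]
  } else if (readout %in% rownames(tc$trajectories)) {
    y <- tc$trajectories[readout, ]
  } else stop("unknown readout '", readout, "'")
  if (t < min(tc$times) || t > max(tc$times)) stop("time out of range")
  stats::approx(tc$times, y, xout = t)$y
}

#' Export a time course as tidy CSV
#'
#' Long format with columns `condition_id`, `species_or_readout`, `time_s`,
#' `value_nM`; full-precision values so that write/read round trips are
#' lossless.
#'
#' @param tc A `txtl_timecourse`.
#' @param path Output path.
#' @param condition_id Identifier written into the `condition_id` column.
#' @param species Character vector of species/readouts to export; defaults to
#'   all readouts.
#' @return `path`, invisibly.
#' @export
write_timecourse_csv <- function(tc, path, condition_id = "condition",
                                 species = names(tc$readouts)) {
  rows <- lapply(species, function(nm) {
    y <- if (nm %in% names(tc$readouts)) tc$readouts[[nm]] else tc$trajectories[nm, ]
    data.frame(condition_id = condition_id, species_or_readout = nm,
               time_s = tc$times, value_nM = y)
  })
  df <- do.call(rbind, rows)
  utils::write.csv(format(df, digits = 17, scientific = FALSE, trim = TRUE),
                   path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a tidy time-course CSV
#'
#' @param path CSV written by [write_timecourse_csv()] (or any table with the
#'   same columns).
#' @return data.frame with columns `condition_id`, `species_or_readout`,
#'   `time_s`, `value_nM`.
#' @export
read_timecourse_csv <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("condition_id", "species_or_readout", "time_s", "value_nM")
  if (!all(need %in% names(df))) stop("missing columns: ",
                                      paste(setdiff(need, names(df)), collapse = ", "))
  df$time_s <- as.numeric(df$time_s)
  df$value_nM <- as.numeric(df$value_nM)
  df
}
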