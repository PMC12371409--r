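#' Promoter specification
#'
#' Describes a promoter class: which RNA polymerase pool it recruits and the
#' association/dissociation rates of that polymerase. Rate fields may be given
#' either as numbers (baked into the network) or as character parameter names
#' resolved from a [ParameterSet][default_parameters] at evaluation time; the
#' latter is what enables parameter screening without rebuilding the network.
#'
#' @param name Promoter name, one of `"T7_strong"`, `"T7_weak"`,
#'   `"sig70_strong"`, `"sig70_weak"`, `"kanR_native"`.
#' @param polymerase_class `"T7"` or `"native"`, selecting the polymerase pool.
#' @param kf_tx Association rate of DNA and polymerase (1/(nM s)), numeric or
#'   parameter name.
#' @param kr_tx Dissociation rate (1/s), numeric or parameter name.
#' @return An object of class `promoter_spec`.
#' @export
promoter_spec <- function(name, polymerase_class = c("T7", "native"),
                          kf_tx, kr_tx) {
  polymerase_class <- match.arg(polymerase_class)
  stopifnot(is.character(name), length(name) == 1L)
  check_rate_ref(kf_tx, "kf_tx", strict_positive = TRUE)
  check_rate_ref(kr_tx, "kr_tx")
  structure(list(name = name, polymerase_class = polymerase_class,
                 kf_tx = kf_tx, kr_tx = kr_tx),
            class = "promoter_spec")
}

# a rate reference is either a finite non-negative number or a parameter name
check_rate_ref <- function(x, what, strict_positive = FALSE) {
  if (is.character(x)) {
    if (length(x) != 1L || !nzchar(x)) stop(what, " parameter name must be a single non-empty string")
    return(invisible(TRUE))
  }
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x)) {
    stop(what, " must be a finite number or a parameter name")
  }
  if (strict_positive && x <= 0) stop(what, " must be > 0")
  if (!strict_positive && x < 0) stop(what, " must be >= 0")
  invisible(TRUE)
}

#' Transcription unit specification
#'
#' One transcribable construct: a promoter plus transcript/protein lengths,
#' ribosome- and nuclease-binding kinetics, and the readout it reports.
#' Untranslated constructs (RNA aptamers, empty vectors) set
#' `translatable = FALSE` and `protein_length = 0`.
#'
#' @param id Unique unit identifier.
#' @param promoter A [promoter_spec()].
#' @param transcript_length Transcript length in nucleotides (> 0).
#' @param translatable Logical; does the transcript carry an RBS and ORF?
#' @param protein_length Protein length in amino acids (0 if untranslated).
#' @param kf_rbs,kr_rbs Ribosome binding/unbinding rates (ignored if
#'   untranslated).
#' @param kf_nuc,kr_nuc Ribonuclease binding/unbinding rates.
#' @param k_deg Catalytic degradation rate of the nuclease-bound transcript
#'   (1/s).
#' @param k_mat Fluorophore maturation rate (1/s); 0 or omitted if the protein
#'   does not mature into a fluorescent readout.
#' @param readout One of `"mature_protein"`, `"free_rna"`, `"none"`.
#' @return An object of class `tu_spec`.
#' @export
transcription_unit <- function(id, promoter, transcript_length,
                               translatable = FALSE, protein_length = 0,
                               kf_rbs = 0, kr_rbs = 0,
                               kf_nuc, kr_nuc, k_deg,
                               k_mat = 0,
                               readout = c("none", "mature_protein", "free_rna")) {
  readout <- match.arg(readout)
  stopifnot(inherits(promoter, "promoter_spec"))
  if (!is.numeric(transcript_length) || transcript_length <= 0)
    stop("transcript_length must be > 0")
  if (translatable && (!is.numeric(protein_length) || protein_length <= 0))
    stop("translatable unit '", id, "' must have protein_length > 0")
  if (!translatable && is.numeric(protein_length) && protein_length != 0)
    stop("untranslated unit '", id, "' must have protein_length 0")
  if (translatable) {
    check_rate_ref(kf_rbs, "kf_rbs")
    check_rate_ref(kr_rbs, "kr_rbs")
  }
  check_rate_ref(kf_nuc, "kf_nuc")
  check_rate_ref(kr_nuc, "kr_nuc")
  check_rate_ref(k_deg, "k_deg")
  check_rate_ref(k_mat, "k_mat")
  if (readout == "mature_protein" && !translatable)
    stop("mature_protein readout requires a translatable unit")
  structure(list(id = id, promoter = promoter,
                 transcript_length = transcript_length,
                 translatable = isTRUE(translatable),
                 protein_length = protein_length,
                 kf_rbs = kf_rbs, kr_rbs = kr_rbs,
                 kf_nuc = kf_nuc, kr_nuc = kr_nuc, k_deg = k_deg,
                 k_mat = k_mat, readout = readout),
            class = "tu_spec")
}

#' Resource pool specification
#'
#' Initial concentrations of the shared TXTL machinery and lumped substrate
#' pools, and the half-saturation constants of the elongation rate laws.
#' All concentrations in nM (substrate pools in nM-nucleotide / nM-residue).
#' Values given here are defaults; a [ParameterSet][default_parameters]
#' containing the canonical names (`RNAP0_native`, `RNAP0_T7`, `Ribo0`,
#' `RNase0`, `NTP0`, `AA0`, `K_NTP`, `K_AA`) overrides them at simulation
#' time so resource initials can be screened like any kinetic constant.
#'
#' @param RNAP0_native,RNAP0_T7 Initial native / T7 RNA polymerase (nM).
#' @param Ribo0 Initial ribosome concentration (nM).
#' @param RNase0 Initial ribonuclease concentration (nM).
#' @param NTP0,AA0 Lumped NTP / amino-acid pools (nM units consumed per
#'   nucleotide or residue polymerized).
#' @param K_NTP,K_AA Half-saturation constants of the elongation rates (nM).
#' @return An object of class `resource_spec`.
#' @export
resource_spec <- function(RNAP0_native = 30, RNAP0_T7 = 100, Ribo0 = 1000,
                          RNase0 = 10, NTP0 = 3e6, AA0 = 4e7,
                          K_NTP = 1e5, K_AA = 1e5) {
  vals <- c(RNAP0_native = RNAP0_native, RNAP0_T7 = RNAP0_T7, Ribo0 = Ribo0,
            RNase0 = RNase0, NTP0 = NTP0, AA0 = AA0, K_NTP = K_NTP, K_AA = K_AA)
  if (any(!is.finite(vals)) || any(vals < 0)) stop("resource values must be finite and >= 0")
  structure(as.list(vals), class = "resource_spec")
}

#' Toxin mechanism configuration
#'
#' The lumped toxin state variable accumulates at the summed transcription or
#' translation flux minus a constant buffering rate `b`; past
#' `toxin_threshold` it degrades a resource pool through a smooth tanh gate
#' (see [toxin_gate()]). The four variants differ in which flux generates the
#' toxin (TX or TL) and which machinery it degrades (RNA polymerases or
#' ribosomes): `TL_TL` (translation generates, ribosomes degraded; the
#' default mechanism), `TX_TX`, `TL_TX`, `TX_TL`, or `off`.
#'
#' @param variant Mechanism variant.
#' @param b Buffering rate (nM/s), numeric or parameter name (default name
#'   `"b"`).
#' @param k_toxin Toxin coefficient (1/s), numeric or parameter name.
#' @param toxin_threshold Threshold toxin concentration (nM), numeric or
#'   parameter name.
#' @return An object of class `toxin_config`.
#' @export
toxin_config <- function(variant = c("TL_TL", "TX_TX", "TL_TX", "TX_TL", "off"),
                         b = "b", k_toxin = "k_toxin",
                         toxin_threshold = "toxin_threshold") {
  if (is.character(variant) && length(variant) == 1L &&
      !variant %in% c("TL_TL", "TX_TX", "TL_TX", "TX_TL", "off"))
    stop("unknown toxin variant '", variant, "'")
  variant <- match.arg(variant)
  check_rate_ref(b, "b")
  check_rate_ref(k_toxin, "k_toxin")
  if (is.numeric(toxin_threshold)) {
    stopifnot(is.finite(toxin_threshold))
  } else check_rate_ref(toxin_threshold, "toxin_threshold")
  structure(list(variant = variant, b = b, k_toxin = k_toxin,
                 toxin_threshold = toxin_threshold),
            class = "toxin_config")
}

#' Default promoter registry
#'
#' The five promoter classes of the crosstalk experiment design: strong and weak T7
#' promoters (T7 RNA polymerase), strong and weak sigma-70 promoters (native
#' polymerase), and the native promoter driving the kanamycin-resistance
#' marker present on every plasmid. Binding rates reference screened
#' parameters `kf_tx_<promoter>` / `kr_tx_<promoter>`.
#'
#' @return Named list of [promoter_spec()] objects.
#' @export
default_promoters <- function() {
  mk <- function(name, cls) promoter_spec(name, cls,
                                          kf_tx = paste0("kf_tx_", name),
                                          kr_tx = paste0("kr_tx_", name))
  list(
    T7_strong    = mk("T7_strong", "T7"),
    T7_weak      = mk("T7_weak", "T7"),
    sig70_strong = mk("sig70_strong", "native"),
    sig70_weak   = mk("sig70_weak", "native"),
    kanR_native  = mk("kanR_native", "native")
  )
}

# construct-class kinetics shared by all units carrying the same transcript
construct_rates <- function(class, translatable) {
  r <- list(kf_nuc = paste0("kf_nuc_", class),
            kr_nuc = paste0("kr_nuc_", class),
            k_deg  = paste0("k_deg_", class),
            kf_rbs = 0, kr_rbs = 0, k_mat = 0)
  if (translatable) {
    r$kf_rbs <- paste0("kf_rbs_", class)
    r$kr_rbs <- paste0("kr_rbs_", class)
  }
  r
}

#' Default transcription-unit registry
#'
#' The ten transcribable constructs of the crosstalk experiments: the sfGFP
#' reporter under four promoters, the 3WJdB RNA aptamer reporter under three
#' (the sigma-70 weak aptamer signal is indistinguishable from noise and is
#' excluded), promoter-bearing empty vectors under the two strong promoters,
#' and a single pooled kanamycin-resistance (kanR) unit representing the
#' marker carried by every plasmid. Aptamer and empty-vector transcripts are
#' untranslated.
#'
#' Transcript/protein lengths are fixed structural constants: sfGFP 918 nt /
#' 240 aa, kanR 816 nt / 271 aa, 3WJdB aptamer 200 nt, empty-vector cryptic
#' transcript 100 nt (shorter than any gene-bearing transcript, which is what
#' gives it the fastest catalytic degradation under the filter heuristics).
#'
#' @return Named list of [transcription_unit()] objects (length 10).
#' @export
default_registry <- function() {
  p <- default_promoters()
  units <- list()
  for (pn in c("T7_strong", "T7_weak", "sig70_strong", "sig70_weak")) {
    cr <- construct_rates("sfGFP", TRUE)
    units[[paste0("sfGFP_", pn)]] <- transcription_unit(
      id = paste0("sfGFP_", pn), promoter = p[[pn]],
      transcript_length = 918, translatable = TRUE, protein_length = 240,
      kf_rbs = cr$kf_rbs, kr_rbs = cr$kr_rbs,
      kf_nuc = cr$kf_nuc, kr_nuc = cr$kr_nuc, k_deg = cr$k_deg,
      k_mat = "k_mat_sfGFP", readout = "mature_protein")
  }
  for (pn in c("T7_strong", "T7_weak", "sig70_strong")) {
    cr <- construct_rates("aptamer", FALSE)
    units[[paste0("aptamer_", pn)]] <- transcription_unit(
      id = paste0("aptamer_", pn), promoter = p[[pn]],
      transcript_length = 200, translatable = FALSE,
      kf_nuc = cr$kf_nuc, kr_nuc = cr$kr_nuc, k_deg = cr$k_deg,
      readout = "free_rna")
  }
  for (pn in c("T7_strong", "sig70_strong")) {
    cr <- construct_rates("empty", FALSE)
    units[[paste0("empty_", pn)]] <- transcription_unit(
      id = paste0("empty_", pn), promoter = p[[pn]],
      transcript_length = 100, translatable = FALSE,
      kf_nuc = cr$kf_nuc, kr_nuc = cr$kr_nuc, k_deg = cr$k_deg,
      readout = "none")
  }
  cr <- construct_rates("kanR", TRUE)
  units$kanR <- transcription_unit(
    id = "kanR", promoter = p$kanR_native,
    transcript_length = 816, translatable = TRUE, protein_length = 271,
    kf_rbs = cr$kf_rbs, kr_rbs = cr$kr_rbs,
    kf_nuc = cr$kf_nuc, kr_nuc = cr$kr_nuc, k_deg = cr$k_deg,
    readout = "none")
  units
}
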