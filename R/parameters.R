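#' Default (fixture) parameter set
#'
#' A named vector of all kinetic constants and initial resource
#' concentrations of the default 10-unit network, at the parameterization
#' shipped with the package. This parameterization was selected during
#' development to reproduce the qualitative crosstalk phenotypes the model
#' exists to capture: a decrease in terminal sfGFP at 30 nM template for the
#' strong promoters with the sigma-70 weak promoter remaining monotone, and
#' the positive-to-negative crosstalk transition with increasing reporter
#' concentration under an added 10 nM empty vector. It satisfies the
#' biological filter heuristics (see [heuristic_filter()]).
#'
#' Units: concentrations nM, time s; binding rates 1/(nM s), first-order
#' rates 1/s, elongation rates nt/s and aa/s, `b` nM/s.
#'
#' @return Named numeric vector (a ParameterSet).
#' @export
default_parameters <- function() {
  c(
    # promoter-polymerase binding (Kd = kr/kf, nM)
    kf_tx_T7_strong = 1e-2,  kr_tx_T7_strong = 1e-1,   # Kd 10
    kf_tx_T7_weak = 1e-2,    kr_tx_T7_weak = 1,        # Kd 100
    kf_tx_sig70_strong = 1e-2, kr_tx_sig70_strong = 3e-1, # Kd 30
    kf_tx_sig70_weak = 1e-2, kr_tx_sig70_weak = 10,    # Kd 1000
    kf_tx_kanR_native = 1e-2, kr_tx_kanR_native = 2,   # Kd 200
    # ribosome binding
    kf_rbs_sfGFP = 1e-2, kr_rbs_sfGFP = 10,
    kf_rbs_kanR = 1e-2,  kr_rbs_kanR = 2,
    # nuclease binding: reporters weaker (stabilizing UTR hairpins) than
    # kanR / empty vector
    kf_nuc_sfGFP = 1e-2,   kr_nuc_sfGFP = 1,
    kf_nuc_aptamer = 1e-2, kr_nuc_aptamer = 1,
    kf_nuc_kanR = 1e-2,    kr_nuc_kanR = 1e-2,
    kf_nuc_empty = 1e-2,   kr_nuc_empty = 2e-2,
    # catalytic degradation: empty vector fastest (shortest transcript)
    k_deg_sfGFP = 5e-2, k_deg_aptamer = 5e-2, k_deg_kanR = 5e-2,
    k_deg_empty = 2e-1,
    # elongation / maturation
    k_tx_elong = 50, k_tl_elong = 4, k_mat_sfGFP = 2e-3,
    K_NTP = 1e5, K_AA = 1e5,
    # resource initials (ribonuclease deliberately scarce: it is the
    # contested resource behind positive crosstalk)
    RNAP0_native = 30, RNAP0_T7 = 100, Ribo0 = 1000, RNase0 = 10,
    NTP0 = 3e6, AA0 = 4e7,
    # toxin mechanism
    b = 2, k_toxin = 1e-1, toxin_threshold = 2000
  )
}

#' Default parameter bounds for sampling
#'
#' Log-space bounds spanning four orders of magnitude (1e-2 to 1e+2 times the
#' nominal) around each default parameter value, as the screening and
#' fitting default. Fully overridable.
#'
#' @param params Nominal values (default [default_parameters()]).
#' @param span Multiplicative half-width (default 100, i.e. 4 orders total).
#' @param sample Names of the parameters to sample; the rest are held fixed
#'   at their nominal values. Defaults to every parameter.
#' @return Object of class `parameter_bounds`: list with named vectors
#'   `lower`, `upper` and `fixed`.
#' @export
default_bounds <- function(params = default_parameters(), span = 100,
                           sample = names(params)) {
  stopifnot(span > 1, all(sample %in% names(params)))
  sampled <- params[sample]
  if (any(sampled <= 0)) stop("sampled parameters must be > 0 for log-space bounds")
  structure(list(lower = sampled / span, upper = sampled * span,
                 fixed = params[setdiff(names(params), sample)]),
            class = "parameter_bounds")
}

#' Construct parameter bounds
#'
#' @param lower,upper Named positive vectors with identical names,
#'   `0 < lower <= upper`.
#' @param fixed Named vector of parameters held fixed.
#' @return `parameter_bounds` object.
#' @export
parameter_bounds <- function(lower, upper, fixed = numeric(0)) {
  stopifnot(identical(names(lower), names(upper)))
  if (any(lower <= 0) || any(lower > upper))
    stop("bounds must satisfy 0 < lower <= upper")
  structure(list(lower = lower, upper = upper, fixed = fixed),
            class = "parameter_bounds")
}
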