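REPORTER_CONCS <- c(0.5, 1, 2.5, 5, 10, 15, 30)
COMBOS <- c("reporter_only", "empty_no_promoter", "empty_T7_strong",
            "empty_sig70_strong")

#' Enumerate the crosstalk experiment grid
#'
#' Full cross-product of reporter promoter, reporter plasmid concentration
#' ({0.5, 1, 2.5, 5, 10, 15, 30} nM), and added-plasmid combination:
#' reporter only, promoterless empty vector, empty vector with a T7-strong
#' promoter, empty vector with a sigma-70-strong promoter. The sfGFP
#' reporter runs on four promoters (112 conditions); the 3WJdB aptamer on
#' three, the sigma-70-weak aptamer being indistinguishable from noise
#' (84 conditions). Ordering is deterministic: promoter, then concentration,
#' then combination.
#'
#' @param reporter `"sfGFP"` or `"aptamer3WJdB"`.
#' @param promoters Optional subset of promoter names.
#' @param concs Optional subset of reporter concentrations (nM).
#' @param combos Optional subset of plasmid combinations.
#' @param empty_conc Added empty-vector concentration (nM), default 10.
#' @return data.frame of conditions with columns `condition_id`, `reporter`,
#'   `promoter`, `reporter_conc`, `combo`, `empty_conc`.
#' @export
enumerate_conditions <- function(reporter = c("sfGFP", "aptamer3WJdB"),
                                 promoters = NULL, concs = REPORTER_CONCS,
                                 combos = COMBOS, empty_conc = 10) {
  reporter <- match.arg(reporter)
  default_proms <- if (reporter == "sfGFP") {
    c("T7_strong", "T7_weak", "sig70_strong", "sig70_weak")
  } else {
    c("T7_strong", "T7_weak", "sig70_strong")
  }
  if (is.null(promoters)) promoters <- default_proms
  if (reporter == "aptamer3WJdB" && "sig70_weak" %in% promoters)
    stop("the sigma-70 weak aptamer signal is below noise; not a valid condition")
  stopifnot(all(combos %in% COMBOS), all(concs %in% REPORTER_CONCS) || all(concs > 0))
  grid <- expand.grid(combo = combos, reporter_conc = concs,
                      promoter = promoters, stringsAsFactors = FALSE,
                      KEEP.OUT.ATTRS = FALSE)
  grid <- grid[, c("promoter", "reporter_conc", "combo")]
  grid$reporter <- reporter
  grid$empty_conc <- empty_conc
  grid$condition_id <- sprintf("%s.%s.%gnM.%s", grid$reporter, grid$promoter,
                               grid$reporter_conc, grid$combo)
  rownames(grid) <- NULL
  grid[, c("condition_id", "reporter", "promoter", "reporter_conc", "combo",
           "empty_conc")]
}

# unit id of the reporter construct for a condition row
reporter_unit_id <- function(condition) {
  prefix <- if (condition$reporter == "sfGFP") "sfGFP_" else "aptamer_"
  paste0(prefix, condition$promoter)
}

#' Compose per-unit bolus doses for a condition
#'
#' The reporter unit is dosed at the reporter concentration; promoter-bearing
#' empty vectors are dosed at `empty_conc` for their combinations. Every
#' physical plasmid carries the kanR marker, so the pooled kanR unit is dosed
#' at the sum of all plasmid concentrations present — including the
#' promoterless empty vector, which contributes only its kanR copy.
#'
#' @param condition One row of [enumerate_conditions()] (data.frame or list).
#' @return A [dose_schedule()].
#' @export
compose_doses <- function(condition) {
  condition <- as.list(condition)
  stopifnot(condition$combo %in% COMBOS)
  dna <- stats::setNames(condition$reporter_conc, reporter_unit_id(condition))
  kan <- condition$reporter_conc
  if (condition$combo != "reporter_only") {
    kan <- kan + condition$empty_conc
    if (condition$combo %in% c("empty_T7_strong", "empty_sig70_strong")) {
      dna[[condition$combo]] <- condition$empty_conc
    }
  }
  dna[["kanR"]] <- kan
  dose_schedule(dna = dna)
}

#' Crosstalk ratio between two time courses
#'
#' Reporter readout at time `t` (default the 3-h endpoint, matching the
#' experimental definition) with the added plasmid divided by the readout
#' without it. Ratios above one indicate positive crosstalk, below one
#' negative crosstalk. A non-positive baseline readout makes the ratio
#' undefined (`NA`), excluded from downstream surrogate terms.
#'
#' @param tc_with,tc_without `txtl_timecourse` objects sharing `readout`.
#' @param readout Readout name.
#' @param t Comparison time (s), default 10800 (3 h).
#' @return Dimensionless ratio, or `NA` if the baseline is not positive.
#' @export
crosstalk_ratio <- function(tc_with, tc_without, readout, t = 10800) {
  base <- readout_at(tc_without, readout, t)
  if (!is.finite(base) || base <= 0) {
    warning("baseline readout not positive; crosstalk ratio undefined")
    return(NA_real_)
  }
  readout_at(tc_with, readout, t) / base
}

#' Simulate a condition grid
#'
#' Runs one simulation per condition and derives terminal readouts, the
#' crosstalk-ratio table (each added-plasmid combination against the
#' same-concentration reporter-only baseline), and per-condition residual
#' mRNA summaries. Deterministic given parameters and tolerances.
#'
#' @param network A `txtl_network` containing the units the conditions dose.
#' @param params Parameter set.
#' @param conditions data.frame from [enumerate_conditions()].
#' @param t_end,t_step,rtol,atol Passed to [simulate_network()].
#' @param t_ratio Time (s) at which crosstalk ratios are taken (default 3 h).
#' @param keep_timecourses Keep full `txtl_timecourse` objects (memory-heavy
#'   for large grids); summaries are always kept.
#' @return Object of class `txtl_grid`: `conditions` (with appended
#'   `terminal` readout column), `crosstalk` (data.frame `promoter`,
#'   `reporter_conc_nM`, `combo`, `ratio`), `mrna` (per condition: terminal
#'   and peak total mRNA), and optionally `timecourses` (named by
#'   condition id).
#' @export
run_grid <- function(network, params, conditions,
                     t_end = 10800, t_step = 300, rtol = 1e-6, atol = 1e-12,
                     t_ratio = 10800, keep_timecourses = FALSE) {
  n <- nrow(conditions)
  terminal <- numeric(n)
  mrna_end <- numeric(n)
  mrna_peak <- numeric(n)
  failed <- character(0)
  tcs <- if (keep_timecourses) vector("list", n) else NULL
  for (i in seq_len(n)) {
    cond <- conditions[i, ]
    tc <- tryCatch(
      simulate_network(network, params, compose_doses(cond),
                       t_end = t_end, t_step = t_step, rtol = rtol, atol = atol),
      error = function(e) e)
    if (inherits(tc, "error")) {
      failed <- c(failed, cond$condition_id)
      terminal[i] <- NA; mrna_end[i] <- NA; mrna_peak[i] <- NA
      next
    }
    terminal[i] <- readout_at(tc, reporter_unit_id(cond), min(t_ratio, t_end))
    mrna_end[i] <- tc$readouts$total_mRNA[length(tc$times)]
    mrna_peak[i] <- max(tc$readouts$total_mRNA)
    if (keep_timecourses) tcs[[i]] <- tc
  }
  if (length(failed))
    warning("simulation failed for conditions: ", paste(failed, collapse = ", "))
  conditions$terminal <- terminal
  if (keep_timecourses) names(tcs) <- conditions$condition_id
  res <- structure(list(conditions = conditions,
                        crosstalk = crosstalk_table(conditions),
                        mrna = data.frame(condition_id = conditions$condition_id,
                                          mrna_end = mrna_end,
                                          mrna_peak = mrna_peak),
                        failed = failed,
                        timecourses = tcs),
                   class = "txtl_grid")
  res
}

#' Crosstalk-ratio table from grid terminal readouts
#'
#' Each (promoter, concentration, added-combo) cell is the terminal readout
#' divided by the same-concentration reporter-only baseline.
#'
#' @param conditions data.frame with columns `promoter`, `reporter_conc`,
#'   `combo`, `terminal` (as produced inside [run_grid()]).
#' @return data.frame `promoter`, `reporter_conc_nM`, `combo`, `ratio`.
#' @export
crosstalk_table <- function(conditions) {
  added <- conditions[conditions$combo != "reporter_only", , drop = FALSE]
  if (!nrow(added))
    return(data.frame(promoter = character(0), reporter_conc_nM = numeric(0),
                      combo = character(0), ratio = numeric(0)))
  base <- conditions[conditions$combo == "reporter_only", , drop = FALSE]
  key <- function(df) paste(df$promoter, df$reporter_conc)
  b <- stats::setNames(base$terminal, key(base))
  denom <- b[key(added)]
  ratio <- ifelse(is.na(denom) | denom <= 0, NA_real_, added$terminal / denom)
  data.frame(promoter = added$promoter, reporter_conc_nM = added$reporter_conc,
             combo = added$combo, ratio = as.numeric(ratio),
             row.names = NULL)
}

#' @export
print.txtl_grid <- function(x, ...) {
  cat("TXTL grid:", nrow(x$conditions), "conditions,",
      nrow(x$crosstalk), "crosstalk ratios",
      if (length(x$failed)) paste0(" (", length(x$failed), " failed)"), "\n")
  invisible(x)
}

#' Write a crosstalk table as CSV
#' @param ct data.frame from [crosstalk_table()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_crosstalk_csv <- function(ct, path) {
  utils::write.csv(format(ct, digits = 17, scientific = FALSE, trim = TRUE),
                   path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
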