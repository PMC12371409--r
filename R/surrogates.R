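STRONG_PROMOTERS <- c("T7_strong", "T7_weak", "sig70_strong")
LOW_CONCS <- c(0.5, 1, 2.5)
HIGH_CONCS <- c(5, 10, 15, 30)
LOG_FLOOR <- 1e-12  # nM; |difference| floor before taking log10

#' Default surrogate goal thresholds
#'
#' Baseline penalties must reach -1e-4 and crosstalk terms -0.05 — strictly
#' below the theoretical zero threshold, so that the trends are more than
#' trivially present. Goals for the deviation and residual-mRNA terms have no
#' natural constant and default to `NA`: screening fills them with the
#' population median, which de facto discards the worse half of sampled
#' parameter sets.
#'
#' @return Named numeric vector of goals (criterion satisfied iff
#'   term <= goal).
#' @export
default_goals <- function() {
  c(baseline = -1e-4, crosstalk = -0.05, large_positive = -0.05,
    deviation = NA_real_, residual_mrna = NA_real_)
}

#' Baseline penalty surrogate term
#'
#' Signed log-magnitude of the difference between the terminal reporter
#' readout at 30 nM template and the best readout among the six lower
#' concentrations. For strong promoters the desired phenotype is a decrease
#' at 30 nM, so the sign indicator is +1 if 30 nM gives the maximum readout
#' and -1 otherwise; for the sigma-70 weak promoter the desired phenotype is
#' monotone increase, so the signs flip. More negative is better. The
#' absolute difference is floored at 1e-12 nM before the log so the term is
#' always finite.
#'
#' @param terminal_readouts Named numeric vector, names the seven reporter
#'   concentrations (nM) as numbers, values terminal readouts (nM).
#' @param promoter Promoter name (decides the sign convention).
#' @return Signed penalty (log10 scale).
#' @export
baseline_penalty <- function(terminal_readouts, promoter) {
  concs <- as.numeric(names(terminal_readouts))
  if (anyNA(concs)) stop("terminal_readouts must be named by concentration")
  missing <- setdiff(REPORTER_CONCS, concs)
  if (length(missing))
    stop("missing concentrations: ", paste(missing, collapse = ", "))
  r30 <- terminal_readouts[[which(concs == 30)]]
  best_lower <- max(terminal_readouts[concs < 30])
  thirty_is_max <- r30 >= best_lower
  s <- if (promoter == "sig70_weak") {
    if (thirty_is_max) -1 else +1
  } else {
    if (thirty_is_max) +1 else -1
  }
  s * log10(max(abs(r30 - best_lower), LOG_FLOOR))
}

#' Positive crosstalk surrogate term
#'
#' One (no crosstalk) minus the maximum crosstalk ratio among the 0.5, 1,
#' and 2.5 nM reporter concentrations across all added-plasmid combinations;
#' negative when positive crosstalk is present at low template loads.
#'
#' @param ratios Crosstalk table slice (data.frame with `reporter_conc_nM`
#'   and `ratio`) for one promoter.
#' @return Term value, or `NA` if every relevant ratio is undefined.
#' @export
positive_crosstalk_term <- function(ratios) {
  r <- ratios$ratio[ratios$reporter_conc_nM %in% LOW_CONCS]
  r <- r[is.finite(r)]
  if (!length(r)) { warning("all low-concentration ratios undefined"); return(NA_real_) }
  1 - max(r)
}

#' Negative crosstalk surrogate term
#'
#' The minimum crosstalk ratio among the 5, 10, 15, and 30 nM reporter
#' concentrations minus one; negative when negative crosstalk is present at
#' high template loads.
#'
#' @inheritParams positive_crosstalk_term
#' @return Term value, or `NA` if every relevant ratio is undefined.
#' @export
negative_crosstalk_term <- function(ratios) {
  r <- ratios$ratio[ratios$reporter_conc_nM %in% HIGH_CONCS]
  r <- r[is.finite(r)]
  if (!length(r)) { warning("all high-concentration ratios undefined"); return(NA_real_) }
  min(r) - 1
}

#' Auxiliary surrogate terms
#'
#' Three additional terms with package-default definitions (these trends
#' admit several formalizations; the defaults below are documented design
#' choices):
#'
#' * `large_positive_term`: max positive-regime ratio of the strong promoters
#'   minus that of the sigma-70 weak promoter — negative when the weak
#'   promoter shows the larger positive crosstalk, the experimentally
#'   observed direction.
#' * `deviation_term`: mean absolute difference between simulated and
#'   reference crosstalk ratios over all defined cells (`NA` without a
#'   reference table).
#' * `residual_mrna_term`: log10 of mean(terminal total mRNA / peak total
#'   mRNA) over reporter-only conditions, floored at -12 — maximally negative
#'   when transcripts peak and then decay to zero.
#'
#' @param grid A `txtl_grid` from [run_grid()].
#' @param reference_ratios Optional reference crosstalk table with the same
#'   columns as `grid$crosstalk`.
#' @return Named list with the three terms.
#' @export
auxiliary_terms <- function(grid, reference_ratios = NULL) {
  ct <- grid$crosstalk
  maxpos <- function(promoters) {
    r <- ct$ratio[ct$promoter %in% promoters & ct$reporter_conc_nM %in% LOW_CONCS]
    r <- r[is.finite(r)]
    if (!length(r)) NA_real_ else max(r)
  }
  large_positive <- maxpos(STRONG_PROMOTERS) - maxpos("sig70_weak")

  deviation <- NA_real_
  if (!is.null(reference_ratios)) {
    key <- function(df) paste(df$promoter, df$reporter_conc_nM, df$combo)
    ref <- stats::setNames(reference_ratios$ratio, key(reference_ratios))
    d <- abs(ct$ratio - ref[key(ct)])
    d <- d[is.finite(d)]
    if (!length(d)) stop("no overlapping defined cells with reference table")
    deviation <- mean(d)
  }

  base <- grid$conditions$combo == "reporter_only"
  ids <- grid$conditions$condition_id[base]
  m <- grid$mrna[match(ids, grid$mrna$condition_id), ]
  frac <- m$mrna_end / pmax(m$mrna_peak, LOG_FLOOR)
  frac <- frac[is.finite(frac)]
  residual <- if (length(frac)) log10(max(mean(frac), LOG_FLOOR)) else NA_real_

  list(large_positive_term = large_positive, deviation_term = deviation,
       residual_mrna_term = residual)
}

#' Surrogate report for a simulated grid
#'
#' Computes every surrogate term (baseline penalty per promoter, positive
#' and negative crosstalk terms per promoter, and the three auxiliary terms)
#' and evaluates the nine-criteria registry against goal thresholds.
#'
#' @param grid A `txtl_grid` over the full sfGFP condition grid.
#' @param goals Named goals as in [default_goals()].
#' @param reference_ratios Optional reference crosstalk table for the
#'   deviation term.
#' @return Object of class `surrogate_report`: `terms` (named numeric),
#'   `criteria` (named logical), `n_satisfied`, `key_trend_complete`.
#' @export
surrogate_report <- function(grid, goals = default_goals(),
                             reference_ratios = NULL) {
  conds <- grid$conditions
  proms <- unique(conds$promoter)
  terms <- c()
  for (pr in proms) {
    sel <- conds$combo == "reporter_only" & conds$promoter == pr
    ro <- stats::setNames(conds$terminal[sel], conds$reporter_conc[sel])
    terms[[paste0("baseline_", pr)]] <- baseline_penalty(ro, pr)
    slice <- grid$crosstalk[grid$crosstalk$promoter == pr, , drop = FALSE]
    terms[[paste0("pos_", pr)]] <- suppressWarnings(positive_crosstalk_term(slice))
    terms[[paste0("neg_", pr)]] <- suppressWarnings(negative_crosstalk_term(slice))
  }
  aux <- auxiliary_terms(grid, reference_ratios)
  terms <- c(unlist(terms), unlist(aux))
  evaluate_criteria(terms, goals)
}

#' Evaluate the nine-criteria registry
#'
#' Criterion satisfied iff its term is at or below the goal (inclusive).
#' Default grouping: worst-case baseline over the three strong promoters;
#' sigma-70 weak baseline; one criterion per promoter requiring both its
#' positive and negative crosstalk terms to meet the crosstalk goal; the
#' large-positive, deviation, and residual-mRNA terms. A term or goal of
#' `NA` leaves that criterion unsatisfied.
#'
#' @param terms Named numeric vector of surrogate terms (as produced by
#'   [surrogate_report()]).
#' @param goals Named goals as in [default_goals()].
#' @return Object of class `surrogate_report`.
#' @export
evaluate_criteria <- function(terms, goals = default_goals()) {
  need <- c("baseline", "crosstalk", "large_positive", "deviation",
            "residual_mrna")
  if (!all(need %in% names(goals)))
    stop("missing goals: ", paste(setdiff(need, names(goals)), collapse = ", "))
  met <- function(val, goal) isTRUE(is.finite(val) && is.finite(goal) && val <= goal)
  tv <- function(nm) if (nm %in% names(terms)) terms[[nm]] else NA_real_
  strong_terms <- vapply(paste0("baseline_", STRONG_PROMOTERS), tv, numeric(1))
  criteria <- c()
  criteria[["baseline_strong"]] <-
    met(suppressWarnings(max(strong_terms)), goals[["baseline"]])
  criteria[["baseline_sig70_weak"]] <-
    met(tv("baseline_sig70_weak"), goals[["baseline"]])
  for (pr in c(STRONG_PROMOTERS, "sig70_weak")) {
    criteria[[paste0("crosstalk_", pr)]] <-
      met(tv(paste0("pos_", pr)), goals[["crosstalk"]]) &&
      met(tv(paste0("neg_", pr)), goals[["crosstalk"]])
  }
  criteria[["large_positive"]] <-
    met(tv("large_positive_term"), goals[["large_positive"]])
  criteria[["deviation"]] <- met(tv("deviation_term"), goals[["deviation"]])
  criteria[["residual_mrna"]] <-
    met(tv("residual_mrna_term"), goals[["residual_mrna"]])
  key <- c("baseline_strong", "baseline_sig70_weak",
           paste0("crosstalk_", c(STRONG_PROMOTERS, "sig70_weak")))
  structure(list(terms = terms, criteria = criteria, goals = goals,
                 n_satisfied = sum(unlist(criteria)),
                 key_trend_complete = all(unlist(criteria[key]))),
            class = "surrogate_report")
}

#' @export
print.surrogate_report <- function(x, ...) {
  cat("Surrogate report:", x$n_satisfied, "of", length(x$criteria),
      "criteria satisfied;",
      if (x$key_trend_complete) "key trends complete" else "key trends incomplete",
      "\n")
  for (nm in names(x$criteria)) {
    cat(sprintf("  %-22s %s\n", nm, if (isTRUE(x$criteria[[nm]])) "yes" else "no"))
  }
  invisible(x)
}

#' Serialize a surrogate report as JSON
#'
#' @param report A `surrogate_report`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_surrogate_json <- function(report, path) {
  stopifnot(inherits(report, "surrogate_report"))
  jsonlite::write_json(
    list(terms = as.list(report$terms), criteria = report$criteria,
         goals = as.list(report$goals), n_satisfied = report$n_satisfied,
         key_trend_complete = report$key_trend_complete),
    path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

#' Scale surrogate terms across a population onto [-15, 15]
#'
#' Per-term affine map of the population range onto the interval \[-15, 15\]
#' (order preserving), matching the scaling used when the summed terms serve
#' as a soft-constraint objective. A term constant across the population
#' maps to 0 with a warning.
#'
#' @param term_matrix Numeric matrix, one row per parameterization, one
#'   column per term (>= 2 rows).
#' @return Matrix of the same shape with each column mapped onto [-15, 15].
#' @export
scale_terms <- function(term_matrix) {
  term_matrix <- as.matrix(term_matrix)
  if (nrow(term_matrix) < 2) stop("need a population of >= 2 parameterizations")
  apply(term_matrix, 2, function(col) {
    rng <- range(col, finite = TRUE)
    if (!all(is.finite(rng)) || diff(rng) == 0) {
      warning("constant term across population; scaled to 0")
      return(rep(0, length(col)))
    }
    -15 + 30 * (col - rng[1]) / diff(rng)
  })
}
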