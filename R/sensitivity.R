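#' Partial rank correlation coefficients
#'
#' Global sensitivity of surrogate terms to parameters: every column is
#' rank-transformed (average ranks for ties), then for each (parameter,
#' term) pair the correlation of the residuals of both rank vectors after
#' linear regression on the ranks of all other parameters. Invariant under
#' strictly monotone transforms of any input; reduces to plain Spearman
#' correlation with a single parameter. Rows with missing values (e.g.
#' failed simulations) are dropped listwise with a message.
#'
#' @param X Numeric matrix of parameter samples (rows = samples, named
#'   columns = parameters).
#' @param Y Numeric matrix of term values for the same samples.
#' @return Object of class `sensitivity_matrix`: terms x parameters matrix
#'   of PRCC values in \[-1, 1\], with attribute `n` (samples used).
#'   Constant columns give `NA` with a warning.
#' @export
prcc <- function(X, Y) {
  X <- as.matrix(X); Y <- as.matrix(Y)
  if (is.null(colnames(X))) colnames(X) <- paste0("x", seq_len(ncol(X)))
  if (is.null(colnames(Y))) colnames(Y) <- paste0("y", seq_len(ncol(Y)))
  keep <- stats::complete.cases(X) & stats::complete.cases(Y)
  if (!all(keep)) message("dropping ", sum(!keep), " incomplete rows")
  X <- X[keep, , drop = FALSE]; Y <- Y[keep, , drop = FALSE]
  n <- nrow(X); p <- ncol(X)
  if (n < p + 3) stop("need at least ", p + 3, " complete samples for ", p,
                      " parameters")
  const_x <- apply(X, 2, function(c) diff(range(c)) == 0)
  const_y <- apply(Y, 2, function(c) diff(range(c)) == 0)
  if (any(const_x) || any(const_y))
    warning("constant columns give undefined PRCC: ",
            paste(c(colnames(X)[const_x], colnames(Y)[const_y]), collapse = ", "))
  RX <- apply(X, 2, rank)
  RY <- apply(Y, 2, rank)
  out <- matrix(NA_real_, ncol(Y), p, dimnames = list(colnames(Y), colnames(X)))
  for (j in seq_len(p)) {
    if (const_x[j]) next
    covars <- setdiff(which(!const_x), j)  # constant covariates carry no rank information
    Z <- cbind(1, RX[, covars, drop = FALSE])
    qz <- qr(Z)
    if (qz$rank < ncol(Z)) stop("rank-deficient regression on covariate ranks")
    rx <- stats::setNames(qr.resid(qz, RX[, j]), NULL)
    for (k in seq_len(ncol(Y))) {
      if (const_y[k]) next
      ry <- qr.resid(qz, RY[, k])
      out[k, j] <- stats::cor(rx, ry)
    }
  }
  structure(out, class = c("sensitivity_matrix", "matrix"), n = n)
}

#' Spearman correlation between surrogate terms
#'
#' Pairwise Spearman rank correlation across the sampled population
#' (average-rank tie handling), exposing trade-offs between qualitative
#' criteria: significantly negative pairs mean satisfying one term tends to
#' violate the other. Symmetric with unit diagonal.
#'
#' @param Y Numeric matrix, rows = parameter sets, columns = terms.
#' @return `sensitivity_matrix` (terms x terms) with attribute `n`.
#' @export
spearman_terms <- function(Y) {
  Y <- as.matrix(Y)
  if (is.null(colnames(Y))) colnames(Y) <- paste0("y", seq_len(ncol(Y)))
  keep <- stats::complete.cases(Y)
  if (!all(keep)) message("dropping ", sum(!keep), " incomplete rows")
  Y <- Y[keep, , drop = FALSE]
  if (nrow(Y) < 3) stop("need at least 3 complete samples")
  const <- apply(Y, 2, function(c) diff(range(c)) == 0)
  if (any(const))
    warning("constant columns give undefined correlations: ",
            paste(colnames(Y)[const], collapse = ", "))
  m <- suppressWarnings(stats::cor(Y, method = "spearman"))
  diag(m) <- ifelse(const, NA_real_, 1)
  structure(m, class = c("sensitivity_matrix", "matrix"), n = nrow(Y))
}

#' @export
print.sensitivity_matrix <- function(x, ...) {
  cat("Sensitivity matrix (", nrow(x), " x ", ncol(x), ", n = ",
      attr(x, "n"), " samples)\n", sep = "")
  print(round(unclass(x), 3))
  invisible(x)
}

#' Write a sensitivity matrix as CSV
#' @param m A `sensitivity_matrix`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_sensitivity_csv <- function(m, path) {
  utils::write.csv(as.data.frame(unclass(m)), path, row.names = TRUE)
  invisible(path)
}
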