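#' Fit kinetic parameters to observed time courses
#'
#' Damped (Levenberg-Marquardt) least squares on replicate-averaged
#' residuals, optimizing the selected free parameters on the log10 scale
#' within bounds. Supports multi-start: additional starts are sampled
#' log-uniformly within the bounds and the best final residual wins.
#'
#' @param data Tidy observation table: columns `condition_id`, `replicate`,
#'   `time_s`, `value` (nM). Replicates are averaged per condition and time
#'   before fitting.
#' @param network Network the conditions dose.
#' @param conditions Condition grid containing every `condition_id` in
#'   `data`.
#' @param init Full named parameter set used for the fixed parameters and as
#'   the first start for the free ones.
#' @param free Character vector of parameter names to fit.
#' @param bounds A [parameter_bounds()] covering at least the free
#'   parameters; `init[free]` must lie inside.
#' @param n_starts Number of starts (1 = `init` only); common practice is
#'   48 or 96 log-uniform starts.
#' @param seed Seed for start sampling.
#' @param t_step Simulation reporting interval; data times must lie within
#'   the simulated span (values are linearly interpolated between report
#'   points).
#' @param rtol,atol Integrator tolerances.
#' @return List: `par` (full parameter set with fitted values), `free`,
#'   `ssr`, `residuals`, `converged`, `start_ssr` (per-start final SSR),
#'   `fit` (the best `nls.lm` object).
#' @export
fit_timecourses <- function(data, network, conditions, init, free, bounds,
                            n_starts = 1, seed = 1, t_step = 300,
                            rtol = 1e-6, atol = 1e-12) {
  need <- c("condition_id", "time_s", "value")
  if (!all(need %in% names(data)))
    stop("data must have columns condition_id, replicate, time_s, value")
  if (all(is.na(data$value))) stop("all observations are NA")
  if (!all(free %in% names(init))) stop("free parameters missing from init")
  if (!all(free %in% names(bounds$lower)))
    stop("bounds must cover every free parameter")
  lo <- bounds$lower[free]; hi <- bounds$upper[free]
  if (any(init[free] < lo) || any(init[free] > hi))
    stop("init outside bounds for: ",
         paste(free[init[free] < lo | init[free] > hi], collapse = ", "))

  # replicate-averaged observations per condition
  agg <- stats::aggregate(value ~ condition_id + time_s, data = data,
                          FUN = mean, na.rm = TRUE)
  ids <- unique(agg$condition_id)
  unknown <- setdiff(ids, conditions$condition_id)
  if (length(unknown))
    stop("conditions not simulable: ", paste(unknown, collapse = ", "))
  t_end <- max(agg$time_s)
  if (t_end <= 0) stop("observation times do not overlap a positive time span")

  resid_fn <- function(theta) {
    p <- init
    p[free] <- 10^theta
    res <- c()
    for (id in ids) {
      cond <- conditions[conditions$condition_id == id, ]
      obs <- agg[agg$condition_id == id, ]
      tc <- simulate_network(network, p, compose_doses(cond),
                             t_end = t_end, t_step = t_step,
                             rtol = rtol, atol = atol)
      pred <- vapply(obs$time_s, function(t)
        readout_at(tc, reporter_unit_id(cond), t), numeric(1))
      res <- c(res, pred - obs$value)
    }
    res
  }

  starts <- matrix(log10(init[free]), nrow = 1)
  if (n_starts > 1) {
    extra <- withr::with_seed(seed, {
      u <- matrix(stats::runif((n_starts - 1) * length(free)),
                  ncol = length(free))
      sweep(sweep(u, 2, log10(hi) - log10(lo), "*"), 2, log10(lo), "+")
    })
    starts <- rbind(starts, extra)
  }
  best <- NULL
  start_ssr <- numeric(nrow(starts))
  for (s in seq_len(nrow(starts))) {
    fit <- tryCatch(
      minpack.lm::nls.lm(par = starts[s, ], fn = resid_fn,
                         lower = log10(lo), upper = log10(hi),
                         # finite-difference steps must dominate integrator
                         # noise on the log10 scale
                         control = minpack.lm::nls.lm.control(maxiter = 100,
                                                              epsfcn = 1e-6)),
      error = function(e) e)
    if (inherits(fit, "error")) { start_ssr[s] <- Inf; next }
    start_ssr[s] <- fit$deviance
    if (is.null(best) || fit$deviance < best$deviance) best <- fit
  }
  if (is.null(best)) stop("no start converged")
  par <- init
  par[free] <- 10^best$par
  list(par = par, free = free, ssr = best$deviance,
       residuals = best$fvec, converged = best$info %in% 1:4,
       start_ssr = start_ssr, fit = best)
}

#' Optimize parameters against surrogate goals
#'
#' Two modes. `"soft"`: the surrogate terms, affinely scaled onto
#' \[-15, 15\] using the ranges of an initial population, are summed into a
#' single objective minimized from each start by a bound-constrained
#' quasi-Newton search (log-parameter space, bounds enforced). `"feasibility"`:
#' the goals are hard constraints; the search minimizes the summed squared
#' constraint violation with the bounds removed, starting from points drawn
#' log-uniformly between 1e-8 and 1e+8; a start whose violation reaches zero
#' is feasible.
#'
#' @param init_population Matrix of parameter sets (rows) used as starts
#'   (soft mode also uses it to freeze the term scaling).
#' @param bounds [parameter_bounds()]; required in soft mode.
#' @param goals Named goals for the term vector that `evaluate` returns.
#'   Unlike [default_goals()], names here match term names one-to-one.
#' @param mode `"soft"` or `"feasibility"`.
#' @param evaluate Function(params) -> named numeric vector of surrogate
#'   terms. Defaults to simulating the sfGFP grid on `network` and returning
#'   the report's terms.
#' @param network Network used by the default evaluator.
#' @param n_starts Number of starts (feasibility mode samples them itself;
#'   default 100; a smaller count keeps desk runs short).
#' @param seed Seed for feasibility-mode start sampling.
#' @param maxit Iteration cap per start.
#' @return List: `par` (best parameter set), `value` (best objective),
#'   `feasible` (feasibility mode: violation == 0), `status` (per-start
#'   data.frame with objective and convergence code). Errors if no start
#'   succeeds.
#' @export
optimize_surrogate <- function(init_population, bounds = NULL, goals,
                               mode = c("soft", "feasibility"),
                               evaluate = NULL, network = NULL,
                               n_starts = NULL, seed = 1, maxit = 100) {
  mode <- match.arg(mode)
  if (is.null(evaluate)) {
    if (is.null(network)) stop("supply either an evaluate function or a network")
    conds <- enumerate_conditions("sfGFP")
    evaluate <- function(p) surrogate_report(run_grid(network, p, conds))$terms
  }
  if (mode == "soft") {
    if (is.null(bounds)) stop("soft mode requires bounds")
    pop <- as.matrix(init_population)
    term0 <- t(apply(pop, 1, evaluate))
    tnames <- colnames(term0)
    rngs <- apply(term0, 2, range, finite = TRUE)
    scale1 <- function(v) {
      s <- ifelse(rngs[2, ] > rngs[1, ],
                  -15 + 30 * (v - rngs[1, ]) / (rngs[2, ] - rngs[1, ]), 0)
      sum(s)
    }
    free <- names(bounds$lower)
    obj <- function(theta) {
      p <- pop[1, ]
      p[free] <- 10^theta
      scale1(evaluate(p)[tnames])
    }
    status <- data.frame(start = seq_len(nrow(pop)), value = NA_real_,
                         convergence = NA_integer_)
    best <- NULL
    for (s in seq_len(nrow(pop))) {
      th0 <- pmin(pmax(log10(pop[s, free]), log10(bounds$lower)),
                  log10(bounds$upper))
      o <- tryCatch(stats::optim(th0, obj, method = "L-BFGS-B",
                                 lower = log10(bounds$lower),
                                 upper = log10(bounds$upper),
                                 control = list(maxit = maxit)),
                    error = function(e) e)
      if (inherits(o, "error")) next
      status$value[s] <- o$value
      status$convergence[s] <- o$convergence
      if (is.null(best) || o$value < best$value) best <- o
    }
    if (is.null(best)) stop("no optimization start succeeded")
    par <- pop[1, ]
    par[free] <- 10^best$par
    return(list(par = par, value = best$value, feasible = NA, status = status))
  }
  # feasibility mode: unbounded search minimizing goal violations
  pnames <- colnames(as.matrix(init_population))
  if (is.null(pnames)) stop("init_population must have named columns")
  if (is.null(n_starts)) n_starts <- nrow(as.matrix(init_population))
  viol <- function(theta) {
    p <- stats::setNames(10^theta, pnames)
    term <- evaluate(p)
    g <- goals[names(term)]
    v <- pmax(term - g, 0)
    sum(v[is.finite(v)]^2)
  }
  starts <- withr::with_seed(seed,
    matrix(stats::runif(n_starts * length(pnames), -8, 8), ncol = length(pnames),
           dimnames = list(NULL, pnames)))
  # seed rows of init_population replace the first sampled starts
  ip <- log10(as.matrix(init_population))
  n_seed <- min(nrow(ip), n_starts)
  starts[seq_len(n_seed), ] <- ip[seq_len(n_seed), , drop = FALSE]
  status <- data.frame(start = seq_len(n_starts), value = NA_real_,
                       convergence = NA_integer_, feasible = NA)
  best <- NULL
  for (s in seq_len(n_starts)) {
    v0 <- viol(starts[s, ])
    if (v0 == 0) {  # already feasible
      status$value[s] <- 0; status$convergence[s] <- 0; status$feasible[s] <- TRUE
      if (is.null(best) || best$value > 0)
        best <- list(par = starts[s, ], value = 0)
      next
    }
    o <- tryCatch(stats::optim(starts[s, ], viol, method = "Nelder-Mead",
                               control = list(maxit = maxit)),
                  error = function(e) e)
    if (inherits(o, "error")) next
    status$value[s] <- o$value
    status$convergence[s] <- o$convergence
    status$feasible[s] <- o$value <= 0
    if (is.null(best) || o$value < best$value) best <- o
  }
  if (is.null(best)) stop("no optimization start succeeded")
  list(par = stats::setNames(10^best$par, pnames), value = best$value,
       feasible = best$value <= 0, status = status)
}
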