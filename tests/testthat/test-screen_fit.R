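test_that("LHS stratifies every parameter's log-range with one draw per bin", {
  b <- default_bounds(sample = c("k_deg_sfGFP", "RNase0", "kr_tx_T7_weak"))
  n <- 100
  pop <- lhs_sample(b, n, seed = 7)
  expect_equal(dim(pop), c(n, length(default_parameters())))
  for (nm in names(b$lower)) {
    lg <- log10(pop[, nm])
    bins <- findInterval(lg, seq(log10(b$lower[[nm]]), log10(b$upper[[nm]]),
                                 length.out = n + 1), rightmost.closed = TRUE)
    expect_equal(sort(bins), 1:n)
  }
  # fixed parameters are constant at their nominal values
  expect_equal(unique(pop[, "b"]), unname(default_parameters()["b"]))
  # reproducible under the seed; n = 1 stays inside bounds
  expect_identical(pop, lhs_sample(b, n, seed = 7))
  one <- lhs_sample(b, 1, seed = 3)
  expect_true(all(one[, names(b$lower)] >= b$lower &
                    one[, names(b$lower)] <= b$upper))
})

test_that("filter heuristics encode the four affinity orderings", {
  p <- default_parameters()
  expect_true(heuristic_filter(p))
  # rule 1: T7 strong must outbind T7 weak
  bad <- p; bad["kr_tx_T7_strong"] <- bad["kr_tx_T7_weak"] * 2
  expect_false(heuristic_filter(bad))
  # rule 2: sigma-70 weak must be the weakest native binder
  bad <- p; bad["kr_tx_sig70_weak"] <- 1e-6
  expect_false(heuristic_filter(bad))
  # rule 3: reporters must bind the nuclease more weakly than kanR/empty
  bad <- p; bad["kr_nuc_kanR"] <- 1e4
  expect_false(heuristic_filter(bad))
  # rule 4: the empty vector must degrade fastest
  bad <- p; bad["k_deg_empty"] <- bad["k_deg_sfGFP"] / 2
  expect_false(heuristic_filter(bad))
  expect_error(heuristic_filter(p[1:3]), "missing parameters")
})

test_that("filter acceptance depends only on Kd ratios, not on kf/kr scale", {
  set.seed(5)
  for (i in 1:20) {
    p <- default_parameters()
    idx <- grep("^k[fr]_(tx|nuc)_", names(p))
    scale <- 10^runif(1, -3, 3)
    p[grep("^kf_", names(p)[idx], value = TRUE)] <-
      p[grep("^kf_", names(p)[idx], value = TRUE)] * scale
    p[grep("^kr_", names(p)[idx], value = TRUE)] <-
      p[grep("^kr_", names(p)[idx], value = TRUE)] * scale
    expect_true(heuristic_filter(p))
  }
})

test_that("with only the T7 ordering active, acceptance is a coin flip", {
  # iid log-uniform Kds for the two T7 promoters; all other rules satisfied
  # by construction, so the acceptance fraction estimates P(Kd_s < Kd_w) = 1/2
  p <- default_parameters()
  set.seed(21)
  n <- 4000
  acc <- vapply(seq_len(n), function(i) {
    q <- p
    q["kr_tx_T7_strong"] <- 10^runif(1, -3, 1)
    q["kr_tx_T7_weak"] <- 10^runif(1, -3, 1)
    heuristic_filter(q)
  }, logical(1))
  expect_equal(mean(acc), 0.5, tolerance = 0.05)
})

test_that("screening ranks the fixture parameterization first and scores
           toxin-free sets as missing the strong-promoter baseline", {
  net <- build_network()
  conds <- enumerate_conditions("sfGFP", combos = "reporter_only")
  p_fix <- default_parameters()
  p_weak <- p_fix; p_weak["k_toxin"] <- 0
  p_odd <- p_fix; p_odd["RNAP0_native"] <- 0.3; p_odd["k_toxin"] <- 0
  scr <- screen(rbind(p_fix, p_weak, p_odd), net, conds)
  expect_equal(nrow(scr$results), 3)
  expect_equal(scr$results$rank[1], 1)
  rep2 <- scr$reports[[2]]
  expect_false(rep2$criteria$baseline_strong)
  rep3 <- scr$reports[[3]]
  expect_false(rep3$criteria$baseline_strong)
  # empty population passes through
  empty <- screen(list(), net, conds)
  expect_equal(nrow(empty$results), 0)
})

test_that("noise-free data generated at the initial guess is a fixed point
           of the fit", {
  net <- build_network()
  p <- default_parameters()
  conds <- enumerate_conditions("sfGFP", promoters = "sig70_strong",
                                concs = c(2.5, 10), combos = "reporter_only")
  fx <- generate_fixture(net, p, conds, cv = 0, replicates = 1)
  fit <- fit_timecourses(fx, net, conds, init = p,
                         free = c("k_deg_sfGFP", "RNase0"),
                         bounds = default_bounds(p))
  expect_lt(fit$ssr, 1e-6)
  expect_equal(fit$par[c("k_deg_sfGFP", "RNase0")],
               p[c("k_deg_sfGFP", "RNase0")], tolerance = 1e-3)
})

test_that("fit rejects starts outside bounds and unusable data", {
  net <- build_network()
  p <- default_parameters()
  conds <- enumerate_conditions("sfGFP", promoters = "sig70_strong",
                                concs = 2.5, combos = "reporter_only")
  b <- default_bounds(p, span = 2)
  bad_init <- p; bad_init["RNase0"] <- p[["RNase0"]] * 10
  expect_error(
    fit_timecourses(data.frame(condition_id = conds$condition_id,
                               replicate = 1, time_s = 300, value = 1),
                    net, conds, bad_init, c("RNase0"), b),
    "outside bounds")
  expect_error(
    fit_timecourses(data.frame(condition_id = "nope", replicate = 1,
                               time_s = 300, value = 1),
                    net, conds, p, "RNase0", default_bounds(p)),
    "not simulable")
  expect_error(
    fit_timecourses(data.frame(condition_id = conds$condition_id,
                               replicate = 1, time_s = 300,
                               value = NA_real_),
                    net, conds, p, "RNase0", default_bounds(p)),
    "all observations")
})

test_that("feasibility mode finds a known feasible box and flags feasible
           starts immediately", {
  # toy 2-parameter problem: terms are log-distances to a box around (1, 10)
  evalf <- function(p) {
    c(t1 = abs(log10(p[["a"]]) - 0) - 1,   # feasible iff a in [0.1, 10]
      t2 = abs(log10(p[["b"]]) - 1) - 1)   # feasible iff b in [1, 100]
  }
  goals <- c(t1 = 0, t2 = 0)
  pop <- matrix(c(1e6, 1e-6), 1, 2, dimnames = list(NULL, c("a", "b")))
  res <- optimize_surrogate(pop, goals = goals, mode = "feasibility",
                            evaluate = evalf, n_starts = 6, seed = 2,
                            maxit = 500)
  expect_true(res$feasible)
  expect_true(abs(log10(res$par[["a"]])) <= 1 + 1e-6)
  expect_true(abs(log10(res$par[["b"]]) - 1) <= 1 + 1e-6)
  # a start already satisfying the goals is feasible with no search
  pop0 <- matrix(c(1, 10), 1, 2, dimnames = list(NULL, c("a", "b")))
  res0 <- optimize_surrogate(pop0, goals = goals, mode = "feasibility",
                             evaluate = evalf, n_starts = 1)
  expect_true(res0$feasible)
  expect_identical(res0$value, 0)
})

test_that("soft mode minimizes the scaled-term sum within bounds", {
  evalf <- function(p) c(t1 = log10(p[["a"]]), t2 = (log10(p[["a"]]) - 1)^2)
  bounds <- parameter_bounds(lower = c(a = 1e-3), upper = c(a = 1e3))
  pop <- matrix(10^c(-2, 0, 2), 3, 1, dimnames = list(NULL, "a"))
  res <- optimize_surrogate(pop, bounds = bounds, goals = NULL, mode = "soft",
                            evaluate = evalf)
  # the returned optimum is the best across starts and beats every start's
  # own initial objective
  expect_lte(res$value, min(res$status$value, na.rm = TRUE))
  expect_true(all(is.finite(res$status$value)))
  expect_error(optimize_surrogate(pop, bounds = NULL, goals = NULL,
                                  mode = "soft", evaluate = evalf),
               "requires bounds")
})
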