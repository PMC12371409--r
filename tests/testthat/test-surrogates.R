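ro <- function(...) {
  v <- c(...)
  stats::setNames(v, c("0.5", "1", "2.5", "5", "10", "15", "30"))
}

test_that("baseline penalty implements the signed log-magnitude rule", {
  # strong promoter, 30 nM below the best lower concentration: desired
  r <- ro(10, 20, 30, 40, 50, 60, 50)
  expect_equal(baseline_penalty(r, "T7_strong"), -1)
  # strong promoter, 30 nM the maximum: undesired, positive term
  r <- ro(10, 20, 30, 40, 50, 60, 160)
  expect_equal(baseline_penalty(r, "T7_strong"), 2)
  # sigma-70 weak with 30 nM the maximum by 10 nM: desired, negative
  r <- ro(1, 2, 3, 4, 5, 10, 20)
  expect_equal(baseline_penalty(r, "sig70_weak"), -1)
  # sigma-70 weak with a decrease at 30: undesired
  r <- ro(1, 2, 3, 4, 5, 20, 10)
  expect_equal(baseline_penalty(r, "sig70_weak"), 1)
  # zero difference saturates at the floor (term = -s * 12; a tie counts as
  # "30 nM is the maximum" for the sign indicator)
  r <- ro(1, 2, 3, 4, 5, 60, 60)
  expect_equal(baseline_penalty(r, "T7_strong"), -12)
  expect_equal(baseline_penalty(r, "sig70_weak"), 12)
  expect_error(baseline_penalty(r[-2], "T7_strong"), "missing concentrations")
})

ct_slice <- function(ratios, concs) {
  data.frame(promoter = "sig70_strong", reporter_conc_nM = concs,
             combo = "empty_no_promoter", ratio = ratios)
}

test_that("positive and negative crosstalk terms follow their definitions", {
  low <- c(0.5, 1, 2.5)
  high <- c(5, 10, 15, 30)
  expect_equal(positive_crosstalk_term(ct_slice(rep(1, 3), low)), 0)
  expect_equal(positive_crosstalk_term(ct_slice(c(1, 1.2, 1.1), low)), -0.2)
  expect_equal(positive_crosstalk_term(ct_slice(c(0.8, 0.7, 0.75), low)), 0.2)
  expect_equal(negative_crosstalk_term(ct_slice(rep(1, 4), high)), 0)
  expect_equal(negative_crosstalk_term(ct_slice(c(0.9, 0.7, 0.8, 1), high)), -0.3)
  expect_equal(negative_crosstalk_term(ct_slice(c(1.2, 1.1, 1.3, 1.4), high)), 0.1)
  expect_warning(r <- positive_crosstalk_term(ct_slice(NA_real_, 1)),
                 "undefined")
  expect_true(is.na(r))
})

test_that("auxiliary terms: large-positive arithmetic and deviation of a
           self-reference", {
  ct <- rbind(
    data.frame(promoter = "T7_strong", reporter_conc_nM = c(1, 10),
               combo = "empty_T7_strong", ratio = c(1.1, 0.9)),
    data.frame(promoter = "sig70_weak", reporter_conc_nM = c(1, 10),
               combo = "empty_T7_strong", ratio = c(1.5, 1.0)))
  grid <- list(crosstalk = ct,
               conditions = data.frame(condition_id = "x",
                                       combo = "reporter_only"),
               mrna = data.frame(condition_id = "x", mrna_end = 1e-9,
                                 mrna_peak = 100))
  aux <- auxiliary_terms(grid)
  expect_equal(aux$large_positive_term, 1.1 - 1.5)
  expect_true(is.na(aux$deviation_term))
  aux <- auxiliary_terms(grid, reference_ratios = ct)
  expect_equal(aux$deviation_term, 0)
  # fully decayed transcripts floor the residual-mRNA term
  grid$mrna$mrna_end <- 0
  expect_equal(auxiliary_terms(grid)$residual_mrna_term, -12)
})

test_that("criteria comparison is inclusive and counts satisfied goals", {
  terms <- c(baseline_T7_strong = -1e-4, baseline_T7_weak = -2,
             baseline_sig70_strong = -3, baseline_sig70_weak = -1e-4,
             pos_T7_strong = -0.05, neg_T7_strong = -0.05,
             pos_T7_weak = -0.2, neg_T7_weak = -0.01,
             pos_sig70_strong = 0.1, neg_sig70_strong = -0.3,
             pos_sig70_weak = -0.4, neg_sig70_weak = -0.2,
             large_positive_term = -0.05, deviation_term = 0.2,
             residual_mrna_term = -3)
  goals <- default_goals()
  goals["deviation"] <- 0.2
  goals["residual_mrna"] <- -2.9
  rep <- evaluate_criteria(terms, goals)
  # boundary values (exactly at goal) are satisfied
  expect_true(rep$criteria$baseline_strong)
  expect_true(rep$criteria$crosstalk_T7_strong)
  expect_true(rep$criteria$deviation)
  # one violated sub-term breaks a per-promoter crosstalk criterion
  expect_false(rep$criteria$crosstalk_T7_weak)
  expect_false(rep$criteria$crosstalk_sig70_strong)
  expect_true(rep$criteria$crosstalk_sig70_weak)
  expect_true(rep$criteria$residual_mrna)   # -3 <= -2.9
  expect_equal(rep$n_satisfied, sum(unlist(rep$criteria)))
  expect_equal(rep$n_satisfied, 7)
  expect_false(rep$key_trend_complete)
  expect_error(evaluate_criteria(terms, goals[c("baseline", "crosstalk")]),
               "missing goals")
})

test_that("population scaling maps ranges onto [-15, 15] preserving order", {
  m <- cbind(a = c(2, 4, 10), b = c(-1, 0, 3))
  s <- scale_terms(m)
  expect_equal(s[, "a"], c(-15, -7.5, 15))
  expect_equal(range(s[, "b"]), c(-15, 15))
  # midpoint of the range maps to 0
  expect_equal(scale_terms(cbind(x = c(0, 5, 10)))[2], 0)
  set.seed(42)
  for (i in 1:10) {
    v <- rnorm(20)
    expect_equal(order(scale_terms(cbind(v = v))[, 1]), order(v))
  }
  expect_warning(s <- scale_terms(cbind(c = rep(3, 4))), "constant")
  expect_equal(unname(s[, 1]), rep(0, 4))
  expect_error(scale_terms(matrix(1, 1, 1)), ">= 2")
})

test_that("the shipped fixture parameterization completes the key trends", {
  net <- build_network()
  g <- run_grid(net, default_parameters(), enumerate_conditions("sfGFP"))
  rep <- surrogate_report(g)
  expect_true(rep$criteria$baseline_strong)
  expect_true(rep$criteria$baseline_sig70_weak)
  for (pr in c("T7_strong", "T7_weak", "sig70_strong", "sig70_weak"))
    expect_true(rep$criteria[[paste0("crosstalk_", pr)]])
  expect_true(rep$key_trend_complete)
  # positive-to-negative transition with increasing reporter concentration
  ct <- g$crosstalk[g$crosstalk$promoter == "sig70_strong" &
                      g$crosstalk$combo == "empty_sig70_strong", ]
  ct <- ct[order(ct$reporter_conc_nM), ]
  expect_true(all(ct$ratio[ct$reporter_conc_nM <= 2.5] > 1))
  expect_true(any(ct$ratio[ct$reporter_conc_nM >= 5] < 1))
})

test_that("forcing zero empty doses drives both crosstalk terms to zero", {
  net <- build_network()
  conds <- enumerate_conditions("sfGFP", promoters = "T7_strong",
                                empty_conc = 0)
  g <- run_grid(net, default_parameters(), conds)
  slice <- g$crosstalk[g$crosstalk$promoter == "T7_strong", ]
  expect_equal(positive_crosstalk_term(slice), 0, tolerance = 1e-6)
  expect_equal(negative_crosstalk_term(slice), 0, tolerance = 1e-6)
})
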