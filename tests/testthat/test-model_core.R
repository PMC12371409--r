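test_that("default registry compiles to the ten experiment constructs", {
  reg <- default_registry()
  expect_length(reg, 10)
  net <- build_network(reg)
  expect_s3_class(net, "txtl_network")
  expect_length(net$units, 10)
  # per class: 4 translated sfGFP (with maturation), 3 aptamer, 2 empty, kanR
  translatable <- vapply(net$units, function(u) u$translatable, logical(1))
  expect_equal(sum(translatable), 5)
  expect_true(all(c("sfGFP_sig70_weak", "aptamer_sig70_strong",
                    "empty_T7_strong", "kanR") %in% names(net$units)))
})

test_that("degenerate and single-unit networks have the expected structure", {
  empty <- build_network(list())
  expect_equal(empty$species,
               c("RNAP_native", "RNAP_T7", "Ribo", "RNase", "NTP", "AA", "toxin"))
  labels <- vapply(empty$reactions, function(r) r$label, character(1))
  expect_equal(labels, "toxin_drain")

  pr <- promoter_spec("sig70_strong", "native", kf_tx = 0.01, kr_tx = 0.1)
  u <- transcription_unit("apt", pr, transcript_length = 200,
                          kf_nuc = 0.01, kr_nuc = 0.5, k_deg = 0.02,
                          readout = "free_rna")
  net <- build_network(list(u), toxin = toxin_config("off", b = 0,
                                                     k_toxin = 0,
                                                     toxin_threshold = 0))
  # DNA, DNA:pol complex, mRNA, mRNA:nuclease complex + 7 globals
  expect_length(net$species, 11)
})

test_that("malformed unit declarations are rejected", {
  pr <- promoter_spec("T7_strong", "T7", kf_tx = 0.01, kr_tx = 0.1)
  u <- transcription_unit("a", pr, 100, kf_nuc = 1e-3, kr_nuc = 0.1,
                          k_deg = 0.01)
  expect_error(build_network(list(u, u)), "duplicate unit id")
  expect_error(
    transcription_unit("b", pr, 100, translatable = FALSE, protein_length = 50,
                       kf_nuc = 1e-3, kr_nuc = 0.1, k_deg = 0.01),
    "protein_length 0")
  expect_error(toxin_config("TX_QUUX"), "unknown toxin variant")
  expect_error(promoter_spec("p", "T7", kf_tx = 0, kr_tx = 0.1), "> 0")
})

test_that("toxin gate is exact at threshold, bounded, and monotone", {
  cfg <- toxin_config("TL_TL", b = 1, k_toxin = 0.1, toxin_threshold = 40)
  expect_identical(toxin_gate(40, cfg), 1)
  expect_equal(toxin_gate(-1e6, cfg), 0)
  expect_equal(toxin_gate(1e6, cfg), 2)
  x <- seq(25, 55, length.out = 400)  # within tanh's numerically strict range
  g <- toxin_gate(x, cfg)
  expect_true(all(diff(g) > 0))
  expect_true(all(g > 0 & g < 2))
  expect_error(toxin_gate(1, toxin_config("off")), "off")
})

test_that("rhs matches the independently coded one-unit oracle", {
  net <- one_unit_network()
  g <- global_params()
  set.seed(11)
  for (rep in 1:25) {
    state <- stats::setNames(runif(length(net$species), 0, 50), net$species)
    state["NTP"] <- runif(1, 0, 2e5)
    state["AA"] <- runif(1, 0, 2e5)
    state["toxin"] <- runif(1, -20, 120)
    got <- evaluate_rhs(net, state, g)
    want <- oracle_rhs_one_unit(state, g, kf_tx = 0.01, kr_tx = 0.1,
                                kf_rbs = 0.01, kr_rbs = 1, kf_nuc = 0.01,
                                kr_nuc = 0.5, k_deg = 0.02, k_mat = 0.002,
                                L = 900, l = 300, b = 0.1, k_toxin = 0.001,
                                thr = 50)
    expect_equal(got[names(want)], want, tolerance = 1e-12)
  }
})

test_that("rhs at an all-zero state is the pure toxin drain", {
  for (variant in c("TL_TL", "TX_TX", "TL_TX", "TX_TL")) {
    net <- one_unit_network(toxin = toxin_config(variant, b = 0.7,
                                                 k_toxin = 0.01,
                                                 toxin_threshold = 10))
    dy <- evaluate_rhs(net, numeric(length(net$species)), global_params())
    expect_equal(unname(dy[["toxin"]]), -0.7)
    expect_true(all(dy[setdiff(names(dy), "toxin")] == 0))
  }
})

test_that("toxin-gated degradation rate is exactly k_toxin * target at threshold", {
  net <- one_unit_network(toxin = toxin_config("TL_TL", b = 0,
                                               k_toxin = 0.05,
                                               toxin_threshold = 25))
  state <- stats::setNames(numeric(length(net$species)), net$species)
  state["Ribo"] <- 120
  state["toxin"] <- 25
  dy <- evaluate_rhs(net, state, global_params())
  expect_equal(unname(dy[["Ribo"]]), -0.05 * 120)
})

test_that("rhs input validation catches bad states", {
  net <- one_unit_network()
  expect_error(evaluate_rhs(net, numeric(3), global_params()), "species count")
  bad <- numeric(length(net$species)); bad[2] <- NaN
  expect_error(evaluate_rhs(net, bad, global_params()), "non-finite")
})

test_that("conservation totals equal the initials on a freshly dosed state", {
  net <- build_network()
  p <- default_parameters()
  y0 <- cfecrosstalk:::initial_state(net, p,
                                     dose_schedule(dna = c(kanR = 10)))
  tot <- conservation_totals(net, y0)
  expect_equal(tot[["RNAP_native"]], unname(p["RNAP0_native"]))
  expect_equal(tot[["RNAP_T7"]], unname(p["RNAP0_T7"]))
  expect_equal(tot[["Ribo"]], unname(p["Ribo0"]))
  expect_equal(tot[["RNase"]], unname(p["RNase0"]))
})

test_that("ribosomes are irreversibly lost in a TL_TL run past threshold", {
  net <- build_network()
  p <- default_parameters()
  d <- dose_schedule(dna = c(sfGFP_T7_strong = 30, kanR = 30))
  tc <- simulate_network(net, p, d, t_step = 60)
  end <- tc$trajectories[, ncol(tc$trajectories)]
  # the gate self-regulates around the threshold: the toxin reaches it and
  # ribosomes (free + bound) are irreversibly degraded
  expect_gt(max(tc$readouts$toxin), unname(p["toxin_threshold"]) * 0.95)
  expect_lt(conservation_totals(net, end)[["Ribo"]], unname(p["Ribo0"]) * 0.5)
})

test_that("model config round trips through YAML", {
  net <- build_network()
  p <- default_parameters()
  path <- withr::local_tempfile(fileext = ".yaml")
  write_model_config(net, p, path)
  back <- read_model_config(path)
  expect_equal(back$network$species, net$species)
  expect_equal(length(back$network$reactions), length(net$reactions))
  expect_equal(back$params[names(p)], p)
  # identical dynamics after the round trip
  state <- stats::setNames(seq_along(net$species) * 0.1, net$species)
  expect_equal(evaluate_rhs(back$network, state, p),
               evaluate_rhs(net, state, p))
})
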