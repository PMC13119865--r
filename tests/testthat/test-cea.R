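test_that("incremental results are classified before any ratio is reported", {
  res <- icer(57340.81, 60103.22, 9.747, 9.721)
  expect_equal(res$incremental_cost, -2762.41)
  expect_equal(res$incremental_qaly, 0.026)
  expect_equal(res$classification, "dominant")
  expect_true(is.na(res$icer))

  expect_equal(icer(100, 100, 1, 1)$classification, "equivalent")
  r <- icer(110, 100, 1.05, 1.00)
  expect_equal(r$classification, "icer")
  expect_equal(r$icer, 200)
  expect_equal(icer(90, 100, 1, 1)$classification, "cost_saving")
  expect_equal(icer(100, 90, 0.9, 1)$classification, "dominated")
})

test_that("net monetary benefit follows the decision rule", {
  expect_equal(nmb(-2762.40, 0.03, 20000), 3362.40)
  expect_equal(nmb(0, 0, 12345), 0)
  expect_equal(nmb(500, 0.05, 10000), 0)
  expect_error(nmb(1, 1, -5), "nonnegative")
})

test_that("the bound rule caps probabilities at one and rejects negatives", {
  b <- dsa_bounds(0.8, "probability")
  expect_equal(unname(b["lo"]), 0.8 * 0.608)
  expect_equal(unname(b["hi"]), 1)
  b2 <- dsa_bounds(94, "cost")
  expect_equal(unname(b2["hi"]), 94 * 1.392)
})

test_that("one-way analysis re-runs the pipeline at both extremes", {
  p <- default_params()
  res <- one_way_dsa(p, "costs.copd_hospital_stay")
  expect_equal(res$base, 1930.01)
  expect_s3_class(res$lo, "ce_result")
  expect_s3_class(res$hi, "ce_result")
  # a costlier hospital stay favours the arm with fewer admissions
  expect_lt(res$hi$incremental_cost, res$lo$incremental_cost)
  expect_error(one_way_dsa(p, "costs.rp21_test", lo = 100, hi = 200),
               "bracket")
})

test_that("the break-even price search agrees with the analytic solution", {
  p <- default_params()
  base <- run_model(p)
  lambda <- p$structural$wtp_threshold
  # the price enters the incremental cost linearly with unit slope, so the
  # analytic break-even is base price + NMB at base price
  analytic <- get_param(p, "costs.rp21_test") +
    nmb(base$incremental_cost, base$incremental_qaly, lambda)
  found <- threshold_price(p, lambda = lambda)
  expect_equal(found, analytic, tolerance = 0.02 / analytic)
  expect_gt(found, get_param(p, "costs.rp21_test"))
  expect_error(threshold_price(p, lambda = 0, bracket = c(5000, 10000)),
               "sign change")
})

test_that("probabilistic draws are reproducible and finite", {
  p <- default_params()
  expect_equal(run_psa(p, n = 0, seed = 1)$n, 0)
  a <- run_psa(p, n = 50, seed = 42)
  b <- run_psa(p, n = 50, seed = 42)
  expect_identical(a$draws, b$draws)
  c <- run_psa(p, n = 50, seed = 43)
  expect_false(identical(a$draws, c$draws))
  expect_true(all(is.finite(a$draws$dcost)))
  expect_true(all(is.finite(a$draws$dqaly)))
})

test_that("per-draw totals from the propagation operator match a full model run", {
  # continuity: as standard errors shrink, draws converge on the
  # deterministic base case computed by the ordinary pipeline
  shrunk <- config_variant(function(cfg) {
    for (nm in names(cfg$costs)) cfg$costs[[nm]]$se <- cfg$costs[[nm]]$mean * 1e-6
    for (nm in names(cfg$utilities$recovery))
      if (cfg$utilities$recovery[[nm]]$dist == "beta")
        cfg$utilities$recovery[[nm]]$se <- 1e-7
    for (nm in names(cfg$utilities$gold)) cfg$utilities$gold[[nm]]$se <- 1e-7
    for (grp in c("intervention", "control", "shared", "hospitalisation"))
      for (nm in names(cfg$probabilities[[grp]]))
        cfg$probabilities[[grp]][[nm]]$se <- 1e-7
    cfg
  })
  p <- load_config(shrunk)
  base <- run_model(p)
  s <- run_psa(p, n = 20, seed = 5)
  expect_equal(mean(s$draws$dcost), base$incremental_cost, tolerance = 1e-3)
  expect_equal(mean(s$draws$dqaly), base$incremental_qaly, tolerance = 1e-3)
})

test_that("the acceptability curve counts positive-benefit draws with half ties", {
  all_dominant <- structure(list(
    draws = data.frame(dcost = c(-10, -5, -1), dqaly = c(0.01, 0.02, 0.005)),
    n = 3L, seed = 1L), class = "psa_samples")
  cc <- ceac(all_dominant)
  expect_true(all(cc$probability == 1))

  # symmetric draws about the NMB boundary at lambda 10000
  sym <- structure(list(
    draws = data.frame(dcost = c(100, -100, 50, -50), dqaly = c(0, 0, 0, 0)),
    n = 4L, seed = 1L), class = "psa_samples")
  expect_equal(ceac(sym, lambda_grid = 10000)$probability, 0.5)
  ties <- structure(list(
    draws = data.frame(dcost = c(0, 0), dqaly = c(0, 0)), n = 2L, seed = 1L),
    class = "psa_samples")
  expect_equal(ceac(ties, lambda_grid = c(0, 20000))$probability, c(0.5, 0.5))

  empty <- structure(list(draws = data.frame(dcost = numeric(), dqaly = numeric()),
                          n = 0L, seed = 1L), class = "psa_samples")
  expect_error(ceac(empty), "nonempty")

  # brute-force recount oracle
  p <- default_params()
  s <- run_psa(p, n = 300, seed = 9)
  grid <- seq(0, 50000, by = 5000)
  got <- ceac(s, grid)$probability
  want <- vapply(grid, function(l) {
    hits <- 0
    for (i in seq_len(s$n)) {
      v <- l * s$draws$dqaly[i] - s$draws$dcost[i]
      if (v > 0) hits <- hits + 1 else if (v == 0) hits <- hits + 0.5
    }
    hits / s$n
  }, numeric(1))
  expect_equal(got, want, tolerance = 1e-12)
  expect_true(all(got >= 0 & got <= 1))
})
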