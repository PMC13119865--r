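# A transition model with an identity alive block and configurable mortality,
# for closed-form checks.
inert_params <- function(qd = 0) {
  p <- default_params()
  p$markov$severity_transitions <- list(stable = c(1, 0, 0),
                                        mild = c(0, 1, 0),
                                        moderate = c(0, 0, 1))
  p$markov$stage_progression <- list(stable = 0, mild = 0, moderate = 0)
  for (s in c("stable", "mild", "moderate"))
    p$markov$disease_death[[s]] <- rep(qd, 3)
  p$markov$mortality$baseline <- 1e-300  # no effective all-cause mortality
  p
}

test_that("annual probabilities convert to quarterly cycles by the power rule", {
  expect_equal(annual_to_cycle_probability(0), 0)
  expect_equal(annual_to_cycle_probability(1), 1)
  expect_equal(annual_to_cycle_probability(0.04), 1 - 0.96^0.25)
  expect_error(annual_to_cycle_probability(1.2), "outside")
  expect_error(annual_to_cycle_probability(-0.1), "outside")
})

test_that("resolved matrices are row-stochastic with mortality overlaid", {
  p <- default_params()
  tm <- build_transition_model(p)
  M <- resolve_matrix(tm, 70)
  expect_equal(unname(rowSums(M)), rep(1, 10), tolerance = 1e-12)
  expect_equal(unname(M[10, ]), c(rep(0, 9), 1))  # dead is absorbing
  expect_error(resolve_matrix(tm, 500), "outside mortality table")

  # zero mortality: alive block passes through unchanged
  p0 <- inert_params()
  p0$markov <- default_params()$markov
  p0$markov$mortality$baseline <- 1e-300
  for (s in c("stable", "mild", "moderate"))
    p0$markov$disease_death[[s]] <- rep(0, 3)
  tm0 <- build_transition_model(p0)
  M0 <- resolve_matrix(tm0, 70)
  expect_equal(M0[1:9, 1:9], copdcea:::alive_block(p0$markov), tolerance = 1e-10,
               ignore_attr = TRUE)

  # certain death: every alive row sends its mass to dead
  p1 <- default_params()
  p1$markov$mortality <- list(type = "gompertz", baseline = 1e6, slope = 0,
                              max_age = 100)
  M1 <- resolve_matrix(build_transition_model(p1), 70)
  expect_equal(unname(M1[, 10]), rep(1, 10), tolerance = 1e-12)

  # property: random configurations stay row-stochastic
  for (seed in 1:20) {
    tm_r <- build_transition_model(random_markov_params(seed))
    for (age in c(60, 75, 99))
      expect_equal(unname(rowSums(resolve_matrix(tm_r, age))), rep(1, 10),
                   tolerance = 1e-12)
  }
})

test_that("an inert cohort with unit utility accrues exactly a quarter per cycle", {
  p <- inert_params()
  p$structural$annual_discount_rate <- 0
  tm <- build_transition_model(p)
  entry <- c(1, rep(0, 9))
  trace <- run_cohort(entry, tm, p$structural, rep(0, 10),
                      c(rep(1, 9), 0))
  expect_equal(trace$qaly_total, 160 * 0.25, tolerance = 1e-9)
  expect_equal(trace$cost_total, 0)
})

test_that("constant per-cycle mortality decays occupancy geometrically", {
  p <- inert_params(qd = 0.1)
  tm <- build_transition_model(p)
  entry <- c(1, rep(0, 9))
  trace <- run_cohort(entry, tm, p$structural, rep(0, 10), rep(0, 10))
  for (t in c(1, 5, 40, 160))
    expect_equal(unname(trace$occupancy[t + 1, 1]), 0.9^t, tolerance = 1e-9)
})

test_that("half-cycle discounting matches its closed form and monotonicity", {
  expect_equal(discount_half_cycle(c(3, 4, 5), 0), 12)
  expect_equal(discount_half_cycle(100, 0.035, 0.25), 100 * 1.035^(-0.125))
  expect_equal(discount_half_cycle(100, 0.035, 0.25), 99.571, tolerance = 1e-4)
  two <- discount_half_cycle(c(100, 100), 0.035, 0.25)
  expect_lt(two, 200)
  expect_gt(two, 100 * 1.035^(-0.125))
  expect_error(discount_half_cycle(1, -0.01), "nonnegative")
  # totals non-increasing in the rate
  rates <- c(0, 0.01, 0.035, 0.1)
  totals <- vapply(rates, function(r) discount_half_cycle(rep(50, 20), r), numeric(1))
  expect_true(all(diff(totals) < 0))
})

test_that("the cohort trace equals the naive matrix-multiplication oracle", {
  for (seed in 1:15) {
    p <- random_markov_params(seed)
    entry <- random_entry(seed + 1000)
    sv <- state_values(p)
    tm <- build_transition_model(p)
    trace <- run_cohort(entry, tm, p$structural, sv$costs, sv$utilities)
    want <- oracle_cohort(entry, p, sv$costs, sv$utilities)
    expect_equal(trace$cost_total, want$cost_total, tolerance = 1e-10)
    expect_equal(trace$qaly_total, want$qaly_total, tolerance = 1e-10)
    expect_equal(unname(trace$occupancy), want$occupancy, tolerance = 1e-10)
  }
})

test_that("occupancy is conserved and the dead state absorbs", {
  p <- default_params()
  run <- run_arm(p, "control")
  occ <- run$trace$occupancy
  expect_equal(unname(rowSums(occ)), rep(1, nrow(occ)), tolerance = 1e-9)
  expect_true(all(diff(occ[, 10]) >= -1e-15))
})

test_that("arm totals of identical runs cancel and state costs price severity", {
  p <- default_params()
  run <- run_arm(p, "control")
  tot <- arm_totals(run, run)
  expect_equal(tot$cost_intervention - tot$cost_control, 0)
  expect_equal(tot$qaly_intervention - tot$qaly_control, 0)

  sv <- state_values(p)
  # severity gradient: moderate states cost more and carry lower utility
  expect_true(all(sv$costs[c("moderate_II", "moderate_III", "moderate_IV")] >
                    sv$costs[c("mild_II", "mild_III", "mild_IV")]))
  expect_true(all(sv$utilities[c("moderate_II", "moderate_III", "moderate_IV")] <
                    sv$utilities[c("mild_II", "mild_III", "mild_IV")]))
  expect_equal(unname(sv$costs["dead"]), 0)
  expect_equal(unname(sv$utilities["dead"]), 0)
})

test_that("trace export writes one row per cycle", {
  p <- default_params()
  run <- run_arm(p, "intervention")
  csv <- tempfile(fileext = ".csv")
  write_trace_csv(run$trace, csv)
  df <- utils::read.csv(csv, check.names = FALSE)
  expect_equal(nrow(df), 160)
  expect_true(all(state_space() %in% names(df)))
})
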