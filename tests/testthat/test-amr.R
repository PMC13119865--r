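test_that("the penalty chain reproduces the published derivation", {
  p <- default_params()
  chain <- penalty_chain(p$amr)
  expect_equal(chain$annual_usd, 1e14 / 35)
  expect_equal(chain$annual_usd_display, 2.8e12)   # truncated, not rounded
  expect_equal(chain$annual_ddd, 14.1 / 1000 * 7.8e9 * 365)
  expect_equal(chain$annual_ddd, 4.01e10, tolerance = 2e-3)
  expect_equal(chain$prescriptions_per_year, chain$annual_ddd / 5)
  expect_equal(chain$prescriptions_per_year, 8.0e9, tolerance = 5e-3)

  # canonical chain: $356.96 -> £285.84 -> x RMf -> £105.76
  expect_equal(unname(chain$gbp_per_prescription["canonical"]), 285.84,
               tolerance = 1e-4)
  expect_equal(penalty_per_prescription(chain, "canonical"), 105.76,
               tolerance = 1e-4)
  # the RMf is pinned by the division oracle between the two printed values
  expect_equal(round(105.76 / 285.84, 3), p$amr$rmf)

  # computed chain diverges from the canonical one and is flagged
  expect_true(chain$divergence)
  expect_equal(penalty_per_prescription(chain, "computed"), 103.4,
               tolerance = 1e-2)

  bad <- p$amr
  bad$rmf <- 0
  expect_error(penalty_chain(bad), "RMf")
})

test_that("chain step arithmetic holds on trivial inputs", {
  expect_equal(annualise_total(70, 35), 2)
  expect_equal(annualise_total(0, 35), 0)
  expect_error(annualise_total(100, 0), "positive")
  expect_equal(annual_ddd(0, 7.8e9), 0)
  expect_equal(annual_ddd(1, 1000), 365)
  expect_equal(prescriptions_per_year(10, 5), 2)
  expect_equal(prescriptions_per_year(0, 5), 0)
  expect_error(prescriptions_per_year(10, 0), "positive")
})

test_that("penalties increment exactly the antibiotic cost items", {
  p <- default_params()
  same <- apply_penalty(p, 0)
  expect_equal(parameters_table(same)$mean, parameters_table(p)$mean)

  pen <- apply_penalty(p, 105.76)
  expect_equal(pen$costs$antibiotic_course$mean, 107.60)
  expect_equal(pen$costs$alternative_antibiotics$mean, 1.01 + 105.76)
  untouched <- setdiff(names(p$costs), c("antibiotic_course", "alternative_antibiotics"))
  for (nm in untouched) expect_equal(pen$costs[[nm]]$mean, p$costs[[nm]]$mean)

  # the broad/narrow-spectrum sensitivity penalties are valid alternatives
  for (alt in unlist(p$amr$penalty$alternatives))
    expect_s3_class(run_model(apply_penalty(p, alt)), "ce_result")
  expect_error(apply_penalty(p, -1), "nonnegative")
})

test_that("trajectory reduction scales rates and stays in range", {
  traj <- amr_trajectory(2023:2040, rep(0.4, 18), "MRSA")
  expect_equal(reduced_trajectory(traj, 0)$rates, traj$rates)
  expect_equal(reduced_trajectory(traj, 0.25)$rates, rep(0.3, 18))
  expect_true(all(reduced_trajectory(traj, 0.99)$rates >= 0))
  expect_error(reduced_trajectory(traj, 1), "reduction")
  expect_error(reduced_trajectory(traj, -0.1), "reduction")
  expect_error(amr_trajectory(2024:2040, rep(0.4, 17)), "base year")
  expect_error(amr_trajectory(2023:2040, rep(1.4, 18)), "\\[0, 1\\]")
})

test_that("scenario cost streams scale with the trajectory and base cost", {
  p <- default_params()
  flat <- amr_trajectory(2023:2040, rep(0.3, 18), "MRSA")
  s <- scenario_costs(flat, 2.2e12, 0.075, apply_rmf = TRUE, rmf = 0.37)
  expect_equal(s$cost, rep(2.2e12 * 0.37 * 0.075, 18))

  set.seed(3)
  rising <- amr_trajectory(2023:2040, seq(0.2, 0.5, length.out = 18), "PRSP")
  a <- scenario_costs(rising, 5.54e11, 0.075)
  b <- scenario_costs(amr_trajectory(2023:2040, rising$rates, "PRSP"),
                      2 * 5.54e11, 0.075)
  expect_equal(b$cost, 2 * a$cost)  # linearity in the base cost

  # elementwise recomputation oracle
  want <- numeric(18)
  for (i in 1:18)
    want[i] <- 5.54e11 * rising$rates[i] / rising$rates[1] * 0.075
  expect_equal(a$cost, want, tolerance = 1e-9)

  zero_base <- amr_trajectory(2023:2040, c(0, rep(0.3, 17)), "X")
  expect_error(scenario_costs(zero_base, 1e9, 0.075), "base-year")
})

test_that("annual savings follow the closed form and grow with the reduction", {
  flat <- amr_trajectory(2023:2040, rep(0.3, 18), "MRSA")
  usual <- scenario_costs(flat, 2.2e12, 0.075, apply_rmf = TRUE, rmf = 0.37)
  expect_equal(annual_savings(usual, usual), 0)
  anchor <- flat$rates[1]
  for (r in c(0.01, 0.05, 0.10, 0.25)) {
    tested <- scenario_costs(reduced_trajectory(flat, r), 2.2e12, 0.075,
                             apply_rmf = TRUE, rmf = 0.37, anchor_rate = anchor)
    expect_equal(annual_savings(usual, tested), 2.2e12 * 0.37 * 0.075 * r,
                 tolerance = 1e-12)
  }
  savings <- vapply(c(0.01, 0.05, 0.10, 0.25), function(r)
    annual_savings(usual, scenario_costs(reduced_trajectory(flat, r), 2.2e12,
                                         0.075, TRUE, 0.37,
                                         anchor_rate = anchor)), numeric(1))
  expect_true(all(diff(savings) > 0))
  short <- scenario_costs(amr_trajectory(2023:2030, rep(0.3, 8), "M"), 1e9, 0.075)
  expect_error(annual_savings(usual, short), "year ranges")
})

test_that("UK testing costs match the published patient counts and totals", {
  t30 <- uk_testing_cost(115000, 0.30, 94)
  expect_equal(t30$patients, 34500)
  expect_equal(t30$cost, 3243000)
  t50 <- uk_testing_cost(115000, 0.50, 94)
  expect_equal(t50$patients, 57500)
  expect_equal(t50$cost, 5405000)
  expect_equal(uk_testing_cost(0, 0.3, 94)$cost, 0)
  expect_error(uk_testing_cost(115000, 1.3, 94), "fraction")

  expect_equal(uk_net_position(0, 1, 3.243e6), -3.243e6)
  expect_gt(uk_net_position(118e6, 1, 5.405e6), 0)
  expect_equal(uk_net_position(100, 0.5, 10), 40)
  expect_error(uk_net_position(1, 0, 1), "share")
})

test_that("the scenario grid is complete and additive across cost bases", {
  p <- default_params()
  grid <- amr_scenario_grid(p)
  expect_equal(nrow(grid), 2 * 4 * 4 * 3)  # pathogens x reductions x bases x shares
  expect_setequal(unique(grid$basis), c("gdp", "hospital", "productivity", "combined"))
  expect_true(all(grid$annual_savings > 0))
  for (pn in unique(grid$pathogen)) for (r in unique(grid$reduction))
    for (sh in unique(grid$uk_share)) {
      cell <- grid[grid$pathogen == pn & grid$reduction == r & grid$uk_share == sh, ]
      expect_equal(cell$annual_savings[cell$basis == "combined"],
                   cell$annual_savings[cell$basis == "hospital"] +
                     cell$annual_savings[cell$basis == "productivity"],
                   tolerance = 1e-9)
    }
  # pure scaling across UK shares
  full <- grid[grid$uk_share == 1, "annual_savings"]
  half <- grid[grid$uk_share == 0.5, "annual_savings"]
  expect_equal(half, full / 2, tolerance = 1e-12)
})
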