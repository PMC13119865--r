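# Count occurrences of a cost item across a tree.
count_cost_item <- function(node, item) {
  n <- if (!is.null(node$cost_items) && item %in% names(node$cost_items))
    node$cost_items[[item]] else 0
  if (node$kind == "chance")
    n <- n + sum(vapply(node$branches,
                        function(b) count_cost_item(b$node, item), numeric(1)))
  n
}

test_that("arms share topology but differ in antibiotic probability and test cost", {
  p <- default_params()
  int <- build_arm_tree("intervention", p)
  ctr <- build_arm_tree("control", p)
  expect_equal(copdcea:::resolve_prob(int$branches[[1]]$p, p), 0.03)
  expect_equal(copdcea:::resolve_prob(ctr$branches[[1]]$p, p), 0.80)
  expect_equal(count_cost_item(int, "rp21_test"), 1)
  expect_equal(count_cost_item(ctr, "rp21_test"), 0)
})

test_that("forced pathways collapse the severity distribution as expected", {
  p <- default_params()
  # everyone improves at first treatment: all mild, only first-line costs
  p1 <- p
  for (nm in c("improve_initial_ab", "improve_initial_st_ab"))
    p1$probabilities$control[[nm]]$mean <- 1
  exp1 <- rollback(build_arm_tree("control", p1), p1)
  expect_equal(unname(exp1$severity_distribution[["mild"]]), 1)
  first_line <- with(p1, 0.8 * (costs$gp_consultation$mean + costs$prescription$mean +
                                  costs$antibiotic_course$mean) +
                       0.2 * (costs$gp_consultation$mean + costs$prescription$mean +
                                costs$antibiotic_course$mean + costs$steroid_course$mean))
  expect_equal(exp1$expected_cost, first_line)

  # nobody ever improves, everyone is admitted and dies: all mass to dead
  p2 <- p
  for (nm in grep("improve", names(p2$probabilities$control), value = TRUE))
    p2$probabilities$control[[nm]]$mean <- 0
  p2$probabilities$shared$improve_third$mean <- 0
  p2$probabilities$shared$mortality_after_admission$mean <- 1
  for (nm in names(p2$probabilities$hospitalisation))
    p2$probabilities$hospitalisation[[nm]]$mean <- 1
  exp2 <- rollback(build_arm_tree("control", p2), p2)
  expect_equal(unname(exp2$severity_distribution[["dead"]]), 1)
  expect_equal(exp2$expected_payoff, 0)
})

test_that("rollback equals the exhaustive path-enumeration oracle", {
  for (seed in 1:25) {
    p <- random_params(seed)
    for (arm in c("intervention", "control")) {
      tree <- build_arm_tree(arm, p)
      got <- rollback(tree, p)
      want <- oracle_enumerate(tree, p)
      expect_equal(got$expected_cost, want$expected_cost, tolerance = 1e-12)
      expect_equal(got$expected_payoff, want$expected_payoff, tolerance = 1e-12)
      expect_equal(unname(got$severity_distribution), unname(want$severity),
                   tolerance = 1e-12)
      expect_equal(unname(sum(got$severity_distribution)), 1, tolerance = 1e-12)
    }
  }
})

test_that("the test cost enters the incremental cost once, with unit slope", {
  p <- default_params()
  base_int <- rollback(build_arm_tree("intervention", p), p)$expected_cost
  base_ctr <- rollback(build_arm_tree("control", p), p)$expected_cost
  p2 <- set_param(p, "costs.rp21_test", 94 + 250)
  up_int <- rollback(build_arm_tree("intervention", p2), p2)$expected_cost
  up_ctr <- rollback(build_arm_tree("control", p2), p2)$expected_cost
  expect_equal(up_int - base_int, 250)
  expect_equal(up_ctr, base_ctr)
})

test_that("severity classes map onto the entry vector as an outer product", {
  p <- default_params()
  sev <- c(mild = 0.7, moderate = 0.2, severe_full = 0.05,
           severe_partial = 0.04, dead = 0.01)
  entry <- severity_to_entry(sev, p)
  expect_length(entry, 10)
  expect_equal(unname(sum(entry)), 1, tolerance = 1e-12)
  expect_equal(unname(entry["dead"]), 0.01)
  # outer-product oracle under the shipped class map (all non-mild alive
  # classes pool into the moderate severity level)
  mix <- p$tree$stage_mix
  expect_equal(unname(entry[c("mild_II", "mild_III", "mild_IV")]), 0.7 * mix)
  expect_equal(unname(entry[c("moderate_II", "moderate_III", "moderate_IV")]),
               (0.2 + 0.05 + 0.04) * mix)
  expect_equal(unname(entry[c("stable_II", "stable_III", "stable_IV")]),
               rep(0, 3))

  all_mild <- severity_to_entry(c(mild = 1, moderate = 0, severe_full = 0,
                                  severe_partial = 0, dead = 0), p)
  expect_equal(unname(sum(all_mild[c("mild_II", "mild_III", "mild_IV")])), 1)
})

test_that("pathway listing covers the tree and its probabilities sum to one", {
  p <- default_params()
  paths <- tree_pathways(build_arm_tree("intervention", p), p)
  expect_equal(sum(paths$probability), 1, tolerance = 1e-12)
  expect_true(all(paths$class %in% c("mild", "moderate", "severe_full",
                                     "severe_partial", "dead")))
  expect_gt(nrow(paths), 10)
})
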