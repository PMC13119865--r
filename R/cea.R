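# Cost-effectiveness calculus and sensitivity analyses.

#' Incremental cost-effectiveness result
#'
#' Computes incremental cost and QALYs of the intervention over control and
#' classifies the result before any ratio is reported: `dominant` when the
#' intervention is cheaper and more effective, `dominated` when costlier and
#' less effective, `equivalent` when both increments are zero, and a numeric
#' ICER (`icer` classification) when the increments share a sign. Boundary
#' cases with exactly one zero increment are labelled `cost_saving`,
#' `cost_increasing`, `more_effective` or `less_effective` and carry no
#' ratio.
#'
#' @param c1,c0 Lifetime cost, intervention and control (GBP).
#' @param q1,q0 Lifetime QALYs, intervention and control.
#' @return An object of class `ce_result`.
#' @export
icer <- function(c1, c0, q1, q0) {
  stopifnot(is.finite(c1), is.finite(c0), is.finite(q1), is.finite(q0))
  dc <- c1 - c0
  dq <- q1 - q0
  ratio <- NA_real_
  cls <- if (dc == 0 && dq == 0) "equivalent"
  else if (dc < 0 && dq > 0) "dominant"
  else if (dc > 0 && dq < 0) "dominated"
  else if (dq == 0) { if (dc < 0) "cost_saving" else "cost_increasing" }
  else if (dc == 0) { if (dq > 0) "more_effective" else "less_effective" }
  else { ratio <- dc / dq; "icer" }
  structure(list(cost_intervention = c1, cost_control = c0,
                 qaly_intervention = q1, qaly_control = q0,
                 incremental_cost = dc, incremental_qaly = dq,
                 icer = ratio, classification = cls), class = "ce_result")
}

#' @export
print.ce_result <- function(x, ...) {
  cat("<ce_result>\n")
  cat(sprintf("  intervention: £%.2f, %.4f QALYs\n", x$cost_intervention, x$qaly_intervention))
  cat(sprintf("  control:      £%.2f, %.4f QALYs\n", x$cost_control, x$qaly_control))
  cat(sprintf("  increments:   £%.2f, %.4f QALYs\n", x$incremental_cost, x$incremental_qaly))
  if (x$classification == "icer")
    cat(sprintf("  ICER: £%.2f per QALY\n", x$icer))
  else cat(sprintf("  classification: %s\n", x$classification))
  invisible(x)
}

#' Net monetary benefit
#'
#' `lambda * dQALY - dCost`: positive when the intervention is
#' cost-effective at willingness-to-pay `lambda`.
#'
#' @param dc Incremental cost (GBP).
#' @param dq Incremental QALYs.
#' @param lambda Willingness-to-pay threshold (GBP/QALY), nonnegative.
#' @return Net monetary benefit in GBP.
#' @export
nmb <- function(dc, dq, lambda) {
  if (any(lambda < 0)) stop("willingness-to-pay threshold must be nonnegative",
                            call. = FALSE)
  lambda * dq - dc
}

#' Default one-way sensitivity bounds
#'
#' The shipped bound rule: lower `base * (1 - spread)`, upper
#' `base * (1 + spread)` with `spread = 0.392` (a 95% interval under a
#' standard error of 20% of the mean); probabilities and utilities are capped
#' at 1.
#'
#' @param base Base-case value.
#' @param kind `"cost"`, `"probability"` or `"utility"`.
#' @param spread Relative half-width.
#' @return Numeric vector `c(lo, hi)`.
#' @export
dsa_bounds <- function(base, kind = "cost", spread = 0.392) {
  lo <- base * (1 - spread)
  hi <- base * (1 + spread)
  if (kind %in% c("probability", "utility")) hi <- min(hi, 1)
  if (lo < 0) stop("lower bound below 0 after applying the bound rule", call. = FALSE)
  c(lo = lo, hi = hi)
}

#' One-way deterministic sensitivity analysis for a single parameter
#'
#' Re-runs the full two-arm pipeline with the named parameter fixed at its
#' lower and upper bound, all other parameters held at base case.
#'
#' @param params A `copd_params` object.
#' @param path Dotted parameter path, e.g. `"costs.rp21_test"`.
#' @param lo,hi Bounds; defaults from [dsa_bounds()] applied to the base
#'   value.
#' @return List with `lo` and `hi`, each a `ce_result`, plus the bounds used.
#' @export
one_way_dsa <- function(params, path, lo = NULL, hi = NULL) {
  item <- item_at(params, path)
  if (is.null(lo) || is.null(hi)) {
    b <- dsa_bounds(item$mean, kind = item$kind)
    if (is.null(lo)) lo <- b[["lo"]]
    if (is.null(hi)) hi <- b[["hi"]]
  }
  if (lo > item$mean || hi < item$mean)
    stop(sprintf("'%s': bounds [%s, %s] do not bracket the base value %s",
                 path, format(lo), format(hi), format(item$mean)), call. = FALSE)
  list(path = path, base = item$mean, lo_value = lo, hi_value = hi,
       lo = run_model(set_param(params, path, lo)),
       hi = run_model(set_param(params, path, hi)))
}

# The twelve short-run parameters carried through the one-way analysis.
.dsa_default_paths <- c(
  "costs.rp21_test", "costs.ae_without_admission", "costs.copd_hospital_stay",
  "costs.antibiotic_course",
  "utilities.recovery.partially_recovered", "utilities.recovery.fully_recovered",
  "probabilities.control.antibiotics_initial",
  "probabilities.hospitalisation.control_ab",
  "probabilities.hospitalisation.control_st_ab",
  "probabilities.intervention.antibiotics_initial",
  "probabilities.hospitalisation.intervention_ab",
  "probabilities.hospitalisation.intervention_st_ab")

#' One-way sensitivity analysis table
#'
#' Applies the bound rule to each listed parameter and reports the
#' classification of the incremental result at each extreme.
#'
#' @param params A `copd_params` object.
#' @param paths Parameter paths to vary; defaults to the twelve short-run
#'   cost, utility and probability drivers.
#' @return A `data.frame` with one row per parameter: base value, bounds,
#'   and the ICER classification at each bound.
#' @export
dsa_table <- function(params, paths = .dsa_default_paths) {
  rows <- lapply(paths, function(p) {
    res <- one_way_dsa(params, p)
    item <- item_at(params, p)
    data.frame(path = p, label = item$label, base = res$base,
               lo = res$lo_value, hi = res$hi_value,
               classification_lo = res$lo$classification,
               icer_lo = res$lo$icer,
               classification_hi = res$hi$classification,
               icer_hi = res$hi$icer,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Break-even price search
#'
#' Finds, by bisection, the unit price of the test at which the net monetary
#' benefit of the intervention is zero at willingness-to-pay `lambda`. The
#' price enters the intervention arm's cost exactly once at probability one,
#' so NMB is strictly decreasing and linear in it; bisection is retained as
#' the generic, model-agnostic search. An error reports the bracket NMBs if
#' no sign change is found.
#'
#' @param params A `copd_params` object.
#' @param lambda Willingness-to-pay threshold (GBP/QALY).
#' @param price_path Path of the price parameter.
#' @param bracket Search interval in GBP.
#' @param tol Price tolerance (GBP).
#' @return The break-even price in GBP.
#' @export
threshold_price <- function(params, lambda = params$structural$wtp_threshold,
                            price_path = "costs.rp21_test",
                            bracket = c(0.01, 10000), tol = 0.01) {
  f <- function(p) {
    res <- run_model(set_param(params, price_path, p))
    nmb(res$incremental_cost, res$incremental_qaly, lambda)
  }
  lo <- bracket[1]; hi <- bracket[2]
  f_lo <- f(lo); f_hi <- f(hi)
  if (sign(f_lo) == sign(f_hi))
    stop(sprintf("no NMB sign change on bracket [%.2f, %.2f]: NMB = %.2f and %.2f",
                 lo, hi, f_lo, f_hi), call. = FALSE)
  while (hi - lo > tol) {
    mid <- (lo + hi) / 2
    f_mid <- f(mid)
    if (sign(f_mid) == sign(f_lo)) { lo <- mid; f_lo <- f_mid } else hi <- mid
  }
  (lo + hi) / 2
}

# Deterministic per-draw seed substream below 2^31.
psa_substream <- function(master, i) {
  (as.numeric(master) %% 32749) * 65521 + i
}

# Precomputed propagation operator: D = sum_t disc_t A_t over the 9 alive
# states, where A_t maps the entry occupancy to cycle-t occupancy. Discounted
# lifetime cost for any state-cost vector c is then entry %*% D %*% c, which
# makes each probabilistic draw a handful of small matrix products. Valid
# because the transition block is not itself sampled in the PSA.
psa_propagation <- function(params, tm = build_transition_model(params)) {
  sc <- params$structural
  n <- sc$n_cycles
  cl <- sc$cycle_length_years
  disc <- (1 + sc$annual_discount_rate)^(-(seq_len(n) - 0.5) * cl)
  A <- diag(9)
  D <- matrix(0, 9, 9)
  for (t in seq_len(n)) {
    D <- D + disc[t] * A
    age <- floor(sc$start_age + (t - 1) * cl)
    q_ac <- annual_to_cycle_probability(tm$mortality$qx[match(age, tm$mortality$age)], cl)
    q <- 1 - (1 - q_ac) * (1 - tm$q_ds)
    A <- A %*% ((1 - q) * tm$B)
  }
  list(D = D, cycle_length = cl)
}

#' Probabilistic sensitivity analysis
#'
#' Draws every distribution-carrying parameter from its fitted Gamma/Beta
#' specification, re-runs the decision tree and lifetime cohort for both
#' arms, and records the incremental cost and QALY pair for each draw.
#' Parameters shared across arms use the same draw within an iteration. A
#' master seed spawns one deterministic substream per draw, so results are
#' reproducible and independent of draw order.
#'
#' @param params A `copd_params` object.
#' @param n Number of Monte-Carlo draws; defaults to the configured count.
#' @param seed Master seed (integer).
#' @return An object of class `psa_samples`: a list with `draws` (a
#'   `data.frame` of `dcost`, `dqaly`), `n`, and `seed`.
#' @export
run_psa <- function(params, n = params$structural$psa_draws, seed = 1L) {
  n <- as.integer(n)
  if (n < 0) stop("number of draws must be nonnegative", call. = FALSE)
  tm <- build_transition_model(params)
  prop <- psa_propagation(params, tm)
  trees <- list(intervention = build_arm_tree("intervention", params),
                control = build_arm_tree("control", params))
  dcost <- dqaly <- numeric(n)
  for (i in seq_len(n)) {
    set.seed(psa_substream(seed, i))
    sp <- sample_parameters(params)
    sv <- state_values(sp)
    totals <- lapply(trees, function(tree) {
      exp <- rollback(tree, sp)
      entry <- severity_to_entry(exp, sp)
      markov_cost <- as.numeric(entry[1:9] %*% prop$D %*% sv$costs[1:9])
      markov_qaly <- as.numeric(entry[1:9] %*% prop$D %*% sv$utilities[1:9]) *
        prop$cycle_length
      c(cost = exp$expected_cost + markov_cost,
        qaly = exp$expected_payoff * sp$tree$tree_duration_years + markov_qaly)
    })
    dcost[i] <- totals$intervention[["cost"]] - totals$control[["cost"]]
    dqaly[i] <- totals$intervention[["qaly"]] - totals$control[["qaly"]]
  }
  structure(list(draws = data.frame(dcost = dcost, dqaly = dqaly),
                 n = n, seed = seed), class = "psa_samples")
}

#' @export
print.psa_samples <- function(x, ...) {
  cat(sprintf("<psa_samples> %d draws (seed %s)\n", x$n, format(x$seed)))
  if (x$n > 0)
    cat(sprintf("  mean increments: £%.2f, %.4f QALYs; P(dominant) = %.3f\n",
                mean(x$draws$dcost), mean(x$draws$dqaly),
                mean(x$draws$dcost < 0 & x$draws$dqaly > 0)))
  invisible(x)
}

#' Cost-effectiveness acceptability curve
#'
#' At each willingness-to-pay value, the fraction of probabilistic draws
#' with positive net monetary benefit; draws exactly on the NMB boundary
#' count one half.
#'
#' @param samples A `psa_samples` object with at least one draw.
#' @param lambda_grid Willingness-to-pay grid (GBP/QALY); default £0-£50,000
#'   in £1,000 steps.
#' @return A `data.frame` with columns `lambda` and `probability`.
#' @export
ceac <- function(samples, lambda_grid = seq(0, 50000, by = 1000)) {
  if (!inherits(samples, "psa_samples") || samples$n == 0L)
    stop("CEAC requires a nonempty probabilistic sample set", call. = FALSE)
  prob <- vapply(lambda_grid, function(l) {
    b <- nmb(samples$draws$dcost, samples$draws$dqaly, l)
    (sum(b > 0) + 0.5 * sum(b == 0)) / samples$n
  }, numeric(1))
  data.frame(lambda = lambda_grid, probability = prob)
}

#' Export the cost-effectiveness plane (incremental pairs) to CSV
#'
#' @param samples A `psa_samples` object.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_ce_plane_csv <- function(samples, path) {
  utils::write.csv(cbind(draw = seq_len(samples$n), samples$draws),
                   path, row.names = FALSE)
  invisible(path)
}
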