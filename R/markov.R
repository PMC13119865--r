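# Lifetime Markov cohort model: 3 exacerbation severities x 3 GOLD stages
# plus an absorbing dead state, quarterly cycles, age-specific all-cause
# mortality overlaid on disease-specific mortality, half-cycle discounting.

#' The ordered 10-state space of the cohort model
#'
#' Nine alive states — severity (stable, mild, moderate exacerbation) crossed
#' with GOLD stage (II, III, IV) — followed by the absorbing dead state.
#'
#' @return Character vector of 10 state names.
#' @export
state_space <- function() {
  c(as.vector(t(outer(.severities, .stages, paste, sep = "_"))), "dead")
}

#' Convert an annual probability to a per-cycle probability
#'
#' Standard rate conversion under a constant hazard within the year:
#' `1 - (1 - q)^(cycle_length)` with cycle length in years (a quarter by
#' default).
#'
#' @param q_annual Annual probability in `[0, 1]`.
#' @param cycle_length Cycle length in years.
#' @return Per-cycle probability.
#' @export
annual_to_cycle_probability <- function(q_annual, cycle_length = 0.25) {
  if (any(!is.finite(q_annual)) || any(q_annual < 0 | q_annual > 1))
    stop("annual probability outside [0,1]", call. = FALSE)
  1 - (1 - q_annual)^cycle_length
}

# 9x9 alive-to-alive base block: severity transition coupled with one-step
# GOLD progression at the severity-specific intensity (stage IV cannot
# progress further). Row-stochastic by construction.
alive_block <- function(mk) {
  S <- rbind(mk$severity_transitions$stable,
             mk$severity_transitions$mild,
             mk$severity_transitions$moderate)
  prog <- c(mk$stage_progression$stable, mk$stage_progression$mild,
            mk$stage_progression$moderate)
  B <- matrix(0, 9, 9)
  idx <- function(s, g) (s - 1L) * 3L + g
  for (s in 1:3) for (g in 1:3) {
    p_up <- if (g < 3) prog[s] else 0
    for (s2 in 1:3) {
      B[idx(s, g), idx(s2, g)] <- S[s, s2] * (1 - p_up)
      if (g < 3) B[idx(s, g), idx(s2, g + 1)] <- S[s, s2] * p_up
    }
  }
  B
}

# Per-state per-cycle disease-specific death probabilities (length 9).
disease_death_vector <- function(mk) {
  as.vector(t(rbind(mk$disease_death$stable, mk$disease_death$mild,
                    mk$disease_death$moderate)))
}

#' Assemble the transition model from a parameter set
#'
#' Bundles the alive-state transition block, disease-specific mortality, the
#' all-cause mortality table (generated from the configured synthetic
#' Gompertz parameters, or read from a CSV table), and the cycle length.
#'
#' @param params A `copd_params` object.
#' @return A list of class `transition_model`.
#' @export
build_transition_model <- function(params) {
  mk <- params$markov
  mort <- mk$mortality
  tab <- if (identical(mort$type, "gompertz")) {
    generate_mortality_table(mortality_generator_spec(
      baseline = mort$baseline, slope = mort$slope, max_age = mort$max_age))
  } else {
    read_mortality_csv(mort$path)
  }
  structure(list(B = alive_block(mk),
                 q_ds = disease_death_vector(mk),
                 mortality = tab,
                 cycle_length = params$structural$cycle_length_years),
            class = "transition_model")
}

#' Resolve the full 10x10 transition matrix at a given age
#'
#' Combines age-specific all-cause mortality (converted to the cycle length)
#' with per-state disease-specific mortality as independent competing risks,
#' `q = 1 - (1 - q_ac)(1 - q_ds)`, rescales the alive-block rows by survival,
#' and fixes the absorbing dead row. Every row sums to one.
#'
#' @param tm A `transition_model`.
#' @param age Age in years; looked up in the mortality table at `floor(age)`.
#' @return Row-stochastic 10x10 matrix over [state_space()].
#' @export
resolve_matrix <- function(tm, age) {
  a <- floor(age)
  row <- match(a, tm$mortality$age)
  if (is.na(row))
    stop(sprintf("age %d outside mortality table range [%d, %d]",
                 a, min(tm$mortality$age), max(tm$mortality$age)), call. = FALSE)
  q_ac <- annual_to_cycle_probability(tm$mortality$qx[row], tm$cycle_length)
  q <- 1 - (1 - q_ac) * (1 - tm$q_ds)
  M <- matrix(0, 10, 10, dimnames = list(state_space(), state_space()))
  M[1:9, 1:9] <- (1 - q) * tm$B
  M[1:9, 10] <- q
  M[10, 10] <- 1
  if (any(abs(rowSums(M) - 1) > 1e-12))
    stop("internal consistency error: resolved row sums deviate from 1", call. = FALSE)
  M
}

#' Per-state cycle costs and utilities
#'
#' Cycle costs are assembled as unit costs times the per-severity and
#' per-stage resource-use quantities, plus the expected cost of admission
#' events (per-cycle admission probability times the hospital-stay cost).
#' State utilities are the GOLD-stage utilities scaled by the severity
#' multipliers; the dead state carries zero cost and utility.
#'
#' @param params A `copd_params` object.
#' @return List with numeric vectors `costs` and `utilities` (length 10).
#' @export
state_values <- function(params) {
  mk <- params$markov
  cost_of <- function(item) params$costs[[item]]$mean
  sev_cost <- numeric(3)
  for (item in names(mk$resource_use))
    sev_cost <- sev_cost + mk$resource_use[[item]] * cost_of(item)
  stage_cost <- numeric(3)
  for (item in names(mk$stage_resource_use))
    stage_cost <- stage_cost + mk$stage_resource_use[[item]] * cost_of(item)
  adm <- c(mk$admission_prob$stable, mk$admission_prob$mild,
           mk$admission_prob$moderate) * cost_of("copd_hospital_stay")
  umult <- c(mk$utility_multipliers$stable, mk$utility_multipliers$mild,
             mk$utility_multipliers$moderate)
  ugold <- c(params$utilities$gold$stage_II$mean,
             params$utilities$gold$stage_III$mean,
             params$utilities$gold$stage_IV$mean)
  costs <- utilities <- stats::setNames(numeric(10), state_space())
  for (s in 1:3) for (g in 1:3) {
    i <- (s - 1L) * 3L + g
    costs[i] <- sev_cost[s] + stage_cost[g] + adm[s]
    utilities[i] <- ugold[g] * umult[s]
  }
  list(costs = costs, utilities = utilities)
}

#' Discount per-cycle increments with the half-cycle method
#'
#' Each increment accruing in cycle `t` (0-based) is discounted to the cycle
#' midpoint: multiplied by `(1 + rate)^(-(t + 0.5) * cycle_length)`.
#'
#' @param increments Numeric vector of per-cycle values, cycle 0 first.
#' @param annual_rate Annual discount rate, nonnegative.
#' @param cycle_length Cycle length in years.
#' @return The discounted total (scalar).
#' @export
discount_half_cycle <- function(increments, annual_rate, cycle_length = 0.25) {
  if (!is.finite(annual_rate) || annual_rate < 0)
    stop("discount rate must be nonnegative", call. = FALSE)
  t <- seq_along(increments) - 1
  sum(increments * (1 + annual_rate)^(-(t + 0.5) * cycle_length))
}

#' Run the cohort through the lifetime horizon
#'
#' Propagates the entry occupancy through the age-resolved transition
#' matrices for the configured number of cycles, accruing per-cycle cost and
#' QALY increments from start-of-cycle occupancy (QALYs as occupancy times
#' utility times the cycle length) and discounting each increment to its
#' cycle midpoint.
#'
#' @param entry Entry occupancy vector (length 10, sums to 1).
#' @param tm A `transition_model`.
#' @param sc The structural constants block of a parameter set.
#' @param state_costs Per-cycle state cost vector (length 10).
#' @param state_utilities State utility vector (length 10).
#' @return An object of class `cohort_trace`: occupancy matrix
#'   (`n_cycles + 1` rows), per-cycle undiscounted increments, discount
#'   factors, and undiscounted/discounted totals.
#' @export
run_cohort <- function(entry, tm, sc, state_costs, state_utilities) {
  if (length(entry) != 10L || abs(sum(entry) - 1) > 1e-9)
    stop("entry distribution must have length 10 and sum to 1", call. = FALSE)
  n <- sc$n_cycles
  cl <- sc$cycle_length_years
  max_age <- sc$start_age + (n - 1) * cl
  if (floor(max_age) > max(tm$mortality$age))
    stop("mortality table does not cover the model horizon", call. = FALSE)
  occ <- matrix(0, n + 1, 10, dimnames = list(NULL, state_space()))
  occ[1, ] <- entry
  cost_cycle <- qaly_cycle <- numeric(n)
  for (t in seq_len(n)) {
    o <- occ[t, ]
    cost_cycle[t] <- sum(o * state_costs)
    qaly_cycle[t] <- sum(o * state_utilities) * cl
    M <- resolve_matrix(tm, sc$start_age + (t - 1) * cl)
    occ[t + 1, ] <- as.vector(o %*% M)
  }
  disc <- (1 + sc$annual_discount_rate)^(-(seq_len(n) - 0.5) * cl)
  structure(list(
    occupancy = occ,
    cost_cycle = cost_cycle, qaly_cycle = qaly_cycle,
    discount_factors = disc,
    cost_total_undiscounted = sum(cost_cycle),
    qaly_total_undiscounted = sum(qaly_cycle),
    cost_total = sum(cost_cycle * disc),
    qaly_total = sum(qaly_cycle * disc)), class = "cohort_trace")
}

#' @export
print.cohort_trace <- function(x, ...) {
  cat(sprintf("<cohort_trace> %d cycles; discounted cost £%.2f, QALYs %.4f\n",
              length(x$cost_cycle), x$cost_total, x$qaly_total))
  invisible(x)
}

#' Export a cohort trace to CSV
#'
#' One row per cycle with state occupancies, undiscounted increments and the
#' discount factor.
#'
#' @param trace A `cohort_trace`.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_trace_csv <- function(trace, path) {
  n <- length(trace$cost_cycle)
  df <- data.frame(cycle = 0:(n - 1), trace$occupancy[seq_len(n), , drop = FALSE],
                   cost = trace$cost_cycle, qaly = trace$qaly_cycle,
                   discount = trace$discount_factors, check.names = FALSE)
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' Run one arm end to end: tree, entry distribution, lifetime cohort
#'
#' Rolls back the arm's decision tree (undiscounted; episode under one
#' year), seeds the Markov model with the resulting severity distribution,
#' and runs the lifetime cohort. Total cost is tree plus discounted Markov
#' cost; total QALYs are the tree payoff credited for the configured episode
#' duration plus discounted Markov QALYs.
#'
#' @param params A `copd_params` object.
#' @param arm `"intervention"` or `"control"`.
#' @param tm Optional prebuilt `transition_model` (shared across arms).
#' @param sv Optional prebuilt [state_values()] list.
#' @return List with the tree expectation, trace, and `total_cost`,
#'   `total_qaly`.
#' @export
run_arm <- function(params, arm, tm = NULL, sv = NULL) {
  if (is.null(tm)) tm <- build_transition_model(params)
  if (is.null(sv)) sv <- state_values(params)
  tree <- build_arm_tree(arm, params)
  exp <- rollback(tree, params)
  entry <- severity_to_entry(exp, params)
  trace <- run_cohort(entry, tm, params$structural, sv$costs, sv$utilities)
  list(arm = arm, tree = exp, trace = trace,
       total_cost = exp$expected_cost + trace$cost_total,
       total_qaly = exp$expected_payoff * params$tree$tree_duration_years +
         trace$qaly_total)
}

#' Per-arm lifetime totals feeding the cost-effectiveness calculus
#'
#' @param intervention_run,control_run Results of [run_arm()].
#' @return List with the four totals: per-arm lifetime cost and QALYs.
#' @export
arm_totals <- function(intervention_run, control_run) {
  list(cost_intervention = intervention_run$total_cost,
       cost_control = control_run$total_cost,
       qaly_intervention = intervention_run$total_qaly,
       qaly_control = control_run$total_qaly)
}

#' Run the full two-arm model
#'
#' @param params A `copd_params` object.
#' @return A `ce_result` (see [icer()]) with the two [run_arm()] results
#'   attached as attribute `"runs"`.
#' @export
run_model <- function(params) {
  tm <- build_transition_model(params)
  sv <- state_values(params)
  int <- run_arm(params, "intervention", tm, sv)
  ctr <- run_arm(params, "control", tm, sv)
  res <- icer(int$total_cost, ctr$total_cost, int$total_qaly, ctr$total_qaly)
  attr(res, "runs") <- list(intervention = int, control = ctr)
  res
}
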