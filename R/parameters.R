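#' Path to the shipped default model configuration
#'
#' @return Path to the YAML configuration installed with the package.
#' @export
default_config_path <- function() {
  system.file("extdata", "default_config.yaml", package = "copdcea",
              mustWork = TRUE)
}

# --- schema -----------------------------------------------------------------

.cost_names <- c(
  "prescription", "phone_call", "patient_contact", "home_visit",
  "gp_consultation", "ae_without_admission", "copd_hospital_stay",
  "community_nurse_followup", "outpatient_followup", "rp21_test",
  "antibiotic_course", "steroid_course", "alternative_antibiotics",
  "secondary_care_followup", "primary_care_followup",
  "secondary_care_spirometry", "primary_care_spirometry",
  "influenza_vaccination", "oxygen_therapy")

.recovery_names <- c("dead", "partially_recovered", "fully_recovered")
.gold_names <- c("stage_II", "stage_III", "stage_IV")

.prob_arm_names <- c("antibiotics_initial", "improve_initial_ab",
                     "improve_initial_st_ab", "improve_second_ab",
                     "improve_second_ab_ae", "improve_second_st_ab")
.prob_shared_names <- c("mortality_after_admission", "improve_third")
.prob_hosp_names <- c("control_ab", "control_st_ab",
                      "intervention_ab", "intervention_st_ab")

.structural_names <- c("annual_discount_rate", "cycle_length_years",
                       "start_age", "end_age", "cohort_size", "wtp_threshold",
                       "psa_draws", "test_sensitivity", "beta_policy")

.severities <- c("stable", "mild", "moderate")
.stages <- c("II", "III", "IV")

cfg_error <- function(path, msg) {
  stop(sprintf("config error at '%s': %s", path, msg), call. = FALSE)
}

check_names <- function(x, required, path, optional = character()) {
  if (!is.list(x)) cfg_error(path, "expected a mapping")
  nm <- names(x)
  missing <- setdiff(required, nm)
  if (length(missing))
    cfg_error(path, paste("missing required key(s):", paste(missing, collapse = ", ")))
  unknown <- setdiff(nm, c(required, optional))
  if (length(unknown))
    cfg_error(path, paste("unknown key(s):", paste(unknown, collapse = ", ")))
  invisible(x)
}

check_number <- function(x, path, lo = -Inf, hi = Inf, strict_lo = FALSE) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x))
    cfg_error(path, "expected a single finite number")
  if (x < lo || x > hi || (strict_lo && x <= lo))
    cfg_error(path, sprintf("value %s outside admissible range [%s, %s]%s",
                            format(x), format(lo), format(hi),
                            if (strict_lo) " (lower bound strict)" else ""))
  x
}

# --- item constructors ------------------------------------------------------

make_cost_item <- function(name, raw) {
  check_names(raw, c("label", "mean", "se"), paste0("costs.", name))
  mean <- check_number(raw$mean, paste0("costs.", name, ".mean"), lo = 0, strict_lo = TRUE)
  se <- check_number(raw$se, paste0("costs.", name, ".se"), lo = 0, strict_lo = TRUE)
  list(name = name, label = raw$label, mean = mean, se = se,
       dist = "gamma", kind = "cost",
       spec = gamma_from_moments(mean, se, name = name))
}

make_utility_item <- function(name, raw, policy) {
  path <- paste0("utilities.", name)
  check_names(raw, c("label", "value", "se", "dist"), path)
  if (identical(raw$dist, "fixed")) {
    value <- check_number(raw$value, paste0(path, ".value"), lo = 0, hi = 1)
    return(list(name = name, label = raw$label, mean = value, se = 0,
                dist = "fixed", kind = "utility", spec = NULL))
  }
  if (!identical(raw$dist, "beta")) cfg_error(path, "dist must be 'beta' or 'fixed'")
  value <- check_number(raw$value, paste0(path, ".value"), lo = 0, hi = 1, strict_lo = TRUE)
  if (value > 1) cfg_error(path, "utility above 1")
  se <- check_number(raw$se, paste0(path, ".se"), lo = 0, strict_lo = TRUE)
  list(name = name, label = raw$label, mean = value, se = se,
       dist = "beta", kind = "utility",
       spec = beta_from_moments(value, se, name = name, policy = policy))
}

make_prob_item <- function(name, raw, policy) {
  path <- paste0("probabilities.", name)
  check_names(raw, c("label", "mean", "se"), path)
  mean <- check_number(raw$mean, paste0(path, ".mean"), lo = 0, hi = 1)
  se <- check_number(raw$se, paste0(path, ".se"), lo = 0)
  spec <- if (mean > 0 && mean < 1 && se > 0)
    beta_from_moments(mean, se, name = name, policy = policy) else NULL
  list(name = name, label = raw$label, mean = mean, se = se,
       dist = if (is.null(spec)) "fixed" else "beta", kind = "probability",
       spec = spec)
}

# --- markov / tree / amr block validation -----------------------------------

validate_markov_block <- function(mk) {
  check_names(mk, c("provenance", "severity_transitions", "stage_progression",
                    "disease_death", "admission_prob", "utility_multipliers",
                    "resource_use", "stage_resource_use", "mortality"),
              "markov")
  check_names(mk$severity_transitions, .severities, "markov.severity_transitions")
  for (s in .severities) {
    row <- mk$severity_transitions[[s]]
    if (!is.numeric(row) || length(row) != 3L)
      cfg_error(paste0("markov.severity_transitions.", s), "expected 3 numbers")
    if (any(row < 0 | row > 1))
      cfg_error(paste0("markov.severity_transitions.", s), "entries outside [0,1]")
    if (abs(sum(row) - 1) > 1e-9)
      cfg_error(paste0("markov.severity_transitions.", s),
                sprintf("row sums to %.12f, not 1", sum(row)))
  }
  check_names(mk$stage_progression, .severities, "markov.stage_progression")
  check_names(mk$disease_death, .severities, "markov.disease_death")
  check_names(mk$admission_prob, .severities, "markov.admission_prob")
  check_names(mk$utility_multipliers, .severities, "markov.utility_multipliers")
  for (s in .severities) {
    check_number(mk$stage_progression[[s]], paste0("markov.stage_progression.", s), 0, 1)
    check_number(mk$admission_prob[[s]], paste0("markov.admission_prob.", s), 0, 1)
    check_number(mk$utility_multipliers[[s]], paste0("markov.utility_multipliers.", s), 0, 1)
    dd <- mk$disease_death[[s]]
    if (!is.numeric(dd) || length(dd) != 3L || any(dd < 0 | dd > 1))
      cfg_error(paste0("markov.disease_death.", s), "expected 3 probabilities in [0,1]")
  }
  for (blk in c("resource_use", "stage_resource_use")) {
    ru <- mk[[blk]]
    if (!is.list(ru) || is.null(names(ru)))
      cfg_error(paste0("markov.", blk), "expected a mapping of cost items to quantities")
    bad <- setdiff(names(ru), .cost_names)
    if (length(bad))
      cfg_error(paste0("markov.", blk), paste("unknown cost item(s):", paste(bad, collapse = ", ")))
    for (item in names(ru)) {
      q <- ru[[item]]
      if (!is.numeric(q) || length(q) != 3L || any(q < 0))
        cfg_error(paste0("markov.", blk, ".", item), "expected 3 nonnegative quantities")
    }
  }
  mort <- mk$mortality
  if (identical(mort$type, "gompertz")) {
    check_names(mort, c("type", "baseline", "slope", "max_age"), "markov.mortality")
    check_number(mort$baseline, "markov.mortality.baseline", lo = 0, strict_lo = TRUE)
    check_number(mort$slope, "markov.mortality.slope", lo = 0)
    check_number(mort$max_age, "markov.mortality.max_age", lo = 1)
  } else if (identical(mort$type, "table")) {
    check_names(mort, c("type", "path"), "markov.mortality")
  } else cfg_error("markov.mortality.type", "must be 'gompertz' or 'table'")
  mk
}

validate_tree_block <- function(tr) {
  check_names(tr, c("second_ab_share", "p_full_given_survival",
                    "tree_duration_years", "viral_alt_antibiotics",
                    "stage_mix", "class_state_map", "bundles"), "tree")
  check_number(tr$second_ab_share, "tree.second_ab_share", 0, 1)
  check_number(tr$p_full_given_survival, "tree.p_full_given_survival", 0, 1)
  check_number(tr$tree_duration_years, "tree.tree_duration_years", 0, 1)
  if (!is.logical(tr$viral_alt_antibiotics))
    cfg_error("tree.viral_alt_antibiotics", "expected true/false")
  mix <- tr$stage_mix
  if (!is.numeric(mix) || length(mix) != 3L || any(mix < 0))
    cfg_error("tree.stage_mix", "expected 3 nonnegative numbers")
  if (abs(sum(mix) - 1) > 1e-9)
    cfg_error("tree.stage_mix", sprintf("sums to %.12f, not 1", sum(mix)))
  csm <- tr$class_state_map
  check_names(csm, c("mild", "moderate", "severe_full", "severe_partial"),
              "tree.class_state_map")
  for (cls in names(csm))
    if (!csm[[cls]] %in% .severities)
      cfg_error(paste0("tree.class_state_map.", cls),
                "must map to one of stable/mild/moderate")
  if (!is.list(tr$bundles) || is.null(names(tr$bundles)))
    cfg_error("tree.bundles", "expected a mapping of bundle names")
  for (b in names(tr$bundles)) {
    bundle <- tr$bundles[[b]]
    bad <- setdiff(names(bundle), .cost_names)
    if (length(bad))
      cfg_error(paste0("tree.bundles.", b),
                paste("unknown cost item(s):", paste(bad, collapse = ", ")))
    for (item in names(bundle))
      check_number(bundle[[item]], paste0("tree.bundles.", b, ".", item), lo = 0)
  }
  tr
}

validate_amr_block <- function(am) {
  check_names(am, c("exchange_rate_gbp_per_usd", "rmf", "copd_prescription_share",
                    "penalty", "annual_costs_gbp", "reductions", "uk_shares",
                    "uk", "trajectories"), "amr")
  check_number(am$exchange_rate_gbp_per_usd, "amr.exchange_rate_gbp_per_usd",
               lo = 0, strict_lo = TRUE)
  check_number(am$rmf, "amr.rmf", lo = 0, hi = 1, strict_lo = TRUE)
  check_number(am$copd_prescription_share, "amr.copd_prescription_share",
               lo = 0, hi = 1, strict_lo = TRUE)
  check_names(am$penalty, c("total_gdp_loss_usd", "horizon_years",
                            "ddd_per_1000_per_day", "world_population",
                            "course_length_days", "canonical_usd_per_prescription",
                            "mode", "alternatives"), "amr.penalty")
  if (!am$penalty$mode %in% c("canonical", "computed"))
    cfg_error("amr.penalty.mode", "must be 'canonical' or 'computed'")
  check_names(am$annual_costs_gbp, c("gdp", "hospital", "productivity"),
              "amr.annual_costs_gbp")
  if (any(am$reductions <= 0 | am$reductions >= 1))
    cfg_error("amr.reductions", "reductions must lie in (0,1)")
  if (any(am$uk_shares <= 0 | am$uk_shares > 1))
    cfg_error("amr.uk_shares", "shares must lie in (0,1]")
  check_names(am$uk, c("annual_diagnoses", "tested_fractions", "unit_cost"), "amr.uk")
  for (p in names(am$trajectories))
    check_names(am$trajectories[[p]],
                c("pathogen", "start_rate", "trend", "trend_type", "noise_sd",
                  "seed", "start_year", "end_year"),
                paste0("amr.trajectories.", p))
  am
}

# --- loader -----------------------------------------------------------------

#' Load and validate a model configuration
#'
#' Reads a YAML configuration, checks it against the documented schema
#' (unknown keys are rejected, every published input must be present, ranges
#' are enforced), fits Gamma/Beta sampling distributions to every cost,
#' utility and probability from its mean and standard error, and enforces the
#' structural identity that the intervention-arm antibiotic probability
#' equals one minus the test sensitivity.
#'
#' @param path Path to a YAML configuration; defaults to the shipped
#'   configuration carrying the published point estimates.
#' @return A validated parameter set of class `copd_params`.
#' @export
load_config <- function(path = default_config_path()) {
  if (!file.exists(path)) stop("config file not found: ", path, call. = FALSE)
  raw <- yaml::read_yaml(path)
  check_names(raw, c("costs", "utilities", "probabilities", "structural",
                     "tree", "markov", "amr"), "<root>")

  st <- check_names(raw$structural, .structural_names, "structural")
  check_number(st$annual_discount_rate, "structural.annual_discount_rate", lo = 0)
  check_number(st$cycle_length_years, "structural.cycle_length_years", lo = 0, strict_lo = TRUE)
  check_number(st$test_sensitivity, "structural.test_sensitivity", lo = 0, hi = 1)
  for (k in c("start_age", "end_age", "cohort_size", "wtp_threshold", "psa_draws"))
    check_number(st[[k]], paste0("structural.", k), lo = 0)
  if (st$end_age <= st$start_age)
    cfg_error("structural.end_age", "must exceed start_age")
  if (!st$beta_policy %in% c("clamp", "raise"))
    cfg_error("structural.beta_policy", "must be 'clamp' or 'raise'")
  st$n_cycles <- as.integer(round((st$end_age - st$start_age) / st$cycle_length_years))
  policy <- st$beta_policy

  check_names(raw$costs, .cost_names, "costs")
  costs <- lapply(.cost_names, function(nm) make_cost_item(nm, raw$costs[[nm]]))
  names(costs) <- .cost_names

  check_names(raw$utilities, c("recovery", "gold"), "utilities")
  check_names(raw$utilities$recovery, .recovery_names, "utilities.recovery")
  check_names(raw$utilities$gold, .gold_names, "utilities.gold")
  recovery <- lapply(.recovery_names, function(nm)
    make_utility_item(nm, raw$utilities$recovery[[nm]], policy))
  names(recovery) <- .recovery_names
  if (recovery$dead$mean != 0)
    cfg_error("utilities.recovery.dead", "dead-state utility must be exactly 0")
  gold <- lapply(.gold_names, function(nm)
    make_utility_item(nm, raw$utilities$gold[[nm]], policy))
  names(gold) <- .gold_names

  check_names(raw$probabilities,
              c("intervention", "control", "shared", "hospitalisation"),
              "probabilities")
  check_names(raw$probabilities$intervention, .prob_arm_names, "probabilities.intervention")
  check_names(raw$probabilities$control, .prob_arm_names, "probabilities.control")
  check_names(raw$probabilities$shared, .prob_shared_names, "probabilities.shared")
  check_names(raw$probabilities$hospitalisation, .prob_hosp_names,
              "probabilities.hospitalisation")
  probs <- list(
    intervention = lapply(.prob_arm_names, function(nm)
      make_prob_item(paste0("intervention.", nm), raw$probabilities$intervention[[nm]], policy)),
    control = lapply(.prob_arm_names, function(nm)
      make_prob_item(paste0("control.", nm), raw$probabilities$control[[nm]], policy)),
    shared = lapply(.prob_shared_names, function(nm)
      make_prob_item(paste0("shared.", nm), raw$probabilities$shared[[nm]], policy)),
    hospitalisation = lapply(.prob_hosp_names, function(nm)
      make_prob_item(paste0("hospitalisation.", nm), raw$probabilities$hospitalisation[[nm]], policy)))
  names(probs$intervention) <- .prob_arm_names
  names(probs$control) <- .prob_arm_names
  names(probs$shared) <- .prob_shared_names
  names(probs$hospitalisation) <- .prob_hosp_names

  # Structural identity: antibiotics in the tested arm arise only from
  # false-negative panel results.
  implied <- 1 - st$test_sensitivity
  if (abs(probs$intervention$antibiotics_initial$mean - implied) > 1e-9)
    cfg_error("probabilities.intervention.antibiotics_initial",
              sprintf("mean %.6g conflicts with 1 - test_sensitivity = %.6g",
                      probs$intervention$antibiotics_initial$mean, implied))

  params <- structure(list(
    costs = costs,
    utilities = list(recovery = recovery, gold = gold),
    probabilities = probs,
    structural = st,
    tree = validate_tree_block(raw$tree),
    markov = validate_markov_block(raw$markov),
    amr = validate_amr_block(raw$amr),
    source = path), class = "copd_params")
  params
}

#' @export
print.copd_params <- function(x, ...) {
  cat("<copd_params> cost-utility model parameter set\n")
  cat(sprintf("  %d cost items, %d utilities, %d pathway probabilities\n",
              length(x$costs),
              length(x$utilities$recovery) + length(x$utilities$gold),
              sum(lengths(x$probabilities))))
  cat(sprintf("  horizon: %d cycles of %.2f y from age %d; discount %.1f%%/y; WTP £%s/QALY\n",
              x$structural$n_cycles, x$structural$cycle_length_years,
              x$structural$start_age, 100 * x$structural$annual_discount_rate,
              format(x$structural$wtp_threshold, big.mark = ",")))
  invisible(x)
}

# --- flat item access (used by DSA, PSA, audit export) ----------------------

# Named list of every distribution-carrying item, keyed by dotted path.
flat_items <- function(params) {
  out <- list()
  for (nm in names(params$costs)) out[[paste0("costs.", nm)]] <- params$costs[[nm]]
  for (nm in names(params$utilities$recovery))
    out[[paste0("utilities.recovery.", nm)]] <- params$utilities$recovery[[nm]]
  for (nm in names(params$utilities$gold))
    out[[paste0("utilities.gold.", nm)]] <- params$utilities$gold[[nm]]
  for (grp in names(params$probabilities))
    for (nm in names(params$probabilities[[grp]]))
      out[[paste0("probabilities.", grp, ".", nm)]] <- params$probabilities[[grp]][[nm]]
  out
}

item_at <- function(params, path) {
  keys <- strsplit(path, ".", fixed = TRUE)[[1]]
  node <- params
  for (k in keys) {
    if (is.null(node[[k]])) stop("unknown parameter path: ", path, call. = FALSE)
    node <- node[[k]]
  }
  node
}

#' Read a single parameter value by dotted path
#'
#' @param params A `copd_params` object.
#' @param path Dotted path, e.g. `"costs.rp21_test"`.
#' @return The item's mean value.
#' @export
get_param <- function(params, path) item_at(params, path)$mean

#' Replace a single parameter value by dotted path
#'
#' Used by the deterministic sensitivity analysis and the break-even price
#' search. The item's mean is replaced; its sampling distribution is refitted
#' from the new mean when the value admits one, and dropped otherwise (a
#' probability pushed to a boundary has no Beta representation, which is
#' irrelevant for deterministic re-runs).
#'
#' @param params A `copd_params` object.
#' @param path Dotted path, e.g. `"costs.rp21_test"`.
#' @param value New mean value.
#' @return The modified parameter set.
#' @export
set_param <- function(params, path, value) {
  keys <- strsplit(path, ".", fixed = TRUE)[[1]]
  item <- item_at(params, path)
  if (item$kind == "cost" && value <= 0)
    stop(sprintf("'%s': cost must be positive", path), call. = FALSE)
  if (item$kind %in% c("probability", "utility") && (value < 0 || value > 1))
    stop(sprintf("'%s': value %s outside [0,1]", path, format(value)), call. = FALSE)
  item$mean <- value
  item$spec <- tryCatch({
    if (item$dist == "gamma") gamma_from_moments(value, item$se, name = path)
    else if (item$dist == "beta" && value > 0 && value < 1 && item$se > 0)
      suppressWarnings(beta_from_moments(value, item$se, name = path,
                                         policy = "clamp"))
    else NULL
  }, error = function(e) NULL)
  expr <- Reduce(function(acc, k) call("[[", acc, k), keys, quote(params))
  eval(call("<-", expr, quote(item)))
  params
}

#' Flatten the resolved parameter set to a data frame
#'
#' One row per cost, utility and probability item, carrying the dotted path,
#' label, mean, standard error, distribution family and fitted distribution
#' parameters — the audit export of the resolved inputs.
#'
#' @param params A `copd_params` object.
#' @return A `data.frame`.
#' @export
parameters_table <- function(params) {
  items <- flat_items(params)
  rows <- lapply(names(items), function(path) {
    it <- items[[path]]
    p1 <- p2 <- NA_real_
    if (inherits(it$spec, "gamma_spec")) { p1 <- it$spec$shape; p2 <- it$spec$scale }
    if (inherits(it$spec, "beta_spec")) { p1 <- it$spec$alpha; p2 <- it$spec$beta }
    data.frame(path = path, label = it$label, kind = it$kind,
               mean = it$mean, se = it$se, dist = it$dist,
               par1 = p1, par2 = p2, stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Write the resolved parameter set to CSV
#'
#' @param params A `copd_params` object.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_parameters_csv <- function(params, path) {
  utils::write.csv(parameters_table(params), path, row.names = FALSE)
  invisible(path)
}

# Paths of items eligible for probabilistic sampling (se > 0, non-fixed).
psa_parameter_paths <- function(params) {
  items <- flat_items(params)
  names(items)[vapply(items, function(it) !is.null(it$spec), logical(1))]
}

# One probabilistic draw: every distribution-carrying item's mean replaced by
# a random variate from its fitted spec, using the current RNG stream. Shared
# items are drawn once, so both arms see the same value within a draw.
sample_parameters <- function(params) {
  for (nm in names(params$costs)) {
    it <- params$costs[[nm]]
    if (!is.null(it$spec)) params$costs[[nm]]$mean <- draw_spec(it$spec)
  }
  for (nm in names(params$utilities$recovery)) {
    it <- params$utilities$recovery[[nm]]
    if (!is.null(it$spec)) params$utilities$recovery[[nm]]$mean <- draw_spec(it$spec)
  }
  for (nm in names(params$utilities$gold)) {
    it <- params$utilities$gold[[nm]]
    if (!is.null(it$spec)) params$utilities$gold[[nm]]$mean <- draw_spec(it$spec)
  }
  for (grp in names(params$probabilities))
    for (nm in names(params$probabilities[[grp]])) {
      it <- params$probabilities[[grp]][[nm]]
      if (!is.null(it$spec)) params$probabilities[[grp]][[nm]]$mean <- draw_spec(it$spec)
    }
  params
}
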