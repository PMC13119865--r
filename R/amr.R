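# Antimicrobial-resistance cost attribution.
#
# Approach 1: a per-prescription resistance penalty derived from the
# projected global GDP loss of resistance, spread over annual prescription
# volume, converted to GBP and scaled by the resistance modulating factor
# (RMf, the fraction of resistance cost attributable to human antibiotic
# consumption), then added to the antibiotic cost items of the model.
#
# Approach 2: annual resistance costs scaled along pathogen resistance-rate
# trajectories, compared between a usual-care scenario and a reduced-rate
# testing scenario, yielding annual cost savings under reduction, cost-basis
# and UK-share grids.

# Truncate (not round) to n significant figures; used for display parity
# with headline figures quoted to two significant figures.
signif_trunc <- function(x, digits = 2) {
  if (x == 0) return(0)
  e <- floor(log10(abs(x))) - digits + 1
  trunc(x / 10^e) * 10^e
}

#' Annualise a multi-year total
#'
#' @param total Total loss (USD) over the horizon.
#' @param horizon Horizon in years, positive.
#' @return `total / horizon` (exact; see [penalty_chain()] for the
#'   two-significant-figure display value).
#' @export
annualise_total <- function(total, horizon) {
  if (!is.finite(horizon) || horizon <= 0)
    stop("horizon must be positive", call. = FALSE)
  total / horizon
}

#' Annual antibiotic consumption in defined daily doses
#'
#' @param rate Consumption in DDD per 1000 population per day.
#' @param population Population count.
#' @param days Days per year.
#' @return DDD per year: `rate / 1000 * population * days`.
#' @export
annual_ddd <- function(rate, population, days = 365) {
  rate / 1000 * population * days
}

#' Annual prescription count from DDD volume
#'
#' @param ddd_per_year Annual DDD volume.
#' @param course_days Days per standard prescription, positive.
#' @return Prescriptions per year.
#' @export
prescriptions_per_year <- function(ddd_per_year, course_days) {
  if (!is.finite(course_days) || course_days <= 0)
    stop("course length must be positive", call. = FALSE)
  ddd_per_year / course_days
}

#' Build the per-prescription resistance penalty chain
#'
#' Carries every step of the derivation — annualised GDP loss, annual DDD
#' volume, prescription count, USD cost per prescription, GBP conversion and
#' RMf scaling — in both a canonical mode (the published per-prescription
#' figure) and a computed mode (full-chain arithmetic from the upstream
#' constants, using the two-significant-figure annual loss for display
#' parity). A divergence flag marks the disagreement between the two.
#'
#' @param amr The `amr` block of a parameter set (see [load_config()]).
#' @return A list of class `penalty_chain`.
#' @export
penalty_chain <- function(amr) {
  pen <- amr$penalty
  if (amr$rmf <= 0 || amr$rmf > 1)
    stop("RMf must lie in (0, 1]", call. = FALSE)
  annual_usd <- annualise_total(pen$total_gdp_loss_usd, pen$horizon_years)
  annual_usd_display <- signif_trunc(annual_usd, 2)
  ddd <- annual_ddd(pen$ddd_per_1000_per_day, pen$world_population)
  presc <- prescriptions_per_year(ddd, pen$course_length_days)
  usd_computed <- annual_usd_display / presc
  usd_canonical <- pen$canonical_usd_per_prescription
  fx <- amr$exchange_rate_gbp_per_usd
  chain <- list(
    total_gdp_loss_usd = pen$total_gdp_loss_usd,
    horizon_years = pen$horizon_years,
    annual_usd = annual_usd,
    annual_usd_display = annual_usd_display,
    annual_ddd = ddd,
    prescriptions_per_year = presc,
    exchange_rate = fx,
    rmf = amr$rmf,
    usd_per_prescription = c(canonical = usd_canonical, computed = usd_computed),
    gbp_per_prescription = c(canonical = usd_canonical * fx,
                             computed = usd_computed * fx),
    penalty_gbp = c(canonical = usd_canonical * fx * amr$rmf,
                    computed = usd_computed * fx * amr$rmf),
    divergence = abs(usd_canonical - usd_computed) > 1e-6,
    mode = pen$mode)
  class(chain) <- "penalty_chain"
  chain
}

#' @export
print.penalty_chain <- function(x, ...) {
  cat("<penalty_chain>\n")
  cat(sprintf("  annual loss: $%.4g (displayed $%.2g); prescriptions/year: %.4g\n",
              x$annual_usd, x$annual_usd_display, x$prescriptions_per_year))
  cat(sprintf("  per prescription: canonical $%.2f -> £%.2f -> £%.2f (RMf %.2f)\n",
              x$usd_per_prescription[["canonical"]],
              x$gbp_per_prescription[["canonical"]],
              x$penalty_gbp[["canonical"]], x$rmf))
  cat(sprintf("  computed chain:   $%.2f -> £%.2f -> £%.2f%s\n",
              x$usd_per_prescription[["computed"]],
              x$gbp_per_prescription[["computed"]],
              x$penalty_gbp[["computed"]],
              if (x$divergence) "  [diverges from canonical]" else ""))
  invisible(x)
}

#' Per-prescription resistance penalty in GBP
#'
#' @param chain A `penalty_chain`.
#' @param mode `"canonical"` (default, published figures) or `"computed"`
#'   (full-chain arithmetic); `NULL` uses the configured mode.
#' @return Penalty in GBP per prescription.
#' @export
penalty_per_prescription <- function(chain, mode = NULL) {
  mode <- mode %||% chain$mode
  chain$penalty_gbp[[match.arg(mode, c("canonical", "computed"))]]
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Add a resistance penalty to antibiotic cost items
#'
#' Every antibiotic-course cost item (`antibiotic_course`,
#' `alternative_antibiotics`) is incremented by the penalty; all other
#' parameters are untouched. Gamma specifications are refitted from the new
#' mean with the unchanged standard error.
#'
#' @param params A `copd_params` object.
#' @param penalty Penalty in GBP per course, nonnegative.
#' @return The modified parameter set.
#' @export
apply_penalty <- function(params, penalty) {
  if (!is.finite(penalty) || penalty < 0)
    stop("penalty must be nonnegative", call. = FALSE)
  for (item in c("antibiotic_course", "alternative_antibiotics"))
    params <- set_param(params, paste0("costs.", item),
                        params$costs[[item]]$mean + penalty)
  params
}

# --- Approach 2 -------------------------------------------------------------

#' Construct a resistance-rate trajectory
#'
#' @param years Integer years (must include the 2023 base year).
#' @param rates Resistance proportions in `[0, 1]`, one per year.
#' @param pathogen Pathogen label (e.g. `"MRSA"`, `"PRSP"`).
#' @param base_year Anchoring year for cost scaling.
#' @return An object of class `amr_trajectory`.
#' @export
amr_trajectory <- function(years, rates, pathogen = "AMR", base_year = 2023) {
  if (length(years) != length(rates))
    stop("years and rates must have equal length", call. = FALSE)
  if (any(rates < 0 | rates > 1))
    stop("resistance rates must lie in [0, 1]", call. = FALSE)
  if (!base_year %in% years)
    stop(sprintf("trajectory must include the %d base year", base_year), call. = FALSE)
  structure(list(pathogen = pathogen, years = as.integer(years),
                 rates = as.numeric(rates), base_year = as.integer(base_year)),
            class = "amr_trajectory")
}

#' @export
print.amr_trajectory <- function(x, ...) {
  cat(sprintf("<amr_trajectory> %s, %d-%d; base-year rate %.4f, final %.4f\n",
              x$pathogen, min(x$years), max(x$years),
              x$rates[x$years == x$base_year], x$rates[length(x$rates)]))
  invisible(x)
}

#' Apply a constant relative reduction to a trajectory
#'
#' The testing scenario: every yearly rate scaled by `1 - reduction`,
#' reflecting a time-constant effect of reduced antibiotic prescribing on
#' resistance levels.
#'
#' @param traj An `amr_trajectory`.
#' @param reduction Fraction in `[0, 1)`.
#' @return The reduced `amr_trajectory`.
#' @export
reduced_trajectory <- function(traj, reduction) {
  if (!is.finite(reduction) || reduction < 0 || reduction >= 1)
    stop("reduction must lie in [0, 1)", call. = FALSE)
  traj$rates <- traj$rates * (1 - reduction)
  traj
}

#' Yearly resistance cost stream under a scenario
#'
#' Costs anchored at the base year scale in proportion to the resistance
#' rate: `cost_t = base_annual_cost * rate_t / anchor_rate * rmf_or_1 *
#' copd_share`. The anchor is the usual-care base-year rate — the rate at
#' which the base-year cost is incurred — so a reduced-rate testing scenario
#' must be anchored to the unreduced trajectory's base-year rate (the
#' default anchor is the trajectory's own). The RMf applies to the GDP cost
#' basis only; hospital and productivity bases are already human-population
#' costs.
#'
#' @param traj An `amr_trajectory`.
#' @param base_annual_cost Annual cost (GBP) incurred at the anchor rate in
#'   the base year.
#' @param copd_share Fraction of prescriptions attributable to COPD
#'   exacerbations.
#' @param apply_rmf Apply the resistance modulating factor?
#' @param rmf The resistance modulating factor (used when `apply_rmf`).
#' @param anchor_rate Base-year rate to anchor the cost scaling; defaults to
#'   the trajectory's own base-year rate.
#' @return A `data.frame` with columns `year` and `cost`.
#' @export
scenario_costs <- function(traj, base_annual_cost, copd_share,
                           apply_rmf = FALSE, rmf = 1, anchor_rate = NULL) {
  anchor_rate <- anchor_rate %||% traj$rates[traj$years == traj$base_year]
  if (anchor_rate == 0)
    stop("base-year resistance rate is zero; cannot anchor cost scaling",
         call. = FALSE)
  mult <- if (apply_rmf) rmf else 1
  data.frame(year = traj$years,
             cost = base_annual_cost * (traj$rates / anchor_rate) * mult * copd_share)
}

#' Annual cost savings between two scenarios
#'
#' Mean over the common year range of the usual-care minus testing-scenario
#' cost streams.
#'
#' @param usual,tested `data.frame`s from [scenario_costs()].
#' @return Annual savings (GBP/year).
#' @export
annual_savings <- function(usual, tested) {
  if (!identical(usual$year, tested$year))
    stop("scenario cost streams cover different year ranges", call. = FALSE)
  mean(usual$cost - tested$cost)
}

#' Annual cost of UK-wide testing
#'
#' @param annual_diagnoses Yearly COPD diagnoses.
#' @param exacerbation_fraction Fraction of patients tested, in `[0, 1]`.
#' @param unit_cost Test unit cost (GBP).
#' @return List with `patients` and `cost` (GBP/year).
#' @export
uk_testing_cost <- function(annual_diagnoses, exacerbation_fraction, unit_cost) {
  if (exacerbation_fraction < 0 || exacerbation_fraction > 1)
    stop("tested fraction must lie in [0, 1]", call. = FALSE)
  if (annual_diagnoses < 0 || unit_cost < 0)
    stop("inputs must be nonnegative", call. = FALSE)
  patients <- annual_diagnoses * exacerbation_fraction
  list(patients = patients, cost = patients * unit_cost)
}

#' Net annual UK position: scaled savings minus testing cost
#'
#' @param savings Annual savings (GBP/year).
#' @param uk_share Share of global savings attributed to the UK, in `(0, 1]`.
#' @param testing_cost Annual testing cost (GBP/year).
#' @return Net position (GBP/year).
#' @export
uk_net_position <- function(savings, uk_share, testing_cost) {
  if (uk_share <= 0 || uk_share > 1)
    stop("UK share must lie in (0, 1]", call. = FALSE)
  savings * uk_share - testing_cost
}

#' Full scenario grid of annual resistance cost savings
#'
#' Crosses pathogens, reduction factors, cost bases (GDP with RMf; hospital
#' and productivity without; their sum as the combined basis) and UK shares.
#'
#' @param params A `copd_params` object (its `amr` block supplies bases,
#'   reductions and shares).
#' @param trajectories Named list of `amr_trajectory` objects; default:
#'   generated from the configured synthetic trajectory specifications.
#' @return A `data.frame` with one row per scenario cell: `pathogen`,
#'   `reduction`, `basis`, `uk_share`, `annual_savings` (GBP/year).
#' @export
amr_scenario_grid <- function(params, trajectories = NULL) {
  am <- params$amr
  if (is.null(trajectories))
    trajectories <- lapply(am$trajectories, function(ts)
      generate_amr_trajectory(do.call(trajectory_generator_spec, ts)))
  bases <- list(
    gdp = list(cost = am$annual_costs_gbp$gdp, rmf = TRUE),
    hospital = list(cost = am$annual_costs_gbp$hospital, rmf = FALSE),
    productivity = list(cost = am$annual_costs_gbp$productivity, rmf = FALSE))
  rows <- list()
  for (pn in names(trajectories)) {
    traj <- trajectories[[pn]]
    anchor <- traj$rates[traj$years == traj$base_year]
    for (r in am$reductions) {
      tested <- reduced_trajectory(traj, r)
      sav <- vapply(bases, function(b) {
        annual_savings(
          scenario_costs(traj, b$cost, am$copd_prescription_share, b$rmf, am$rmf),
          scenario_costs(tested, b$cost, am$copd_prescription_share, b$rmf,
                         am$rmf, anchor_rate = anchor))
      }, numeric(1))
      sav <- c(sav, combined = sav[["hospital"]] + sav[["productivity"]])
      for (basis in names(sav)) for (share in am$uk_shares)
        rows[[length(rows) + 1L]] <- data.frame(
          pathogen = traj$pathogen, reduction = r, basis = basis,
          uk_share = share, annual_savings = sav[[basis]] * share,
          stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, rows)
}
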