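# Synthetic stand-ins for inputs the model needs but which are not available
# as published point estimates: pathogen resistance-rate trajectories,
# all-cause mortality by age, and the Markov transition/resource-use block.
# Every generator is a pure function of its specification (seed included),
# and every emitted file carries a provenance header marking it synthetic.

#' Specification for a synthetic resistance-rate trajectory
#'
#' @param pathogen Pathogen label.
#' @param start_rate Resistance proportion in the start year.
#' @param trend Yearly drift: relative (multiplicative, e.g. `-0.02` for a
#'   2% yearly decline) or additive, per `trend_type`.
#' @param trend_type `"relative"` or `"additive"`.
#' @param noise_sd Standard deviation of yearly Gaussian perturbations.
#' @param seed RNG seed for the perturbations.
#' @param start_year,end_year Year range (inclusive).
#' @return A list of class `trajectory_spec`.
#' @export
trajectory_generator_spec <- function(pathogen = "AMR", start_rate = 0.05,
                                      trend = 0, trend_type = c("relative", "additive"),
                                      noise_sd = 0, seed = 1L,
                                      start_year = 2023, end_year = 2040) {
  trend_type <- match.arg(trend_type)
  stopifnot(start_rate > 0, start_rate < 1, noise_sd >= 0,
            end_year >= start_year)
  structure(list(pathogen = pathogen, start_rate = start_rate, trend = trend,
                 trend_type = trend_type, noise_sd = noise_sd,
                 seed = as.integer(seed), start_year = as.integer(start_year),
                 end_year = as.integer(end_year)), class = "trajectory_spec")
}

#' Generate a synthetic resistance-rate trajectory
#'
#' Deterministic drift curve (relative or additive yearly trend from the
#' start rate) plus optional seeded Gaussian noise, clipped to
#' `[0.001, 0.999]`. With zero noise the output is the exact drift curve;
#' identical specifications yield identical trajectories.
#'
#' @param spec A `trajectory_spec`.
#' @return An [amr_trajectory()] whose base year is the start year.
#' @export
generate_amr_trajectory <- function(spec) {
  stopifnot(inherits(spec, "trajectory_spec"))
  years <- spec$start_year:spec$end_year
  t <- seq_along(years) - 1
  rates <- if (spec$trend_type == "relative")
    spec$start_rate * (1 + spec$trend)^t
  else spec$start_rate + spec$trend * t
  if (spec$noise_sd > 0) {
    old <- if (exists(".Random.seed", .GlobalEnv)) get(".Random.seed", .GlobalEnv) else NULL
    on.exit(if (!is.null(old)) assign(".Random.seed", old, .GlobalEnv))
    set.seed(spec$seed)
    rates <- rates + stats::rnorm(length(rates), 0, spec$noise_sd)
  }
  rates <- pmin(pmax(rates, 0.001), 0.999)
  traj <- amr_trajectory(years, rates, pathogen = spec$pathogen,
                         base_year = spec$start_year)
  attr(traj, "provenance") <- list(synthetic = TRUE, spec = unclass(spec))
  traj
}

#' Write a trajectory to CSV with a synthetic-provenance header
#'
#' @param traj An `amr_trajectory`.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_trajectory_csv <- function(traj, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(sprintf("# synthetic resistance-rate trajectory: %s", traj$pathogen),
               sprintf("# base_year: %d", traj$base_year)), con)
  utils::write.csv(data.frame(year = traj$years, rate = traj$rates),
                   con, row.names = FALSE)
  invisible(path)
}

#' Read a trajectory CSV (as written by [write_trajectory_csv()])
#'
#' @param path CSV path with columns `year`, `rate`; `#` lines ignored.
#' @param pathogen Pathogen label; defaults to the header annotation if
#'   present.
#' @param base_year Base year for cost anchoring.
#' @return An `amr_trajectory`.
#' @export
read_trajectory_csv <- function(path, pathogen = NULL, base_year = 2023) {
  header <- grep("^#", readLines(path, n = 5), value = TRUE)
  if (is.null(pathogen)) {
    m <- grep("trajectory:", header, value = TRUE)
    pathogen <- if (length(m)) trimws(sub(".*trajectory:", "", m[1])) else "AMR"
  }
  df <- utils::read.csv(path, comment.char = "#")
  amr_trajectory(df$year, df$rate, pathogen = pathogen, base_year = base_year)
}

#' Specification for a synthetic all-cause mortality table
#'
#' Gompertz mortality: hazard `h(a) = baseline * exp(slope * a)`, giving the
#' age-specific annual death probability
#' `q(a) = 1 - exp(-(baseline/slope) * (exp(slope*(a+1)) - exp(slope*a)))`
#' (constant-hazard limit when `slope = 0`). Defaults emulate recent
#' England & Wales all-cause mortality in shape: q rises from roughly 0.008
#' at 60 to roughly 0.35 at 100.
#'
#' @param baseline Baseline hazard at age 0, positive.
#' @param slope Exponential age slope, nonnegative.
#' @param max_age Last age in the table.
#' @param population Synthetic population per single year of age (used only
#'   to emit a deaths/population representation).
#' @return A list of class `mortality_spec`.
#' @export
mortality_generator_spec <- function(baseline = 2.7e-5, slope = 0.095,
                                     max_age = 100, population = 650000) {
  stopifnot(baseline > 0, slope >= 0, max_age >= 1, population > 0)
  structure(list(baseline = baseline, slope = slope,
                 max_age = as.integer(max_age), population = population),
            class = "mortality_spec")
}

#' Generate a synthetic age-indexed mortality table
#'
#' @param spec A `mortality_spec`.
#' @return A `data.frame` with columns `age` (0 to `max_age`), `qx` (annual
#'   death probability, clipped to `[0, 1]`), `deaths` and `population`.
#' @export
generate_mortality_table <- function(spec) {
  stopifnot(inherits(spec, "mortality_spec"))
  age <- 0:spec$max_age
  H <- if (spec$slope == 0) spec$baseline + 0 * age
  else (spec$baseline / spec$slope) *
    (exp(spec$slope * (age + 1)) - exp(spec$slope * age))
  qx <- pmin(1, 1 - exp(-H))
  df <- data.frame(age = age, qx = qx,
                   deaths = qx * spec$population, population = spec$population)
  attr(df, "provenance") <- list(synthetic = TRUE, spec = unclass(spec))
  df
}

#' Write a mortality table to CSV with a synthetic-provenance header
#'
#' @param table Mortality table from [generate_mortality_table()].
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_mortality_csv <- function(table, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("# synthetic all-cause mortality table (Gompertz)", con)
  utils::write.csv(table, con, row.names = FALSE)
  invisible(path)
}

#' Read a mortality table CSV
#'
#' Accepts either an annual-probability column `qx` or the pair
#' `deaths`/`population` from which `qx` is derived.
#'
#' @param path CSV path; `#` lines ignored.
#' @return A `data.frame` with columns `age` and `qx`.
#' @export
read_mortality_csv <- function(path) {
  df <- utils::read.csv(path, comment.char = "#")
  if (!"age" %in% names(df)) stop("mortality CSV needs an 'age' column", call. = FALSE)
  if (!"qx" %in% names(df)) {
    if (!all(c("deaths", "population") %in% names(df)))
      stop("mortality CSV needs 'qx' or 'deaths' and 'population'", call. = FALSE)
    df$qx <- df$deaths / df$population
  }
  if (any(df$qx < 0 | df$qx > 1))
    stop("mortality probabilities outside [0, 1]", call. = FALSE)
  df[, c("age", "qx")]
}

#' Generate a synthetic Markov transition/resource-use block
#'
#' Builds the long-run model's configuration block — severity transitions,
#' GOLD-stage progression, disease-specific mortality, admission-event
#' rates, utility multipliers and per-state resource-use quantities — from
#' two scalar intensities. Exacerbation intensity scales movement towards
#' worse severities; progression intensity scales GOLD-stage progression.
#' With `randomize = TRUE` the intensities are drawn from seeded uniform
#' ranges, for property sweeps. The block is provenance-flagged synthetic
#' and is valid input for [load_config()]-level validation.
#'
#' @param seed RNG seed (used only when `randomize = TRUE`).
#' @param stage_mix Initial GOLD-stage mix (3 nonnegative numbers summing
#'   to 1); carried for provenance, not used in the block itself.
#' @param exacerbation_intensity Scale on upward severity movement, in
#'   `(0, 2]`.
#' @param progression_intensity Scale on stage progression, in `[0, 2]`.
#' @param randomize Draw intensities randomly from the seeded ranges?
#' @return A named list shaped like the `markov` configuration block.
#' @export
generate_transition_defaults <- function(seed = 1L,
                                         stage_mix = rep(1 / 3, 3),
                                         exacerbation_intensity = 1,
                                         progression_intensity = 1,
                                         randomize = FALSE) {
  if (abs(sum(stage_mix) - 1) > 1e-9 || any(stage_mix < 0))
    stop("stage mix must be nonnegative and sum to 1", call. = FALSE)
  if (randomize) {
    old <- if (exists(".Random.seed", .GlobalEnv)) get(".Random.seed", .GlobalEnv) else NULL
    on.exit(if (!is.null(old)) assign(".Random.seed", old, .GlobalEnv))
    set.seed(as.integer(seed))
    exacerbation_intensity <- stats::runif(1, 0.3, 1.8)
    progression_intensity <- stats::runif(1, 0.3, 1.8)
  }
  e <- exacerbation_intensity
  if (e <= 0 || e > 2) stop("exacerbation intensity must lie in (0, 2]", call. = FALSE)
  if (progression_intensity < 0 || progression_intensity > 2)
    stop("progression intensity must lie in [0, 2]", call. = FALSE)
  # Upward severity movement scales with intensity; recovery movement fixed;
  # diagonals absorb the remainder (positive for all admissible intensities).
  sev <- list(stable = c(1 - (0.12 + 0.03) * e, 0.12 * e, 0.03 * e),
              mild = c(0.35, 1 - 0.35 - 0.20 * e, 0.20 * e),
              moderate = c(0.10, 0.25, 0.65))
  prog <- lapply(list(stable = 0.003, mild = 0.012, moderate = 0.045),
                 function(p) min(1, p * progression_intensity))
  list(
    provenance = "synthetic",
    severity_transitions = sev,
    stage_progression = prog,
    disease_death = list(stable = c(0.0000, 0.0005, 0.0015),
                         mild = c(0.0010, 0.0020, 0.0040),
                         moderate = c(0.0040, 0.0080, 0.0150)),
    admission_prob = list(stable = 0, mild = 0.02, moderate = 0.10),
    utility_multipliers = list(stable = 1.0, mild = 0.90, moderate = 0.75),
    resource_use = list(
      gp_consultation = c(0.30, 1.00, 2.00),
      prescription = c(0.30, 1.00, 2.00),
      antibiotic_course = c(0.00, 0.50, 1.00),
      steroid_course = c(0.00, 0.50, 1.00),
      phone_call = c(0.50, 1.00, 1.50),
      patient_contact = c(0.25, 0.50, 1.00),
      community_nurse_followup = c(0.00, 0.20, 0.60),
      primary_care_followup = c(0.20, 0.50, 1.00),
      primary_care_spirometry = c(0.25, 0.25, 0.25),
      influenza_vaccination = c(0.25, 0.25, 0.25)),
    stage_resource_use = list(
      outpatient_followup = c(0.00, 0.25, 0.50),
      secondary_care_followup = c(0.00, 0.25, 0.50),
      secondary_care_spirometry = c(0.00, 0.00, 0.25),
      oxygen_therapy = c(0.00, 0.00, 1.00),
      home_visit = c(0.00, 0.05, 0.15)),
    mortality = list(type = "gompertz", baseline = 2.7e-5, slope = 0.095,
                     max_age = 100))
}
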