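# End-to-end orchestration: base case, sensitivity analyses, resistance
# costing, and file outputs with a run manifest.

as_params <- function(config) {
  if (inherits(config, "copd_params")) config else load_config(config)
}

# Assumption flags surfaced in manifests: synthetic and clamped inputs.
assumption_flags <- function(params) {
  flags <- character()
  if (identical(params$markov$provenance, "synthetic"))
    flags <- c(flags, "markov transition/resource-use block is synthetic")
  if (identical(params$markov$mortality$type, "gompertz"))
    flags <- c(flags, "all-cause mortality is a synthetic Gompertz table")
  items <- flat_items(params)
  clamped <- names(items)[vapply(items, function(it)
    isTRUE(it$spec$clamped), logical(1))]
  if (length(clamped))
    flags <- c(flags, paste("Beta standard error clamped for:",
                            paste(clamped, collapse = ", ")))
  flags <- c(flags, "tree cost bundles and admission recovery split are assumptions")
  flags
}

base_case_table <- function(res) {
  data.frame(
    row = c("RP2.1 test", "Usual practice", "Difference", "ICER"),
    cost = c(res$cost_intervention, res$cost_control, res$incremental_cost, NA),
    qaly = c(res$qaly_intervention, res$qaly_control, res$incremental_qaly, NA),
    classification = c("", "", "",
                       if (res$classification == "icer")
                         sprintf("%.2f", res$icer) else res$classification),
    stringsAsFactors = FALSE)
}

#' Run the base-case analysis
#'
#' Full deterministic two-arm run at the configured point estimates,
#' reported as per-arm lifetime costs and QALYs, their differences, and the
#' ICER classification.
#'
#' @param config A `copd_params` object or path to a YAML configuration.
#' @param out_dir Optional output directory; when given, the report is
#'   written as `base_case.csv` and `base_case.json`.
#' @return List with `result` (a `ce_result`) and `table` (a `data.frame`).
#' @export
run_base_case <- function(config = default_config_path(), out_dir = NULL) {
  params <- as_params(config)
  res <- run_model(params)
  tab <- base_case_table(res)
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    utils::write.csv(tab, file.path(out_dir, "base_case.csv"), row.names = FALSE)
    jsonlite::write_json(unclass(res), file.path(out_dir, "base_case.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
  }
  list(result = res, table = tab)
}

#' Approach-1 resistance penalty table
#'
#' Re-runs the base case with each candidate per-prescription resistance
#' penalty added to the antibiotic cost items: the GDP-derived penalty from
#' the configured chain, and the broad/narrow-spectrum alternatives.
#'
#' @param params A `copd_params` object.
#' @return A `data.frame` with one row per penalty: source, penalty (GBP),
#'   classification and incremental cost/QALYs.
#' @export
amr_approach1_table <- function(params) {
  chain <- penalty_chain(params$amr)
  penalties <- c(gdp_chain = penalty_per_prescription(chain),
                 unlist(params$amr$penalty$alternatives))
  rows <- lapply(names(penalties), function(nm) {
    res <- run_model(apply_penalty(params, penalties[[nm]]))
    data.frame(source = nm, penalty_gbp = penalties[[nm]],
               incremental_cost = res$incremental_cost,
               incremental_qaly = res$incremental_qaly,
               classification = res$classification, stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' UK testing-cost comparison table
#'
#' Annual cost of testing the exacerbating UK COPD population at the
#' configured tested fractions, with patient counts.
#'
#' @param params A `copd_params` object.
#' @return A `data.frame` with columns `tested_fraction`, `patients`,
#'   `annual_cost`.
#' @export
uk_testing_table <- function(params) {
  uk <- params$amr$uk
  rows <- lapply(uk$tested_fractions, function(f) {
    tc <- uk_testing_cost(uk$annual_diagnoses, f, uk$unit_cost)
    data.frame(tested_fraction = f, patients = tc$patients,
               annual_cost = tc$cost)
  })
  do.call(rbind, rows)
}

# Run one suite stage, recording its status in the mutable manifest
# environment; failures are recorded and do not abort later stages.
run_stage <- function(env, name, fn) {
  res <- tryCatch(list(ok = TRUE, value = fn()),
                  error = function(e) list(ok = FALSE, error = conditionMessage(e)))
  env$stages[[name]] <- if (res$ok) list(status = "ok")
  else list(status = "error", message = res$error)
  if (res$ok) res$value else NULL
}

#' Run the full analysis suite and write every artifact
#'
#' Executes, in order: parameter audit export, base case, one-way
#' sensitivity table, break-even price, probabilistic sensitivity analysis
#' with cost-effectiveness plane and acceptability curve, Approach-1
#' penalty table, Approach-2 scenario grid with trajectories, and the UK
#' testing-cost comparison. Each stage's outcome is recorded in a manifest
#' (written even when stages fail; remaining stages are still attempted).
#' All randomness flows from the single seed, so repeated runs are
#' byte-identical.
#'
#' @param config A `copd_params` object or path to a YAML configuration.
#' @param out_dir Output directory.
#' @param seed Master seed for the probabilistic analysis.
#' @param psa_draws Number of probabilistic draws; defaults to the
#'   configured count.
#' @return The manifest list, invisibly.
#' @export
run_full_suite <- function(config = default_config_path(), out_dir, seed = 1L,
                           psa_draws = NULL) {
  params <- as_params(config)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  draws <- psa_draws %||% params$structural$psa_draws
  env <- new.env()
  env$stages <- list()
  env$outputs <- character()
  emit <- function(file) {
    env$outputs <- c(env$outputs, file)
    file.path(out_dir, file)
  }

  run_stage(env, "parameters", function()
    write_parameters_csv(params, emit("parameters.csv")))
  run_stage(env, "base_case", function() {
    bc <- run_base_case(params, out_dir = out_dir)
    env$outputs <- c(env$outputs, "base_case.csv", "base_case.json")
    bc
  })
  run_stage(env, "dsa", function() {
    tab <- dsa_table(params)
    utils::write.csv(tab, emit("dsa.csv"), row.names = FALSE)
    tab
  })
  run_stage(env, "threshold", function() {
    thr <- threshold_price(params)
    jsonlite::write_json(list(wtp_threshold = params$structural$wtp_threshold,
                              break_even_price = thr),
                         emit("threshold.json"), auto_unbox = TRUE, digits = NA)
    thr
  })
  run_stage(env, "psa", function() {
    samples <- run_psa(params, n = draws, seed = seed)
    write_ce_plane_csv(samples, emit("ce_plane.csv"))
    utils::write.csv(ceac(samples), emit("ceac.csv"), row.names = FALSE)
    samples
  })
  run_stage(env, "amr_approach1", function() {
    tab <- amr_approach1_table(params)
    utils::write.csv(tab, emit("amr_approach1.csv"), row.names = FALSE)
    tab
  })
  run_stage(env, "amr_approach2", function() {
    trajectories <- lapply(params$amr$trajectories, function(ts)
      generate_amr_trajectory(do.call(trajectory_generator_spec, ts)))
    for (nm in names(trajectories))
      write_trajectory_csv(trajectories[[nm]],
                           emit(sprintf("trajectory_%s.csv", nm)))
    grid <- amr_scenario_grid(params, trajectories)
    utils::write.csv(grid, emit("amr_scenarios.csv"), row.names = FALSE)
    grid
  })
  run_stage(env, "uk_testing", function() {
    tab <- uk_testing_table(params)
    utils::write.csv(tab, emit("uk_testing.csv"), row.names = FALSE)
    tab
  })

  manifest <- list(
    package_version = as.character(utils::packageVersion("copdcea")),
    config = if (is.character(config)) config else "(in-memory parameter set)",
    seed = seed, psa_draws = draws,
    assumption_flags = assumption_flags(params),
    outputs = env$outputs, stages = env$stages,
    succeeded = all(vapply(env$stages,
                           function(s) identical(s$status, "ok"), logical(1))))
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(manifest)
}
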