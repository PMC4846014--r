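# End-to-end orchestration: simulate -> terrain -> thin/split -> fit all
# candidates -> rank -> average -> classify, written to a run directory as
# plain-text artifacts with a machine-readable log.

#' Run configuration
#'
#' Bundles every stage parameter of a full pipeline run. A run is
#' reproducible from its configuration alone: all randomness derives from
#' `seed` via [stage_seed()].
#'
#' @param seed integer run seed.
#' @param scenario a [scenario_config()] (its own seed is overridden by
#'   `seed`).
#' @param beta regularization multiplier for fitting.
#' @param bg_n background sample size.
#' @param train_fraction training fraction of the thinned points.
#' @param aicc_points `"train"` or `"all"` for the AICc sample.
#' @param delta_max plausible-set cutoff.
#' @param suitable,optimal classification thresholds.
#' @param registry candidate registry.
#' @return list of class `"run_config"`.
#' @export
run_config <- function(seed = 1, scenario = scenario_config(seed = seed),
                       beta = 1.0, bg_n = 10000, train_fraction = 0.8,
                       aicc_points = "train", delta_max = 7,
                       suitable = 0.5, optimal = 0.75,
                       registry = default_registry()) {
  scenario$seed <- seed
  structure(list(seed = seed, scenario = scenario, beta = beta, bg_n = bg_n,
                 train_fraction = train_fraction, aicc_points = aicc_points,
                 delta_max = delta_max, suitable = suitable,
                 optimal = optimal, registry = registry),
            class = "run_config")
}

#' Run the whole pipeline into a directory
#'
#' Simulates the scenario, derives predictors, thins to one presence per
#' stand, fixes the train/test split, fits and ranks the full candidate set,
#' builds the model-averaged suitability map, classifies it, and writes every
#' intermediate (ASCII grids, CSV tables, the lambdas file of the top model,
#' a summary, and a key-value log of all stage parameters and seeds) under
#' `outdir`. Identical configurations produce identical output trees.
#'
#' @param config a [run_config()].
#' @param outdir output directory (created if needed).
#' @return invisibly, a list with the in-memory results: `bundle`,
#'   `occurrences`, `comparison`, `importance`, `suitability`, `summary`.
#' @export
run_all <- function(config = run_config(), outdir = tempfile("run")) {
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop(sprintf("stage '%s' failed: %s", name, conditionMessage(e)),
           call. = FALSE))
  }
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  bundle <- stage("simulate", simulate_scenario(config$scenario))
  for (nm in names(bundle$stack))
    write_ascii_grid(bundle$stack[[nm]],
                     file.path(outdir, paste0("predictor_", nm, ".asc")))
  occ <- stage("thin", thin_by_polygon(bundle$presences, bundle$stands,
                                       seed = stage_seed(config$seed, "thin")))
  occ <- stage("split", train_test_split(occ, config$train_fraction,
                                         seed = stage_seed(config$seed,
                                                           "split")))
  write_occurrences(occ, file.path(outdir, "occurrences.csv"))
  comparison <- stage("select", run_comparison(
    bundle$stack, occ, registry = config$registry, beta = config$beta,
    aicc_points = config$aicc_points, bg_n = config$bg_n,
    seed = stage_seed(config$seed, "background")))
  utils::write.csv(as.data.frame(comparison),
                   file.path(outdir, "comparison.csv"), row.names = FALSE)
  importance <- variable_importance(comparison, config$registry)
  utils::write.csv(importance, file.path(outdir, "importance.csv"),
                   row.names = FALSE)
  top <- comparison$model[which(comparison$rank == 1L)]
  write_model_params(attr(comparison, "models")[[top]],
                     file.path(outdir, "top_model_lambdas.txt"))
  suit <- stage("map", suitability_map(
    comparison, bundle$stack, delta_max = config$delta_max,
    suitable = config$suitable, optimal = config$optimal))
  write_ascii_grid(suit$average, file.path(outdir, "suitability_average.asc"))
  write_ascii_grid(suit$classified,
                   file.path(outdir, "suitability_classes.asc"))
  summary <- summarize_habitat(suit$classified, occ)
  writeLines(c(
    sprintf("fraction_suitable: %.6f", summary$fraction_suitable),
    sprintf("fraction_optimal: %.6f", summary$fraction_optimal),
    sprintf("n_points: %d", summary$n_points),
    sprintf("n_points_in_suitable: %d", summary$n_points_in_suitable),
    sprintf("n_points_in_optimal: %d", summary$n_points_in_optimal),
    sprintf("averaged_models: %s", paste(suit$models, collapse = ", "))),
    file.path(outdir, "summary.txt"))
  log <- c(
    sprintf("seed: %d", config$seed),
    sprintf("grid: %d x %d @ %g", config$scenario$nrows,
            config$scenario$ncols, config$scenario$cellsize),
    sprintf("n_presences: %d", config$scenario$n_presences),
    sprintf("n_stands: %d", config$scenario$n_stands),
    sprintf("smoothing_passes: %d", config$scenario$smoothing_passes),
    sprintf("beta: %g", config$beta),
    sprintf("bg_n: %d", config$bg_n),
    sprintf("train_fraction: %g", config$train_fraction),
    sprintf("aicc_points: %s", config$aicc_points),
    sprintf("delta_max: %g", config$delta_max),
    sprintf("thresholds: %g, %g", config$suitable, config$optimal),
    sprintf("stage_seed_%s: %d", c("thin", "split", "background"),
            vapply(c("thin", "split", "background"),
                   function(s) stage_seed(config$seed, s), 1L)))
  writeLines(log, file.path(outdir, "run_log.txt"))
  invisible(list(bundle = bundle, occurrences = occ, comparison = comparison,
                 importance = importance, suitability = suit,
                 summary = summary, outdir = outdir))
}
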