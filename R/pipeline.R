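#' End-to-end pipeline configuration
#'
#' @param cohort a [cohort_config()].
#' @param detection a [detection_params()].
#' @param k folds for cross-validation.
#' @param models classifier names to evaluate.
#' @param seed master seed: governs every stochastic stage through derived
#'   child seeds.
#' @param n_components principal components retained per fold.
#' @return list of class `pipeline_config`.
#' @export
pipeline_config <- function(cohort = cohort_config(),
                            detection = detection_params(),
                            k = 4, models = classifier_names(),
                            seed = 17L, n_components = 5) {
  stopifnot(inherits(cohort, "cohort_config"),
            inherits(detection, "detection_params"))
  structure(list(cohort = cohort, detection = detection, k = k,
                 models = models, seed = as.integer(seed),
                 n_components = n_components),
            class = "pipeline_config")
}

#' Read a pipeline configuration from YAML
#'
#' Recognized top-level sections: `circuit` (args of [build_circuit()]),
#' `styles` (`normal`/`aggressive` overrides), `noise`, `effect`,
#' `effect_size`, `counts` (`healthy`, `mci`), `between_subject_cv`,
#' `detection` (args of [detection_params()]), `cv` (`k`, `models`,
#' `n_components`), `seed`.
#'
#' @param path YAML file path.
#' @return a `pipeline_config`.
#' @export
read_pipeline_config <- function(path) {
  y <- yaml::read_yaml(path)
  # [[ access throughout: $ would partial-match (e.g. effect_size for effect)
  circuit <- do.call(build_circuit, y[["circuit"]] %||% list())
  styles <- driving_styles(normal = y[["styles"]][["normal"]] %||% list(),
                           aggressive = y[["styles"]][["aggressive"]] %||% list())
  noise <- do.call(noise_params, y[["noise"]] %||% list())
  effect <- do.call(effect_params, y[["effect"]] %||% list())
  seed <- as.integer(y[["seed"]] %||% 17L)
  coh <- cohort_config(
    circuit = circuit, styles = styles, noise = noise, effect = effect,
    effect_size = y[["effect_size"]] %||% 1,
    n_healthy = y[["counts"]][["healthy"]], n_mci = y[["counts"]][["mci"]],
    between_subject_cv = y[["between_subject_cv"]] %||% 0.10,
    seed = seed
  )
  det <- do.call(detection_params, y[["detection"]] %||% list())
  pipeline_config(
    cohort = coh, detection = det,
    k = y[["cv"]][["k"]] %||% 4,
    models = y[["cv"]][["models"]] %||% classifier_names(),
    seed = seed,
    n_components = y[["cv"]][["n_components"]] %||% 5
  )
}

#' Run the full analysis pipeline
#'
#' Chains simulate -> extract -> evaluate -> contribute and writes every
#' artifact under `out_dir`: `roster.csv`, per-session sensor logs plus
#' `manifest.csv` (under `sessions/`), `features.csv`, the three
#' cross-validation result CSVs, `contributions.csv`, and `run_log.txt`
#' recording seeds, parameters and stage timings. Rerunning with the same
#' configuration and seed reproduces every artifact byte-identically.
#'
#' @param config a [pipeline_config()].
#' @param out_dir output directory (created; reused if it exists).
#' @param write_sessions write per-session sensor logs (the slowest artifact;
#'   `TRUE` by default).
#' @param quiet suppress progress messages.
#' @return invisibly, a list with the in-memory stage results (`cohort`,
#'   `features`, `cv`, `contributions`) and `out_dir`.
#' @export
run_pipeline <- function(config = pipeline_config(), out_dir,
                         write_sessions = TRUE, quiet = FALSE) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  log_lines <- c(sprintf("drivecog %s pipeline run", packageVersion("drivecog")),
                 sprintf("seed: %d", config$seed),
                 sprintf("k: %d | models: %s", config$k,
                         paste(config$models, collapse = ", ")))
  say <- function(fmt, ...) if (!quiet) message(sprintf(fmt, ...))
  stage <- function(name, expr) {
    t0 <- proc.time()[["elapsed"]]
    out <- tryCatch(expr, error = function(e) {
      stopf("pipeline stage '%s' failed: %s (artifacts so far in %s)",
            name, conditionMessage(e), out_dir)
    })
    dtime <- proc.time()[["elapsed"]] - t0
    log_lines <<- c(log_lines, sprintf("stage %-12s %8.2f s", name, dtime))
    say("[%s] done in %.1f s", name, dtime)
    out
  }

  cohort <- stage("simulate", generate_cohort(config$cohort, seed = config$seed))
  write_roster(cohort$roster, file.path(out_dir, "roster.csv"))
  if (write_sessions)
    stage("write_logs", write_cohort(cohort, file.path(out_dir, "sessions")))

  features <- stage("extract", extract_feature_table(cohort, config$detection))
  write_feature_table(features, file.path(out_dir, "features.csv"))

  cv <- stage("evaluate", cross_validate(features, models = config$models,
                                         k = config$k, seed = config$seed,
                                         n_components = config$n_components))
  write_cv_results(cv, out_dir)

  contrib <- stage("contrib", feature_contribution(cv))
  utils::write.csv(as.data.frame(contrib), file.path(out_dir, "contributions.csv"),
                   row.names = FALSE, quote = FALSE)

  writeLines(log_lines, file.path(out_dir, "run_log.txt"))
  say("artifacts in %s", out_dir)
  invisible(list(cohort = cohort, features = features, cv = cv,
                 contributions = contrib, out_dir = out_dir))
}

#' Render a plain-text report from a completed run directory
#'
#' Validates the run artifacts and writes `report.txt` with the mean ± sd
#' metric table (one row per model), the per-fold detail header, and the
#' feature-contribution ranking.
#'
#' @param run_dir directory produced by [run_pipeline()].
#' @param path output file; default `report.txt` inside `run_dir`.
#' @return the report lines, invisibly.
#' @export
make_report <- function(run_dir, path = file.path(run_dir, "report.txt")) {
  need <- c("roster.csv", "features.csv", "results_full.csv",
            "results_per_fold.csv", "contributions.csv")
  missing <- need[!file.exists(file.path(run_dir, need))]
  if (length(missing) > 0)
    stopf("incomplete run in %s; missing artifact(s): %s", run_dir,
          paste(missing, collapse = ", "))

  res <- utils::read.csv(file.path(run_dir, "results_full.csv"),
                         stringsAsFactors = FALSE)
  metric_cols <- paste0(rep(c("accuracy", "sensitivity", "specificity",
                              "ppv", "npv"), each = 2), c("_mean", "_sd"))
  bad <- setdiff(c("model", metric_cols), names(res))
  if (length(bad) > 0)
    stopf("results_full.csv is malformed; missing column(s): %s",
          paste(bad, collapse = ", "))
  contrib <- utils::read.csv(file.path(run_dir, "contributions.csv"),
                             stringsAsFactors = FALSE)
  bad <- setdiff(c("feature_index", "feature_name", "score", "rank"),
                 names(contrib))
  if (length(bad) > 0)
    stopf("contributions.csv is malformed; missing column(s): %s",
          paste(bad, collapse = ", "))
  roster <- read_roster(file.path(run_dir, "roster.csv"))

  fmt_pm <- function(m, s) {
    s[is.na(s)] <- 0
    sprintf("%3.0f ± %2.0f%%", 100 * m, 100 * s)
  }
  lines <- c(
    "Driving-performance MCI classification report",
    sprintf("Cohort: %d subjects (%d Healthy, %d MCI)", nrow(roster),
            sum(roster$status == "Healthy"), sum(roster$status == "MCI")),
    "",
    "Cross-validated diagnostic metrics (mean ± sd over folds):",
    sprintf("%-20s %12s %12s %12s %12s %12s", "Model", "Accuracy",
            "Sensitivity", "Specificity", "PPV", "NPV")
  )
  for (i in seq_len(nrow(res))) {
    r <- res[i, ]
    lines <- c(lines, sprintf(
      "%-20s %12s %12s %12s %12s %12s", r$model,
      fmt_pm(r$accuracy_mean, r$accuracy_sd),
      fmt_pm(r$sensitivity_mean, r$sensitivity_sd),
      fmt_pm(r$specificity_mean, r$specificity_sd),
      fmt_pm(r$ppv_mean, r$ppv_sd),
      fmt_pm(r$npv_mean, r$npv_sd)
    ))
  }
  lines <- c(lines, "", "Top feature contributions (summed across folds):")
  top <- utils::head(contrib, 10)
  lines <- c(lines, sprintf("  %2d. %-32s %.4f", top$rank, top$feature_name,
                            top$score))
  writeLines(lines, path)
  invisible(lines)
}
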