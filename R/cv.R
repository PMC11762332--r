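#' Leakage-free inter-subject cross-validation
#'
#' Evaluates the six classifiers on a per-subject feature table under
#' stratified k-fold subject-level cross-validation. Inside every fold, and
#' using the training subjects only: missing features are imputed with
#' training means, features are z-scored, PCA is fitted and the first
#' `n_components` scores are used to train each classifier. The fold's test
#' subjects are then transformed with the training-fitted preprocessor and
#' classified. Reported summaries are the mean and standard deviation of each
#' diagnostic metric across folds; fold values that are undefined (zero
#' denominator) are excluded from the mean and the number of contributing
#' folds is reported.
#'
#' @param features data frame from [extract_feature_table()] (or
#'   [read_feature_table()]): `subject_id`, `status`, `f01`..`f26`.
#' @param models character vector of classifier names
#'   (see [classifier_names()]).
#' @param k number of folds.
#' @param seed master seed: drives the fold assignment and each stochastic
#'   learner (child seeds derived deterministically).
#' @param n_components principal components retained per fold.
#' @param folds optional pre-built [assign_folds()] result (overrides `k` and
#'   the fold-assignment seed).
#' @return object of class `drive_cv`: list with `summary` (per-model mean/sd
#'   table), `per_fold` (per model x fold confusion counts and metrics),
#'   `per_class` (accuracy for healthy, MCI and all subjects pooled over
#'   folds), `pca_models` (per-fold `pca_preprocessor`s, for
#'   [feature_contribution()]), `folds`, `models`, `seed`.
#' @examples
#' \donttest{
#' coh <- generate_cohort(cohort_config(circuit = build_circuit(laps = 3)))
#' feats <- extract_feature_table(coh)
#' cv <- cross_validate(feats, k = 4, seed = 17)
#' cv
#' }
#' @export
cross_validate <- function(features, models = classifier_names(), k = 4,
                           seed = 1L, n_components = 5, folds = NULL) {
  bad <- setdiff(models, classifier_names())
  if (length(bad) > 0)
    stopf("unknown classifier(s): %s; valid names: %s",
          paste(bad, collapse = ", "),
          paste(classifier_names(), collapse = ", "))
  roster <- features[, c("subject_id", "status")]
  if (is.null(folds)) folds <- assign_folds(roster, k = k, seed = seed)
  validate_folds(folds, roster)
  k <- folds$k

  X <- feature_matrix(features)
  status <- stats::setNames(features$status, features$subject_id)

  per_fold <- list()
  pca_models <- vector("list", k)
  pooled_pred <- list()

  for (f in seq_len(k)) {
    tr_ids <- folds$folds[[f]]$train
    te_ids <- folds$folds[[f]]$test
    pp <- fit_preprocessor(X[tr_ids, , drop = FALSE],
                           n_components = n_components)
    pca_models[[f]] <- pp
    tr_scores <- apply_preprocessor(pp, X[tr_ids, , drop = FALSE])
    te_scores <- apply_preprocessor(pp, X[te_ids, , drop = FALSE])

    for (m in models) {
      fit <- tryCatch(
        train_classifier(m, tr_scores, status[tr_ids],
                         seed = child_seed(seed, m, f)),
        error = function(e) stopf("fold %d, model %s: %s", f, m, conditionMessage(e))
      )
      ev <- evaluate_fold(fit, te_scores, status[te_ids])
      per_fold[[length(per_fold) + 1L]] <- data.frame(
        model = m, fold = f,
        TP = ev$counts[["TP"]], FP = ev$counts[["FP"]],
        TN = ev$counts[["TN"]], FN = ev$counts[["FN"]],
        t(ev$metrics), stringsAsFactors = FALSE
      )
      pooled_pred[[length(pooled_pred) + 1L]] <- data.frame(
        model = m, fold = f, subject_id = te_ids,
        truth = as.character(status[te_ids]),
        pred = as.character(ev$predictions), stringsAsFactors = FALSE
      )
    }
  }
  per_fold <- do.call(rbind, per_fold)
  rownames(per_fold) <- NULL
  pooled_pred <- do.call(rbind, pooled_pred)

  metric_names <- c("accuracy", "sensitivity", "specificity", "ppv", "npv")
  summ <- lapply(models, function(m) {
    rows <- per_fold[per_fold$model == m, ]
    out <- data.frame(model = m, stringsAsFactors = FALSE)
    for (mt in metric_names) {
      v <- rows[[mt]]
      out[[paste0(mt, "_mean")]] <- mean(v, na.rm = TRUE)
      out[[paste0(mt, "_sd")]] <- stats::sd(v[!is.na(v)])
      out[[paste0(mt, "_nfolds")]] <- sum(!is.na(v))
    }
    out
  })
  summ <- do.call(rbind, summ)

  per_class <- lapply(models, function(m) {
    p <- pooled_pred[pooled_pred$model == m, ]
    data.frame(
      model = m,
      acc_healthy = mean(p$pred[p$truth == "Healthy"] == "Healthy"),
      acc_mci = mean(p$pred[p$truth == "MCI"] == "MCI"),
      acc_all = mean(p$pred == p$truth),
      stringsAsFactors = FALSE
    )
  })
  per_class <- do.call(rbind, per_class)

  structure(
    list(summary = summ, per_fold = per_fold, per_class = per_class,
         predictions = pooled_pred, pca_models = pca_models, folds = folds,
         models = models, seed = as.integer(seed),
         n_components = n_components),
    class = "drive_cv"
  )
}

#' @export
print.drive_cv <- function(x, ...) {
  cat(sprintf("<drive_cv> %d-fold inter-subject CV, %d models (seed %d)\n\n",
              x$folds$k, length(x$models), x$seed))
  s <- x$summary
  fmt <- function(m, sdv) {
    sdv[is.na(sdv)] <- 0
    sprintf("%3.0f ± %2.0f%%", 100 * m, 100 * sdv)
  }
  disp <- data.frame(
    Model = s$model,
    Accuracy = fmt(s$accuracy_mean, s$accuracy_sd),
    Sensitivity = fmt(s$sensitivity_mean, s$sensitivity_sd),
    Specificity = fmt(s$specificity_mean, s$specificity_sd),
    PPV = fmt(s$ppv_mean, s$ppv_sd),
    NPV = fmt(s$npv_mean, s$npv_sd),
    check.names = FALSE
  )
  print(disp, row.names = FALSE)
  invisible(x)
}

#' @export
summary.drive_cv <- function(object, ...) {
  cat("Per-model metric means ± sd across folds",
      "(undefined fold values excluded; *_nfolds = contributing folds):\n")
  print(object$summary, row.names = FALSE, digits = 3)
  cat("\nPer-class accuracy (pooled over folds):\n")
  print(object$per_class, row.names = FALSE, digits = 3)
  invisible(object$summary)
}

#' Per-class accuracy bar chart
#'
#' Grouped bars of accuracy in identifying healthy subjects, MCI subjects and
#' all subjects pooled, per model.
#'
#' @param x a `drive_cv`.
#' @param ... passed to [graphics::barplot()].
#' @export
plot.drive_cv <- function(x, ...) {
  pc <- x$per_class
  m <- t(as.matrix(pc[, c("acc_healthy", "acc_mci", "acc_all")]))
  colnames(m) <- pc$model
  graphics::barplot(m, beside = TRUE, ylim = c(0, 1),
                    legend.text = c("Healthy", "MCI", "All"),
                    args.legend = list(x = "topright", bty = "n"),
                    ylab = "Accuracy", las = 2, ...)
  invisible(x)
}

#' Write cross-validation results to CSV files
#'
#' Writes a display summary (percent, 0 decimals), a full-precision
#' machine-readable summary, and the per-fold confusion/metric detail.
#'
#' @param cv a `drive_cv`.
#' @param dir output directory.
#' @return invisibly, the paths written.
#' @export
write_cv_results <- function(cv, dir) {
  stopifnot(inherits(cv, "drive_cv"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  s <- cv$summary
  disp <- data.frame(model = s$model, stringsAsFactors = FALSE)
  for (mt in c("accuracy", "sensitivity", "specificity", "ppv", "npv")) {
    mu <- s[[paste0(mt, "_mean")]]
    sdv <- s[[paste0(mt, "_sd")]]
    sdv[is.na(sdv)] <- 0
    disp[[mt]] <- sprintf("%.0f ± %.0f", 100 * mu, 100 * sdv)
  }
  p1 <- file.path(dir, "results_display.csv")
  p2 <- file.path(dir, "results_full.csv")
  p3 <- file.path(dir, "results_per_fold.csv")
  utils::write.csv(disp, p1, row.names = FALSE)
  utils::write.csv(s, p2, row.names = FALSE, quote = FALSE)
  utils::write.csv(cv$per_fold, p3, row.names = FALSE, quote = FALSE)
  invisible(c(display = p1, full = p2, per_fold = p3))
}
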