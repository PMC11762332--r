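test_that("no subject contributes to both train and test of any fold", {
  cv <- default_cv()
  roster <- default_features()[, c("subject_id", "status")]
  expect_silent(validate_folds(cv$folds, roster))
  for (f in cv$folds$folds)
    expect_length(intersect(f$train, f$test), 0)
  tests <- unlist(lapply(cv$folds$folds, `[[`, "test"))
  expect_setequal(tests, roster$subject_id)
  expect_false(any(duplicated(tests)))
})

test_that("per-fold preprocessing is fit on training rows only", {
  cv <- default_cv()
  feats <- default_features()
  X <- as.matrix(feats[, sprintf("f%02d", 1:26)])
  rownames(X) <- feats$subject_id
  f1 <- cv$folds$folds[[1]]
  # the stored preprocessor is exactly what training rows alone produce ...
  pp_train <- fit_preprocessor(X[f1$train, ], n_components = 5)
  expect_equal(cv$pca_models[[1]]$center, pp_train$center, tolerance = 1e-12)
  expect_equal(cv$pca_models[[1]]$gamma, pp_train$gamma, tolerance = 1e-12)
  # ... and differs from what train + test rows would give
  pp_all <- fit_preprocessor(X, n_components = 5)
  expect_false(isTRUE(all.equal(cv$pca_models[[1]]$center, pp_all$center)))
  # and from training with one subject removed
  pp_less <- fit_preprocessor(X[f1$train[-1], ], n_components = 5)
  expect_false(isTRUE(all.equal(cv$pca_models[[1]]$center, pp_less$center)))
})

test_that("summary means and sds match brute-force recomputation from fold detail", {
  cv <- default_cv()
  for (m in cv$models) {
    rows <- cv$per_fold[cv$per_fold$model == m, ]
    # metrics recomputed from the stored confusion counts
    for (i in seq_len(nrow(rows))) {
      cc <- structure(as.integer(rows[i, c("TP", "FP", "TN", "FN")]),
                      names = c("TP", "FP", "TN", "FN"),
                      class = "confusion_counts")
      mm <- fold_metrics(cc)
      expect_equal(rows$accuracy[i], mm[["accuracy"]])
      expect_equal(rows$sensitivity[i], mm[["sensitivity"]])
      expect_equal(rows$ppv[i], mm[["ppv"]])
    }
    srow <- cv$summary[cv$summary$model == m, ]
    for (mt in c("accuracy", "sensitivity", "specificity", "ppv", "npv")) {
      v <- rows[[mt]]
      expect_equal(srow[[paste0(mt, "_mean")]], mean(v, na.rm = TRUE))
      expect_equal(srow[[paste0(mt, "_nfolds")]], sum(!is.na(v)))
      if (sum(!is.na(v)) > 1)
        expect_equal(srow[[paste0(mt, "_sd")]], sd(v[!is.na(v)]))
    }
  }
})

test_that("cross-validation is deterministic at a fixed seed", {
  feats <- default_features()
  cv1 <- suppressWarnings(cross_validate(feats, models = c("SVM", "KNN"),
                                         k = 4, seed = 23))
  cv2 <- suppressWarnings(cross_validate(feats, models = c("SVM", "KNN"),
                                         k = 4, seed = 23))
  expect_identical(cv1$summary, cv2$summary)
  expect_identical(cv1$per_fold, cv2$per_fold)
})

test_that("per-class accuracies decompose the pooled accuracy", {
  cv <- default_cv()
  roster <- default_features()
  nh <- sum(roster$status == "Healthy"); nm <- sum(roster$status == "MCI")
  for (i in seq_len(nrow(cv$per_class))) {
    pc <- cv$per_class[i, ]
    expect_equal(pc$acc_all,
                 (pc$acc_healthy * nh + pc$acc_mci * nm) / (nh + nm),
                 tolerance = 1e-12)
  }
})

test_that("a pre-built fold assignment is honoured and invalid k rejected", {
  feats <- default_features()
  fa <- assign_folds(feats[, c("subject_id", "status")], k = 3, seed = 31)
  cv <- suppressWarnings(cross_validate(feats, models = "KNN", folds = fa))
  expect_equal(cv$folds$k, 3)
  expect_identical(cv$folds, fa)
  expect_error(cross_validate(feats, models = "KNN", k = 22), "exceeds")
})
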