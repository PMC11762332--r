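#' Available classifier names and their fixed hyperparameters
#'
#' Six standard binary classifiers with fixed, conventional hyperparameters:
#' SVM (C = 1.0, RBF kernel, gamma = 1/(d * var(X))), Random Forest
#' (100 trees, Gini, unlimited depth), AdaBoost (50 depth-1 stumps, learning
#' rate 1.0), KNN (k = 5, Euclidean), QDA (no regularization), and L2
#' logistic regression (C = 1.0). No hyperparameter tuning is performed.
#'
#' @return character vector of valid model names.
#' @export
classifier_names <- function() {
  c("SVM", "RandomForest", "AdaBoost", "KNN", "QDA", "LogisticRegression")
}

#' Train one classifier on PCA scores
#'
#' MCI is the positive class throughout. Stochastic learners are seeded.
#' Single-class training data yield a constant-prediction model with a
#' warning rather than an error.
#'
#' @param name one of [classifier_names()].
#' @param x numeric score matrix (training subjects x components).
#' @param y factor or character labels (`"Healthy"`/`"MCI"`).
#' @param seed integer seed for stochastic learners.
#' @param knn_k neighborhood size override for KNN (default 5).
#' @return object of class `drive_classifier`.
#' @export
train_classifier <- function(name, x, y, seed = 1L, knn_k = 5L) {
  if (!name %in% classifier_names())
    stopf("unknown classifier '%s'; valid names: %s", name,
          paste(classifier_names(), collapse = ", "))
  x <- as.matrix(x)
  y <- factor(as.character(y), levels = c("Healthy", "MCI"))
  if (anyNA(y)) stopf("labels must be 'Healthy' or 'MCI'")
  if (nrow(x) != length(y)) stopf("x rows and y length differ")

  if (nlevels(droplevels(y)) < 2) {
    warnf("single-class training data; returning a constant '%s' predictor",
          as.character(y[1]))
    return(structure(list(name = name, constant = as.character(y[1])),
                     class = "drive_classifier"))
  }

  set.seed(as.integer(seed))
  fit <- switch(
    name,
    SVM = e1071::svm(x = x, y = y, type = "C-classification",
                     kernel = "radial", cost = 1,
                     gamma = 1 / (ncol(x) * pop_var(x)), scale = FALSE),
    RandomForest = randomForest::randomForest(x = x, y = y, ntree = 100),
    AdaBoost = ada_fit(x, y, n_rounds = 50L, learning_rate = 1),
    KNN = list(x = x, y = y, k = as.integer(knn_k)),
    QDA = MASS::qda(x = x, grouping = y),
    LogisticRegression = glmnet::glmnet(x, y, family = "binomial", alpha = 0,
                                        lambda = 1 / nrow(x),
                                        standardize = FALSE)
  )
  structure(list(name = name, fit = fit, levels = levels(y)),
            class = "drive_classifier")
}

#' Predict class labels from a trained classifier
#'
#' @param object a `drive_classifier`.
#' @param newx score matrix of test subjects.
#' @param ... unused.
#' @return factor of predicted labels with levels `Healthy`, `MCI`.
#' @export
predict.drive_classifier <- function(object, newx, ...) {
  newx <- as.matrix(newx)
  lv <- c("Healthy", "MCI")
  if (!is.null(object$constant))
    return(factor(rep(object$constant, nrow(newx)), levels = lv))
  pred <- switch(
    object$name,
    SVM = stats::predict(object$fit, newx),
    RandomForest = stats::predict(object$fit, newx),
    AdaBoost = ada_predict(object$fit, newx),
    KNN = class::knn(train = object$fit$x, test = newx, cl = object$fit$y,
                     k = min(object$fit$k, nrow(object$fit$x))),
    QDA = stats::predict(object$fit, newx)$class,
    LogisticRegression = stats::predict(object$fit, newx, type = "class")[, 1]
  )
  factor(as.character(pred), levels = lv)
}

#' @export
print.drive_classifier <- function(x, ...) {
  cat(sprintf("<drive_classifier> %s%s\n", x$name,
              if (!is.null(x$constant)) sprintf(" (constant: %s)", x$constant) else ""))
  invisible(x)
}

# ---- discrete AdaBoost (SAMME) over depth-1 rpart stumps ------------------
# Implemented in-package: binary AdaBoost with decision stumps, additive
# weighted vote. err is clamped away from {0, 1}; boosting stops early when a
# stump is no better than chance or fits perfectly.
ada_fit <- function(x, y, n_rounds = 50L, learning_rate = 1) {
  df <- data.frame(y = y, x, check.names = FALSE)
  n <- nrow(df)
  w <- rep(1 / n, n)
  stumps <- list()
  alphas <- numeric(0)
  ctrl <- rpart::rpart.control(maxdepth = 1, minsplit = 2, minbucket = 1,
                               cp = 0, xval = 0)
  for (m in seq_len(n_rounds)) {
    fit <- rpart::rpart(y ~ ., data = df, weights = w, method = "class",
                        control = ctrl)
    pred <- stats::predict(fit, df, type = "class")
    err <- sum(w[pred != y]) / sum(w)
    if (err >= 0.5) break                      # stump no better than chance
    err_c <- min(max(err, 1e-10), 1 - 1e-10)
    alpha <- learning_rate * log((1 - err_c) / err_c)
    stumps[[length(stumps) + 1L]] <- fit
    alphas <- c(alphas, alpha)
    if (err <= 0) break                        # perfect stump: stop boosting
    w <- w * exp(alpha * (pred != y))
    w <- w / sum(w)
  }
  if (length(stumps) == 0) {                   # fall back to the majority class
    maj <- names(which.max(table(y)))
    return(list(constant = maj, levels = levels(y)))
  }
  list(stumps = stumps, alphas = alphas, levels = levels(y))
}

ada_predict <- function(model, newx) {
  if (!is.null(model$constant))
    return(factor(rep(model$constant, nrow(newx)), levels = model$levels))
  df <- as.data.frame(newx)
  votes <- matrix(0, nrow(df), length(model$levels),
                  dimnames = list(NULL, model$levels))
  for (m in seq_along(model$stumps)) {
    pred <- stats::predict(model$stumps[[m]], df, type = "class")
    for (lv in model$levels)
      votes[, lv] <- votes[, lv] + model$alphas[m] * (pred == lv)
  }
  factor(model$levels[max.col(votes, ties.method = "first")],
         levels = model$levels)
}
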