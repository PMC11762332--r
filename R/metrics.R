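#' Confusion counts for binary MCI classification
#'
#' MCI is the positive class: TP = MCI called MCI, TN = Healthy called
#' Healthy.
#'
#' @param truth,pred factors or characters with values `Healthy`/`MCI`.
#' @return object of class `confusion_counts`: named integer vector
#'   `TP, FP, TN, FN`.
#' @export
confusion_counts <- function(truth, pred) {
  truth <- as.character(truth)
  pred <- as.character(pred)
  stopifnot(length(truth) == length(pred))
  out <- c(TP = sum(truth == "MCI" & pred == "MCI"),
           FP = sum(truth == "Healthy" & pred == "MCI"),
           TN = sum(truth == "Healthy" & pred == "Healthy"),
           FN = sum(truth == "MCI" & pred == "Healthy"))
  structure(as.integer(out), names = names(out), class = "confusion_counts")
}

#' Diagnostic metrics from confusion counts
#'
#' Accuracy = (TP+TN)/(TP+TN+FP+FN); sensitivity (recall) = TP/(TP+FN);
#' specificity = TN/(TN+FP); PPV = TP/(TP+FP); NPV = TN/(TN+FN). A metric
#' whose denominator is zero is undefined and reported as `NA`, never as 0.
#' Per-class accuracies (accuracy restricted to truly healthy / truly MCI
#' test subjects) equal specificity and sensitivity respectively.
#'
#' @param cc a [confusion_counts()] result.
#' @return named numeric: `accuracy`, `sensitivity`, `specificity`, `ppv`,
#'   `npv`, `acc_healthy`, `acc_mci`.
#' @export
fold_metrics <- function(cc) {
  stopifnot(inherits(cc, "confusion_counts"))
  tp <- cc[["TP"]]; fp <- cc[["FP"]]; tn <- cc[["TN"]]; fn <- cc[["FN"]]
  rate <- function(num, den) if (den == 0) NA_real_ else num / den
  sens <- rate(tp, tp + fn)
  spec <- rate(tn, tn + fp)
  c(accuracy = rate(tp + tn, tp + tn + fp + fn),
    sensitivity = sens,
    specificity = spec,
    ppv = rate(tp, tp + fp),
    npv = rate(tn, tn + fn),
    acc_healthy = spec,
    acc_mci = sens)
}

#' Evaluate a trained classifier on a test fold
#'
#' @param model a `drive_classifier`.
#' @param test_scores score matrix of the fold's test subjects.
#' @param test_labels their true statuses.
#' @return list with `counts` ([confusion_counts()]) and `metrics`
#'   ([fold_metrics()]).
#' @export
evaluate_fold <- function(model, test_scores, test_labels) {
  if (length(test_labels) == 0) stopf("test set is empty")
  pred <- predict(model, test_scores)
  cc <- confusion_counts(test_labels, pred)
  list(counts = cc, metrics = fold_metrics(cc), predictions = pred)
}
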