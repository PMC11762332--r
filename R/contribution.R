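#' Variance-weighted loading contribution of each feature
#'
#' For a fitted PCA with loadings matrix W (components x features, entries
#' \eqn{w_{ij}}) and explained-variance ratios \eqn{\gamma_i}, the
#' contribution of original feature j is
#' \deqn{\mathrm{contribution}_j = \sum_i |w_{ij}| \, \gamma_i,}
#' i.e., absolute loadings weighted by how much variance each retained
#' component explains, summed over the retained components.
#'
#' @param pp a fitted [fit_preprocessor()] result.
#' @return numeric vector of nonnegative scores, one per original feature.
#' @export
loading_contribution <- function(pp) {
  stopifnot(inherits(pp, "pca_preprocessor"))
  W <- pp$W
  gamma <- pp$gamma
  if (nrow(W) != length(gamma))
    stopf("dimension mismatch: %d loading rows vs %d variance ratios",
          nrow(W), length(gamma))
  as.numeric(colSums(abs(W) * gamma))
}

#' Aggregate per-fold contribution scores into a ranked table
#'
#' Element-wise sum of the per-fold score vectors, sorted from highest to
#' lowest. Ties are broken by feature index (schema order).
#'
#' @param per_fold_scores list of numeric score vectors, one per fold, all
#'   the same length.
#' @param feature_names optional feature names; defaults to the packaged
#'   26-feature schema when the length matches.
#' @return object of class `contribution_table`: data frame with
#'   `feature_index`, `feature_name`, `score`, `rank`, ordered by rank.
#' @export
aggregate_contributions <- function(per_fold_scores, feature_names = NULL) {
  if (length(per_fold_scores) == 0) stopf("need at least one fold score vector")
  lens <- lengths(per_fold_scores)
  if (length(unique(lens)) != 1)
    stopf("inconsistent score-vector lengths: %s",
          paste(unique(lens), collapse = ", "))
  total <- Reduce(`+`, per_fold_scores)
  p <- length(total)
  if (is.null(feature_names)) {
    feature_names <- if (p == 26) feature_schema()$name
                     else sprintf("feature_%02d", seq_len(p))
  }
  ord <- order(-total, seq_len(p))
  out <- data.frame(
    feature_index = ord,
    feature_name = feature_names[ord],
    score = total[ord],
    rank = seq_len(p),
    stringsAsFactors = FALSE
  )
  structure(out, class = c("contribution_table", "data.frame"))
}

#' Rank features by contribution across CV folds
#'
#' Computes the [loading_contribution()] of every per-fold PCA fitted during
#' [cross_validate()] and sums them across folds. The scores are reported
#' unnormalized; set `normalize = TRUE` for the share-of-total variant
#' (scores divided by their sum; an extension, clearly labeled in the
#' `normalized` attribute).
#'
#' @param cv a `drive_cv`.
#' @param normalize report scores divided by their total.
#' @return a `contribution_table`.
#' @export
feature_contribution <- function(cv, normalize = FALSE) {
  stopifnot(inherits(cv, "drive_cv"))
  scores <- lapply(cv$pca_models, loading_contribution)
  tab <- aggregate_contributions(scores)
  if (normalize) {
    tab$score <- tab$score / sum(tab$score)
    attr(tab, "normalized") <- TRUE
  } else {
    attr(tab, "normalized") <- FALSE
  }
  tab
}

#' @export
print.contribution_table <- function(x, ...) {
  cat(sprintf("<contribution_table> %d features%s\n", nrow(x),
              if (isTRUE(attr(x, "normalized"))) " (normalized)" else ""))
  print.data.frame(utils::head(x, 10), row.names = FALSE, digits = 4)
  if (nrow(x) > 10) cat(sprintf("  ... and %d more\n", nrow(x) - 10))
  invisible(x)
}

#' Contribution bar chart
#'
#' @param x a `contribution_table`.
#' @param ... passed to [graphics::barplot()].
#' @export
plot.contribution_table <- function(x, ...) {
  graphics::barplot(x$score, names.arg = x$feature_name, las = 2,
                    cex.names = 0.6, ylab = "Contribution score", ...)
  invisible(x)
}
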