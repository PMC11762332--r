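#' Fit the per-fold preprocessor: imputation, scaling, PCA
#'
#' All statistics are computed from training rows only, so no information
#' from a fold's test subjects leaks into the transform. Missing feature
#' values are imputed with the training-fold column mean, features are
#' z-scored with training mean/SD, and PCA is fitted on the scaled training
#' matrix. By default the first 5 principal components are retained
#' (configurable, or the smallest number reaching `variance_threshold`).
#'
#' @param x numeric training matrix (subjects x features), may contain `NA`.
#' @param n_components number of principal components to retain.
#' @param variance_threshold if non-`NULL`, overrides `n_components` with the
#'   smallest count whose cumulative explained-variance ratio reaches it.
#' @return object of class `pca_preprocessor`: `impute_means`, `center`,
#'   `scale`, `W` (loadings, components x features, unit-norm rows), `gamma`
#'   (explained-variance ratio per retained component), `n_components`.
#' @export
fit_preprocessor <- function(x, n_components = 5, variance_threshold = NULL) {
  x <- as.matrix(x)
  if (nrow(x) < 2) stopf("need at least 2 training subjects, got %d", nrow(x))

  impute_means <- colMeans(x, na.rm = TRUE)
  impute_means[!is.finite(impute_means)] <- 0
  for (j in seq_len(ncol(x))) x[is.na(x[, j]), j] <- impute_means[j]

  ctr <- colMeans(x)
  scl <- apply(x, 2, stats::sd)
  zero_var <- !is.finite(scl) | scl == 0
  if (any(zero_var)) {
    warnf("%d zero-variance feature(s); scale std clamped to 1", sum(zero_var))
    scl[zero_var] <- 1
  }
  xs <- sweep(sweep(x, 2, ctr), 2, scl, "/")

  pc <- stats::prcomp(xs, center = FALSE, scale. = FALSE)
  ev <- pc$sdev^2
  ratio <- ev / sum(ev)
  if (!is.null(variance_threshold)) {
    n_components <- which(cumsum(ratio) >= variance_threshold)[1]
    if (is.na(n_components)) n_components <- length(ratio)
  }
  ncomp <- min(n_components, ncol(pc$rotation))

  structure(
    list(impute_means = impute_means, center = ctr, scale = scl,
         W = t(pc$rotation[, seq_len(ncomp), drop = FALSE]),
         gamma = ratio[seq_len(ncomp)],
         n_components = ncomp, all_ratio = ratio),
    class = "pca_preprocessor"
  )
}

#' Apply a fitted preprocessor to new data
#'
#' @param pp a `pca_preprocessor`.
#' @param x numeric matrix (subjects x features), may contain `NA` (imputed
#'   with the training means).
#' @return score matrix (subjects x retained components).
#' @export
apply_preprocessor <- function(pp, x) {
  stopifnot(inherits(pp, "pca_preprocessor"))
  x <- as.matrix(x)
  if (ncol(x) != length(pp$center))
    stopf("feature count mismatch: got %d, preprocessor expects %d",
          ncol(x), length(pp$center))
  for (j in seq_len(ncol(x))) x[is.na(x[, j]), j] <- pp$impute_means[j]
  xs <- sweep(sweep(x, 2, pp$center), 2, pp$scale, "/")
  xs %*% t(pp$W)
}

#' @export
print.pca_preprocessor <- function(x, ...) {
  cat(sprintf("<pca_preprocessor> %d components, %.1f%% variance retained\n",
              x$n_components, 100 * sum(x$gamma)))
  invisible(x)
}
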