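#' Principal component analysis (SVD, mean-centred)
#'
#' Deterministic up to component sign; the sign is fixed so the
#' largest-magnitude loading element of each component is positive.
#'
#' @param X numeric matrix, samples x channels.
#' @param k number of components, `k <= min(n - 1, channels)`.
#' @return An object of class `pca_fit`: `center`, `loadings` (channels x
#'   k, orthonormal), `scores` (samples x k), `sdev` (per-component score
#'   sd, n-1 denominator, all `min(n-1, p)` of them), `explained`
#'   (variance fractions, non-increasing), `k`.
#' @export
fit_pca <- function(X, k) {
  X <- as.matrix(X)
  n <- nrow(X); p <- ncol(X)
  k <- as.integer(k)
  if (k < 1L || k > min(n - 1L, p)) {
    stop("k must satisfy 1 <= k <= min(n - 1, channels) = ", min(n - 1L, p))
  }
  center <- colMeans(X)
  Xc <- sweep(X, 2L, center, "-")
  sv <- svd(Xc)
  loadings <- sv$v[, seq_len(k), drop = FALSE]
  scores <- sv$u[, seq_len(k), drop = FALSE] %*%
    diag(sv$d[seq_len(k)], k, k)
  for (j in seq_len(k)) {
    i <- which.max(abs(loadings[, j]))
    if (loadings[i, j] < 0) {
      loadings[, j] <- -loadings[, j]
      scores[, j] <- -scores[, j]
    }
  }
  structure(
    list(center = center, loadings = loadings, scores = scores,
         sdev = sv$d / sqrt(n - 1L),
         explained = sv$d^2 / sum(sv$d^2), k = k, n = n),
    class = "pca_fit"
  )
}

#' @export
print.pca_fit <- function(x, ...) {
  cat("<pca_fit> ", x$k, " component(s); explained variance: ",
      paste(sprintf("%.1f%%", 100 * x$explained[seq_len(x$k)]),
            collapse = ", "), "\n", sep = "")
  invisible(x)
}

#' Project new data onto a fitted PCA
#' @param object a `pca_fit`.
#' @param newdata samples x channels matrix on the training grid.
#' @param ... unused.
#' @return scores matrix (samples x k).
#' @export
predict.pca_fit <- function(object, newdata, ...) {
  newdata <- as.matrix(newdata)
  if (ncol(newdata) != length(object$center)) {
    stop("newdata has ", ncol(newdata), " channels; model expects ",
         length(object$center))
  }
  sweep(newdata, 2L, object$center, "-") %*% object$loadings
}

#' Smallest number of components reaching a variance target
#' @param model a `pca_fit`.
#' @param target cumulative explained-variance fraction (default 0.95).
#' @return integer component count (capped at the fitted `k`).
#' @export
choose_k_explained <- function(model, target = 0.95) {
  stopifnot(inherits(model, "pca_fit"))
  k <- which(cumsum(model$explained) >= target)[1L]
  if (is.na(k)) k <- model$k
  min(k, model$k)
}

#' Mahalanobis outlier screen in PCA score space
#'
#' Squared Mahalanobis distance over the first k components,
#' `d^2 = sum_j score_j^2 / lambda_j` with `lambda_j` the component
#' variance, compared against a chi-square(k) quantile.
#'
#' @param model a `pca_fit`.
#' @param threshold_quantile chi-square quantile in (0, 1), default 0.975.
#' @return An `outlier_report`: `distance2`, `threshold` (on the squared
#'   scale), `quantile`, `k`, `removed`/`kept` flags.
#' @export
mahalanobis_screen <- function(model, threshold_quantile = 0.975) {
  stopifnot(inherits(model, "pca_fit"))
  if (threshold_quantile <= 0 || threshold_quantile >= 1) {
    stop("threshold_quantile must lie in (0, 1)")
  }
  lambda <- model$sdev[seq_len(model$k)]^2
  if (any(lambda <= .Machine$double.eps * lambda[1L])) {
    stop("zero eigenvalue among the first ", model$k,
         " components; reduce k")
  }
  d2 <- rowSums(sweep(model$scores^2, 2L, lambda, "/"))
  threshold <- stats::qchisq(threshold_quantile, df = model$k)
  removed <- d2 > threshold
  structure(
    list(distance2 = d2, threshold = threshold,
         quantile = threshold_quantile, k = model$k,
         removed = removed, kept = !removed),
    class = "outlier_report"
  )
}

#' @export
print.outlier_report <- function(x, ...) {
  cat("<outlier_report> ", sum(x$removed), "/", length(x$removed),
      " spectra flagged (chi-square(", x$k, ") quantile ",
      x$quantile, ", threshold d2 > ", format(x$threshold, digits = 4),
      ")\n", sep = "")
  invisible(x)
}
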