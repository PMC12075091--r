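#' Principal component regression (multi-response)
#'
#' Regresses each response on the first k PCA scores of the centred
#' predictor matrix and maps the coefficients back to channel space.  With
#' `k = rank(X)` the predictions coincide with ordinary least squares on
#' centred data.
#'
#' @param X numeric matrix, samples x channels.
#' @param Y numeric matrix or vector of responses (e.g. mM of each analyte
#'   in a mixture); a vector is treated as a single response.
#' @param k number of retained principal components.
#' @return A `pcr_fit` with `b` (channels x responses regression vectors),
#'   `intercept` (per response), the underlying `pca_fit`, score-space
#'   coefficients `gamma`, fitted values and residuals.
#' @export
fit_pcr <- function(X, Y, k) {
  X <- as.matrix(X)
  Y <- as.matrix(Y)
  if (nrow(X) != nrow(Y)) stop("X and Y must have the same number of rows")
  k <- as.integer(k)
  pca <- fit_pca(X, k = min(nrow(X) - 1L, ncol(X)))
  d <- pca$sdev * sqrt(pca$n - 1L)
  if (k < 1L || k > sum(d > d[1L] * 1e-10)) {
    stop("k = ", k, " exceeds the rank of centred X (",
         sum(d > d[1L] * 1e-10), ")")
  }
  Tm <- pca$scores[, seq_len(k), drop = FALSE]
  y_center <- colMeans(Y)
  Yc <- sweep(Y, 2L, y_center, "-")
  # scores are orthogonal, so the regression decouples per component
  gamma <- crossprod(Tm, Yc) / colSums(Tm^2)
  b <- pca$loadings[, seq_len(k), drop = FALSE] %*% gamma
  intercept <- y_center - drop(crossprod(b, pca$center))
  fitted <- sweep(X %*% b, 2L, intercept, "+")
  structure(
    list(b = b, intercept = intercept, gamma = gamma, k = k, pca = pca,
         x_center = pca$center, y_center = y_center,
         fitted.values = fitted, residuals = Y - fitted,
         response_names = colnames(Y), call = match.call()),
    class = "pcr_fit"
  )
}

#' @export
print.pcr_fit <- function(x, ...) {
  cat("<pcr_fit> ", x$k, " component(s), ", nrow(x$b), " channels, ",
      ncol(x$b), " response(s)\n", sep = "")
  rmse <- sqrt(colMeans(x$residuals^2))
  cat("  calibration RMSE: ",
      paste(format(rmse, digits = 4), collapse = ", "), "\n", sep = "")
  invisible(x)
}

#' @export
coef.pcr_fit <- function(object, ...) {
  structure(object$b, intercept = object$intercept)
}

#' Predict mixture concentrations from a fitted PCR model
#' @param object a `pcr_fit`.
#' @param newdata samples x channels matrix on the training grid.
#' @param ... unused.
#' @return matrix of predictions, samples x responses.
#' @export
predict.pcr_fit <- function(object, newdata, ...) {
  newdata <- as.matrix(newdata)
  if (ncol(newdata) != nrow(object$b)) {
    stop("newdata has ", ncol(newdata), " channels; model expects ",
         nrow(object$b))
  }
  sweep(newdata %*% object$b, 2L, object$intercept, "+")
}

#' @export
residuals.pcr_fit <- function(object, ...) object$residuals

#' @export
fitted.pcr_fit <- function(object, ...) object$fitted.values
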