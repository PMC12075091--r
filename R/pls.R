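#' NIPALS partial least squares regression (single response)
#'
#' Classic PLS1 with deflation: at each latent variable the weight vector
#' is `w = X'y / ||X'y||`, scores `t = X w`, y-loading `q = t'y / t't`,
#' X-loading `p = X't / t't`, then X (and y) are deflated.  The channel
#' regression vector is assembled as `b = W (P'W)^-1 q`.  Deterministic up
#' to sign; the sign of each weight vector is fixed so its
#' largest-magnitude element is positive.
#'
#' @param X numeric matrix, samples x channels.
#' @param y numeric response (e.g. concentration in mM).
#' @param n_lv number of latent variables.
#' @return A `plsr_fit` with weights `W`, loadings `P`, scores `T`,
#'   y-loadings `q`, regression vector `b`, `intercept`, centres, fitted
#'   values and residuals.
#' @export
fit_plsr <- function(X, y, n_lv) {
  X <- as.matrix(X)
  y <- as.numeric(y)
  n <- nrow(X); p <- ncol(X)
  if (n != length(y)) stop("nrow(X) must equal length(y)")
  if (stats::sd(y) == 0) stop("response has zero variance")
  n_lv <- as.integer(n_lv)
  if (n_lv < 1L || n_lv > min(n - 1L, p)) {
    stop("n_lv must satisfy 1 <= n_lv <= min(n - 1, channels) = ",
         min(n - 1L, p))
  }
  x_center <- colMeans(X)
  y_center <- mean(y)
  Xd <- sweep(X, 2L, x_center, "-")
  yd <- y - y_center
  W <- matrix(0, p, n_lv); P <- matrix(0, p, n_lv)
  Tm <- matrix(0, n, n_lv); qv <- numeric(n_lv)
  for (a in seq_len(n_lv)) {
    w <- drop(crossprod(Xd, yd))
    nw <- sqrt(sum(w^2))
    if (nw < 1e-12 * max(1, sqrt(sum(yd^2)))) {
      stop("n_lv = ", n_lv, " exceeds the effective rank of centred X ",
           "(covariance vanished at latent variable ", a, ")")
    }
    w <- w / nw
    i <- which.max(abs(w))
    if (w[i] < 0) w <- -w
    t_vec <- drop(Xd %*% w)
    tt <- sum(t_vec^2)
    q_a <- sum(t_vec * yd) / tt
    p_vec <- drop(crossprod(Xd, t_vec)) / tt
    Xd <- Xd - tcrossprod(t_vec, p_vec)
    yd <- yd - q_a * t_vec
    W[, a] <- w; P[, a] <- p_vec; Tm[, a] <- t_vec; qv[a] <- q_a
  }
  b <- drop(W %*% solve(crossprod(P, W), qv))
  intercept <- y_center - sum(x_center * b)
  fitted <- drop(X %*% b) + intercept
  structure(
    list(W = W, P = P, T = Tm, q = qv, b = b, intercept = intercept,
         x_center = x_center, y_center = y_center, n_lv = n_lv,
         fitted.values = fitted, residuals = y - fitted, y = y,
         call = match.call()),
    class = "plsr_fit"
  )
}

#' @export
print.plsr_fit <- function(x, ...) {
  cat("<plsr_fit> ", x$n_lv, " latent variable(s), ",
      length(x$b), " channels\n", sep = "")
  cat("  calibration RMSE: ",
      format(sqrt(mean(x$residuals^2)), digits = 4), "\n", sep = "")
  invisible(x)
}

#' @export
summary.plsr_fit <- function(object, ...) {
  tt <- colSums(object$T^2)
  y_var <- object$q^2 * tt
  y_tot <- sum((object$y - mean(object$y))^2)
  per_lv <- data.frame(
    lv = seq_len(object$n_lv),
    y_variance_fraction = y_var / y_tot
  )
  m <- regression_metrics(object$y, object$fitted.values)
  structure(list(per_lv = per_lv, rmse_cal = m$rmse, r2_cal = m$r2,
                 n_lv = object$n_lv),
            class = "summary.plsr_fit")
}

#' @export
print.summary.plsr_fit <- function(x, ...) {
  cat("PLS regression, ", x$n_lv, " latent variable(s)\n", sep = "")
  cat(sprintf("  calibration RMSE %.4g, R2 %.4f\n", x$rmse_cal, x$r2_cal))
  print(x$per_lv, row.names = FALSE)
  invisible(x)
}

#' @export
coef.plsr_fit <- function(object, ...) {
  structure(object$b, intercept = object$intercept)
}

#' Predict concentrations from a fitted PLS model
#' @param object a `plsr_fit`.
#' @param newdata samples x channels matrix on the training grid (same
#'   transform chain applied as in training).
#' @param ... unused.
#' @return numeric predictions.
#' @export
predict.plsr_fit <- function(object, newdata, ...) {
  newdata <- as.matrix(newdata)
  if (ncol(newdata) != length(object$b)) {
    stop("newdata has ", ncol(newdata), " channels; model expects ",
         length(object$b))
  }
  drop(newdata %*% object$b) + object$intercept
}

#' @export
residuals.plsr_fit <- function(object, ...) object$residuals

#' @export
fitted.plsr_fit <- function(object, ...) object$fitted.values
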