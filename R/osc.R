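#' Orthogonal signal correction (Wold-style)
#'
#' Iteratively extracts score vectors that capture large X-variance while
#' being orthogonal to the response, and deflates X by them, so the
#' subsequent regression is not distracted by response-irrelevant
#' structure (scatter, baseline families).  Each removed component stores
#' a weight vector `w` and loading `p`; new spectra are corrected with
#' `t = X w; X <- X - t p'`.
#'
#' @param X numeric matrix, samples x channels (centred internally; the
#'   centre is stored and re-used when correcting new data).
#' @param y numeric response vector (centred internally).
#' @param n_components number of components to remove (default 1; 0 is a
#'   no-op).
#' @param tol relative convergence tolerance on the score vector.
#' @param max_iter maximum inner iterations per component.
#' @param weight_energy fraction of X variance spanned by the subspace in
#'   which the weight vector is estimated (default 0.99).  Estimating `w`
#'   in the full column space reproduces the score vector exactly, noise
#'   directions included, and the overfitted weights then inject noise
#'   when the correction is applied to new spectra; restricting the
#'   pseudo-inverse to the dominant-variance subspace is the standard
#'   regularization of the weight step.
#' @return An `osc_fit`: per-component `w`, `p`, `t`, iteration counts and
#'   orthogonality residuals `|t'y| / (||t|| ||y||)`, plus the training
#'   centres.
#' @export
fit_osc <- function(X, y, n_components = 1L, tol = 1e-10, max_iter = 100L,
                    weight_energy = 0.99) {
  X <- as.matrix(X)
  y <- as.numeric(y)
  if (nrow(X) != length(y)) stop("nrow(X) must equal length(y)")
  n_components <- as.integer(n_components)
  if (n_components < 0L) stop("n_components must be >= 0")
  x_center <- colMeans(X)
  y_center <- mean(y)
  Xd <- sweep(X, 2L, x_center, "-")
  yc <- y - y_center
  comps <- list()
  if (n_components > 0L && sum(yc^2) == 0) {
    stop("response has zero variance; OSC orthogonality is undefined")
  }
  for (comp in seq_len(n_components)) {
    sv <- svd(Xd)
    energy_before <- c(0, cumsum(sv$d^2)[-length(sv$d)]) / sum(sv$d^2)
    pos <- sv$d > sv$d[1L] * 1e-10 & energy_before < weight_energy
    t_vec <- sv$u[, 1L] * sv$d[1L]
    iter <- 0L
    repeat {
      iter <- iter + 1L
      t_orth <- t_vec - yc * sum(yc * t_vec) / sum(yc^2)
      if (sqrt(sum(t_orth^2)) < 1e-14 * sqrt(sum(t_vec^2))) {
        # score fully aligned with y: restart from the next PC
        t_orth <- sv$u[, 2L] * sv$d[2L]
        t_orth <- t_orth - yc * sum(yc * t_orth) / sum(yc^2)
      }
      # project back into the column space of X through the pseudo-inverse
      w <- sv$v[, pos, drop = FALSE] %*%
        (crossprod(sv$u[, pos, drop = FALSE], t_orth) / sv$d[pos])
      w <- w / sqrt(sum(w^2))
      t_new <- drop(Xd %*% w)
      delta <- sqrt(sum((t_new - t_vec)^2)) / sqrt(sum(t_new^2))
      t_vec <- t_new
      if (delta < tol) break
      if (iter >= max_iter) {
        resid <- abs(sum(t_vec * yc)) /
          (sqrt(sum(t_vec^2)) * sqrt(sum(yc^2)))
        stop("OSC did not converge after ", max_iter,
             " iterations (last orthogonality residual ",
             format(resid, digits = 3), ")")
      }
    }
    # final exact orthogonalization before deflation
    t_vec <- t_vec - yc * sum(yc * t_vec) / sum(yc^2)
    p_vec <- drop(crossprod(Xd, t_vec)) / sum(t_vec^2)
    Xd <- Xd - tcrossprod(t_vec, p_vec)
    comps[[comp]] <- list(
      w = drop(w), p = p_vec, t = t_vec, iterations = iter,
      orthogonality = abs(sum(t_vec * yc)) /
        (sqrt(sum(t_vec^2)) * sqrt(sum(yc^2)))
    )
  }
  structure(
    list(components = comps, n_components = n_components,
         x_center = x_center, y_center = y_center, tol = tol),
    class = "osc_fit"
  )
}

#' @export
print.osc_fit <- function(x, ...) {
  cat("<osc_fit> ", x$n_components, " removed component(s)\n", sep = "")
  for (i in seq_along(x$components)) {
    c_i <- x$components[[i]]
    cat(sprintf("  [%d] %d iteration(s), orthogonality residual %.2e\n",
                i, c_i$iterations, c_i$orthogonality))
  }
  invisible(x)
}

#' Apply a fitted orthogonal signal correction to spectra
#'
#' @param osc an `osc_fit`.
#' @param X samples x channels matrix on the training grid.
#' @return The corrected matrix (same scale as the input).
#' @export
apply_osc <- function(osc, X) {
  stopifnot(inherits(osc, "osc_fit"))
  X <- as.matrix(X)
  if (ncol(X) != length(osc$x_center)) {
    stop("X has ", ncol(X), " channels; OSC model expects ",
         length(osc$x_center))
  }
  Xc <- sweep(X, 2L, osc$x_center, "-")
  for (comp in osc$components) {
    t_new <- drop(Xc %*% comp$w)
    Xc <- Xc - tcrossprod(t_new, comp$p)
  }
  sweep(Xc, 2L, osc$x_center, "+")
}
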