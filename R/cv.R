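#' Prediction metrics
#'
#' @param y_true observed values (length >= 2, non-constant).
#' @param y_pred predicted values.
#' @return list with `rmse` (`sqrt(mean((y_pred - y_true)^2))`) and `r2`
#'   (`1 - SSres/SStot`).
#' @export
regression_metrics <- function(y_true, y_pred) {
  y_true <- as.numeric(y_true); y_pred <- as.numeric(y_pred)
  if (length(y_true) != length(y_pred)) stop("length mismatch")
  if (length(y_true) < 2L) stop("need at least 2 observations")
  ss_tot <- sum((y_true - mean(y_true))^2)
  if (ss_tot == 0) stop("R2 is undefined for constant y_true")
  ss_res <- sum((y_pred - y_true)^2)
  list(rmse = sqrt(mean((y_pred - y_true)^2)), r2 = 1 - ss_res / ss_tot)
}

#' Cross-validation fold assignment
#'
#' @param n number of samples.
#' @param scheme `"loo"` (leave-one-out) or `"lko"`
#'   (leave-k-spectra-out with a seeded random partition).
#' @param k_out fold size for `"lko"` (default 5).
#' @param seed RNG seed for the `"lko"` partition.
#' @return list of integer index vectors, one per fold; every sample
#'   appears in exactly one fold.
#' @export
make_folds <- function(n, scheme = c("loo", "lko"), k_out = 5L, seed = 1L) {
  scheme <- match.arg(scheme)
  if (scheme == "loo") return(as.list(seq_len(n)))
  k_out <- as.integer(k_out)
  if (k_out >= n) stop("k_out must be smaller than the number of samples")
  if (k_out < 1L) stop("k_out must be >= 1")
  perm <- with_seed(seed, sample.int(n))
  split(perm, ceiling(seq_along(perm) / k_out))
}

#' Generic cross-validation of a fitting pipeline
#'
#' Every response-using step (OSC, column scaling, ...) must live inside
#' `fit` so it is re-estimated on each training fold; `fit` receives the
#' training block and must return an object that `predict_fn` can apply to
#' the held-out block.
#'
#' @param X samples x channels matrix (response-free preprocessing already
#'   applied).
#' @param y response vector.
#' @param fit function(X_train, y_train) -> model.
#' @param predict_fn function(model, X_test) -> predictions (default:
#'   [predict()]).
#' @param scheme,k_out,seed see [make_folds()].
#' @return A `cv_result`: pooled held-out `predictions` (each sample
#'   predicted exactly once), `rmse`, `r2`, `folds`, `scheme`, `seed`.
#' @export
cross_validate <- function(X, y, fit, predict_fn = stats::predict,
                           scheme = c("loo", "lko"), k_out = 5L,
                           seed = 1L) {
  scheme <- match.arg(scheme)
  X <- as.matrix(X); y <- as.numeric(y)
  n <- nrow(X)
  folds <- make_folds(n, scheme, k_out, seed)
  preds <- rep(NA_real_, n)
  for (fold in folds) {
    model <- fit(X[-fold, , drop = FALSE], y[-fold])
    preds[fold] <- as.numeric(predict_fn(model, X[fold, , drop = FALSE]))
  }
  m <- regression_metrics(y, preds)
  structure(
    list(predictions = preds, rmse = m$rmse, r2 = m$r2, folds = folds,
         scheme = scheme, k_out = if (scheme == "lko") k_out else NA_integer_,
         seed = seed, y = y),
    class = "cv_result"
  )
}

#' @export
print.cv_result <- function(x, ...) {
  cat("<cv_result> ", x$scheme, " (", length(x$folds), " folds): RMSE ",
      format(x$rmse, digits = 4), ", R2 ", format(x$r2, digits = 4),
      "\n", sep = "")
  invisible(x)
}

# Regression vector for every latent-variable count 1..A from one NIPALS
# run: b_a = W_a (P_a' W_a)^-1 q_a on the leading sub-blocks.
pls_b_per_lv <- function(model) {
  A <- model$n_lv
  vapply(seq_len(A), function(a) {
    Wa <- model$W[, seq_len(a), drop = FALSE]
    Pa <- model$P[, seq_len(a), drop = FALSE]
    drop(Wa %*% solve(crossprod(Pa, Wa), model$q[seq_len(a)]))
  }, numeric(nrow(model$W)))
}

#' Cross-validated PLS with per-fold OSC and latent-variable selection
#'
#' Within each fold: fit OSC on the training block (if requested), correct
#' both blocks, fit one NIPALS model at the maximum latent-variable count
#' and collect held-out predictions for every count 1..max_lv in a single
#' pass.  The reported model size minimizes the pooled RMSECV.
#'
#' @param X samples x channels matrix.
#' @param y response vector (mM).
#' @param max_lv largest latent-variable count to consider (default 10).
#' @param osc_components OSC components removed per fold (default 1; 0
#'   disables OSC).
#' @param scheme,k_out,seed see [make_folds()].
#' @return A `cv_plsr_result`: `rmsecv` and `r2cv` per latent-variable
#'   count, the selected `n_lv`, and a `cv_result` at the selected count.
#' @export
cv_plsr <- function(X, y, max_lv = 10L, osc_components = 1L,
                    scheme = c("loo", "lko"), k_out = 5L, seed = 1L) {
  scheme <- match.arg(scheme)
  X <- as.matrix(X); y <- as.numeric(y)
  n <- nrow(X)
  max_lv <- min(as.integer(max_lv), n - 2L, ncol(X))
  folds <- make_folds(n, scheme, k_out, seed)
  preds <- matrix(NA_real_, n, max_lv)
  for (fold in folds) {
    Xtr <- X[-fold, , drop = FALSE]; ytr <- y[-fold]
    Xte <- X[fold, , drop = FALSE]
    if (osc_components > 0L) {
      osc <- fit_osc(Xtr, ytr, n_components = osc_components)
      Xtr <- apply_osc(osc, Xtr)
      Xte <- apply_osc(osc, Xte)
    }
    model <- fit_plsr(Xtr, ytr, n_lv = max_lv)
    B <- pls_b_per_lv(model)
    icept <- model$y_center - drop(crossprod(B, model$x_center))
    preds[fold, ] <- sweep(Xte %*% B, 2L, icept, "+")
  }
  rmsecv <- sqrt(colMeans((preds - y)^2))
  ss_tot <- sum((y - mean(y))^2)
  r2cv <- 1 - colSums((preds - y)^2) / ss_tot
  best <- which.min(rmsecv)
  cv <- structure(
    list(predictions = preds[, best], rmse = rmsecv[best], r2 = r2cv[best],
         folds = folds, scheme = scheme,
         k_out = if (scheme == "lko") k_out else NA_integer_,
         seed = seed, y = y),
    class = "cv_result"
  )
  structure(
    list(rmsecv = rmsecv, r2cv = r2cv, n_lv = best, cv = cv,
         osc_components = osc_components, predictions_per_lv = preds),
    class = "cv_plsr_result"
  )
}

#' @export
print.cv_plsr_result <- function(x, ...) {
  cat("<cv_plsr_result> best n_lv = ", x$n_lv, " (RMSECV ",
      format(x$cv$rmse, digits = 4), ", R2cv ",
      format(x$cv$r2, digits = 4), ")\n", sep = "")
  invisible(x)
}

#' Cross-validated PCR with component-count selection
#'
#' Same single-pass strategy as [cv_plsr()]: one PCA per fold, held-out
#' predictions for every component count 1..max_pc, component count chosen
#' by pooled RMSECV summed over responses.
#'
#' @param X samples x channels matrix.
#' @param Y responses matrix (or vector).
#' @param max_pc largest component count considered.
#' @param scheme,k_out,seed see [make_folds()].
#' @return A `cv_pcr_result`: per-count pooled `rmsecv`, selected `k`,
#'   held-out predictions and per-response metrics at the selected count.
#' @export
cv_pcr <- function(X, Y, max_pc = 10L, scheme = c("loo", "lko"),
                   k_out = 5L, seed = 1L) {
  scheme <- match.arg(scheme)
  X <- as.matrix(X); Y <- as.matrix(Y)
  n <- nrow(X)
  max_pc <- min(as.integer(max_pc), n - 2L, ncol(X))
  folds <- make_folds(n, scheme, k_out, seed)
  preds <- array(NA_real_, c(n, ncol(Y), max_pc))
  for (fold in folds) {
    Xtr <- X[-fold, , drop = FALSE]; Ytr <- Y[-fold, , drop = FALSE]
    Xte <- X[fold, , drop = FALSE]
    pca <- fit_pca(Xtr, k = min(nrow(Xtr) - 1L, ncol(Xtr)))
    d <- pca$sdev * sqrt(pca$n - 1L)
    rank_tr <- sum(d > d[1L] * 1e-10)
    y_center <- colMeans(Ytr)
    Yc <- sweep(Ytr, 2L, y_center, "-")
    Tte <- predict(pca, Xte)
    for (k in seq_len(min(max_pc, rank_tr))) {
      Tm <- pca$scores[, seq_len(k), drop = FALSE]
      gamma <- crossprod(Tm, Yc) / colSums(Tm^2)
      preds[fold, , k] <- sweep(Tte[, seq_len(k), drop = FALSE] %*% gamma,
                                2L, y_center, "+")
    }
    if (rank_tr < max_pc) {
      for (k in seq(rank_tr + 1L, max_pc)) {
        preds[fold, , k] <- preds[fold, , rank_tr]
      }
    }
  }
  rmsecv <- vapply(seq_len(max_pc), function(k) {
    sqrt(mean((preds[, , k] - Y)^2))
  }, 0)
  best <- which.min(rmsecv)
  per_response <- lapply(seq_len(ncol(Y)), function(j) {
    regression_metrics(Y[, j], preds[, j, best])
  })
  names(per_response) <- colnames(Y)
  structure(
    list(rmsecv = rmsecv, k = best,
         predictions = preds[, , best, drop = TRUE],
         per_response = per_response, folds = folds, scheme = scheme,
         seed = seed, Y = Y),
    class = "cv_pcr_result"
  )
}

#' @export
print.cv_pcr_result <- function(x, ...) {
  cat("<cv_pcr_result> best k = ", x$k, "\n", sep = "")
  for (nm in names(x$per_response)) {
    cat(sprintf("  %s: RMSE %.4g, R2 %.4f\n", nm,
                x$per_response[[nm]]$rmse, x$per_response[[nm]]$r2))
  }
  invisible(x)
}
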