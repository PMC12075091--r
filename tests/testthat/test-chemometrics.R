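test_that("PCA recovers exact low-rank structure", {
  set.seed(21)
  u <- rnorm(15)
  line <- outer(u, c(1, -2, 0.5)) + matrix(1:3, 15, 3, byrow = TRUE)
  pca <- fit_pca(line, 2)
  expect_gt(pca$explained[1], 1 - 1e-10)
  # reconstruction with all components recovers X
  X <- matrix(rnorm(15 * 4), 15, 4)
  full <- fit_pca(X, 4)
  rec <- sweep(full$scores %*% t(full$loadings), 2, full$center, "+")
  expect_equal(rec, X, tolerance = 1e-8)
  # scores are the centred projections
  expect_equal(full$scores,
               sweep(X, 2, full$center, "-") %*% full$loadings,
               tolerance = 1e-10)
  # orthonormal loadings
  expect_equal(crossprod(full$loadings), diag(4), tolerance = 1e-8)
  expect_error(fit_pca(X, 15), "k must satisfy")
})

test_that("Mahalanobis screen is centred, symmetric and finds outliers", {
  # symmetric two-cluster data: equal distances
  X <- rbind(matrix(c(1, 0, -1, 0), 2, 2, byrow = TRUE),
             matrix(c(0, 1, 0, -1), 2, 2, byrow = TRUE))
  pca <- fit_pca(X, 2)
  rep_ <- mahalanobis_screen(pca, 0.975)
  expect_equal(max(rep_$distance2) - min(rep_$distance2), 0,
               tolerance = 1e-10)
  # a sample sitting at the centroid has distance zero
  X2 <- rbind(X, colMeans(X))
  d2 <- mahalanobis_screen(fit_pca(X2, 2), 0.975)$distance2
  expect_equal(d2[5], 0, tolerance = 1e-12)

  # injected spikes dominate every clean spectrum and are all flagged
  g <- generate_spectra_set(small_design(reps = 10L, seed = 31L))
  out <- inject_outliers(g$set, 0.05, magnitude = 0.3, seed = 5L)
  pcao <- fit_pca(out$set$absorbance,
                  choose_k_explained(fit_pca(out$set$absorbance, 10L)))
  scr <- mahalanobis_screen(pcao, 0.975)
  expect_gt(min(scr$distance2[out$flags]), max(scr$distance2[!out$flags]))
  expect_true(all(scr$removed[out$flags]))
})

test_that("OSC components are orthogonal to the response", {
  set.seed(32)
  X <- matrix(rnorm(40 * 20), 40, 20)
  y <- drop(X %*% rnorm(20)) + rnorm(40, 0, 0.1)
  osc <- fit_osc(X, y, n_components = 2L)
  yc <- y - mean(y)
  for (comp in osc$components) {
    expect_lte(abs(sum(comp$t * yc)),
               1e-8 * sqrt(sum(comp$t^2)) * sqrt(sum(yc^2)))
  }
  # zero components is the identity
  osc0 <- fit_osc(X, y, n_components = 0L)
  expect_equal(apply_osc(osc0, X), X)
})

test_that("OSC removes response-orthogonal variance, not signal", {
  # y proportional to the top principal component: the removed component
  # must carry the orthogonal structure, leaving y predictable with 1 LV
  set.seed(33)
  u <- rnorm(30); v <- rnorm(12)
  X <- outer(u, v) + matrix(rnorm(30 * 12, 0, 1e-3), 30, 12)
  y <- u * sqrt(sum(v^2))
  osc <- fit_osc(X, y, 1L)
  m <- fit_plsr(apply_osc(osc, X), y, 1L)
  expect_lt(sqrt(mean(residuals(m)^2)), 5e-3)
  # adding the removed component to a spectrum does not move predictions
  # (through the OSC-corrected prediction path)
  x_new <- matrix(X[4, ] + 3 * osc$components[[1]]$p, 1)
  expect_equal(unname(predict(m, apply_osc(osc, x_new))),
               unname(predict(m, apply_osc(osc, X[4, , drop = FALSE]))),
               tolerance = 1e-6)
})

test_that("full-rank NIPALS PLS matches the least-squares oracle", {
  set.seed(34)
  X <- matrix(rnorm(20 * 8), 20, 8)
  y <- drop(X %*% rnorm(8)) + rnorm(20, 0, 0.2)
  oracle <- ols_oracle(X, y)
  m <- fit_plsr(X, y, n_lv = 8L)
  expect_equal(fitted(m), oracle$fitted, tolerance = 1e-6)
  expect_equal(unname(coef(m))[seq_len(8)], oracle$b, tolerance = 1e-6,
               ignore_attr = TRUE)
  # scores mutually orthogonal; b-route equals the deflation route
  G <- crossprod(m$T)
  expect_equal(G, diag(diag(G)), tolerance = 1e-8)
  seq_fit <- m$y_center + drop(m$T %*% m$q)
  expect_equal(seq_fit, fitted(m), tolerance = 1e-8)
})

test_that("PLS handles exact rank-1 problems and symmetry", {
  set.seed(35)
  t1 <- rnorm(12); p1 <- rnorm(6)
  X <- outer(t1, p1)
  y <- 2 * t1
  m <- fit_plsr(X, y, 1L)
  expect_lt(sqrt(mean(residuals(m)^2)), 1e-10)
  # permuting channels permutes b and leaves predictions unchanged
  X2 <- matrix(rnorm(20 * 5), 20, 5)
  y2 <- drop(X2 %*% rnorm(5)) + rnorm(20, 0, 0.1)
  perm <- c(3, 5, 1, 4, 2)
  m1 <- fit_plsr(X2, y2, 3L)
  m2 <- fit_plsr(X2[, perm], y2, 3L)
  expect_equal(m2$b, m1$b[perm], tolerance = 1e-10)
  expect_equal(predict(m2, X2[, perm]), predict(m1, X2),
               tolerance = 1e-10)
  expect_error(fit_plsr(X2, rep(1, 20), 2L), "zero variance")
  # the column-mean spectrum predicts the mean response
  expect_equal(drop(predict(m1, rbind(colMeans(X2)))), mean(y2),
               tolerance = 1e-10)
  expect_equal(predict(m1, X2), fitted(m1))
})

test_that("PCR matches OLS at full rank and recovers exact mixtures", {
  set.seed(36)
  X <- matrix(rnorm(20 * 8), 20, 8)
  y <- drop(X %*% rnorm(8)) + rnorm(20, 0, 0.2)
  oracle <- ols_oracle(X, y)
  pcr <- fit_pcr(X, y, k = 8L)
  expect_equal(drop(fitted(pcr)), oracle$fitted, tolerance = 1e-6)
  # single response at full rank: PCR = PLS = OLS
  pls <- fit_plsr(X, y, 8L)
  expect_equal(drop(fitted(pcr)), fitted(pls), tolerance = 1e-6)
  expect_error(fit_pcr(X, y, k = 9L), "rank")

  # two orthogonal signatures, zero noise, the paired redox design
  # (GSSG = 5 - GSH/2): centred X is rank 1, and one component recovers
  # both analytes exactly
  grid <- seq_len(40)
  s1 <- exp(-0.5 * ((grid - 10) / 2)^2)
  s2 <- exp(-0.5 * ((grid - 30) / 2)^2)
  conc <- cbind(GSH = 1:9, GSSG = (10 - 1:9) / 2)
  Xm <- conc %*% rbind(s1, s2)
  pm <- fit_pcr(Xm, conc, k = 1L)
  expect_lt(max(abs(residuals(pm))), 1e-8)
  # an unpaired (full-rank) design needs and supports two components
  conc2 <- cbind(GSH = c(1, 2, 3, 4, 5), GSSG = c(5, 3, 4, 1, 2))
  pm2 <- fit_pcr(conc2 %*% rbind(s1, s2), conc2, k = 2L)
  expect_lt(max(abs(residuals(pm2))), 1e-8)
})

test_that("metrics follow their definitions", {
  m <- regression_metrics(c(0, 2), c(1, 1))
  expect_equal(m$rmse, 1)
  expect_equal(m$r2, 0)
  m2 <- regression_metrics(c(1, 2, 3), c(1, 2, 4))
  expect_equal(m2$rmse, sqrt(1 / 3))
  expect_equal(m2$r2, 0.5)
  m3 <- regression_metrics(1:5, 1:5)
  expect_equal(m3$rmse, 0); expect_equal(m3$r2, 1)
  expect_error(regression_metrics(c(1, 1), c(1, 2)), "constant")
})

test_that("fold construction covers each sample exactly once", {
  loo <- make_folds(7, "loo")
  expect_length(loo, 7L)
  expect_identical(sort(unlist(loo)), 1:7)
  l5 <- make_folds(25, "lko", k_out = 5L, seed = 2L)
  expect_length(l5, 5L)
  expect_true(all(lengths(l5) == 5L))
  expect_identical(sort(unname(unlist(l5))), 1:25)
  expect_error(make_folds(5, "lko", k_out = 5L), "smaller")
})

test_that("cross-validation of a noise-free model is exact", {
  set.seed(37)
  t1 <- rnorm(20); p1 <- rnorm(10)
  X <- outer(t1, p1); y <- 3 * t1 + 1
  cv <- cross_validate(X, y, fit = function(Xt, yt) fit_plsr(Xt, yt, 1L),
                       scheme = "loo")
  expect_length(cv$folds, 20L)
  expect_lt(cv$rmse, 1e-8)
  expect_false(anyNA(cv$predictions))
})

test_that("regression-vector peaks are found, signed and filtered", {
  grid <- seq(1300, 1600, 2)
  b <- exp(-0.5 * ((grid - 1362) / 5)^2) -
    0.6 * exp(-0.5 * ((grid - 1450) / 20)^2)
  pk <- regression_vector_peaks(b, grid = grid)
  expect_equal(pk$wavelength[1], 1362)
  expect_equal(pk$sign[pk$wavelength == 1362], 1)
  expect_equal(pk$sign[abs(pk$wavelength - 1450) <= 2], -1)
  # flipping the band flips the reported sign
  pk2 <- regression_vector_peaks(-b, grid = grid)
  expect_equal(pk2$sign[1], -1)
  # flat vector: nothing to report
  expect_identical(nrow(regression_vector_peaks(rep(0.2, length(grid)),
                                                grid = grid)), 0L)
  expect_error(regression_vector_peaks(b, window = c(3000, 3100),
                                       grid = grid), "outside")
})
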