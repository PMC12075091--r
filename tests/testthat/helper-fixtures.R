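# Shared fixtures and independent oracles for the test suite.

# Small, fast experiment design used by most spectra tests.
small_design <- function(analytes = list(analyte_signature("GSH")),
                         reps = 3L, noise_sd = 1e-3, seed = 42L, ...) {
  experiment_design(analytes = analytes, replicates_per_level = reps,
                    noise_sd = noise_sd, n_blanks = 5L, seed = seed, ...)
}

# Noise-free design: pure Beer-Lambert mixing, no scatter/baseline.
noiseless_design <- function(analytes = list(analyte_signature("GSH")),
                             reps = 2L, seed = 7L, ...) {
  experiment_design(analytes = analytes, replicates_per_level = reps,
                    noise_sd = 0, scatter_gain_sd = 0,
                    baseline_offset_sd = 0, baseline_slope_sd = 0,
                    n_blanks = 2L, seed = seed, ...)
}

# Brute-force OLS oracle on centred data (normal equations).
ols_oracle <- function(X, y) {
  Xc <- scale(X, center = TRUE, scale = FALSE)
  yc <- y - mean(y)
  b <- solve(crossprod(Xc), crossprod(Xc, yc))
  list(b = drop(b),
       fitted = drop(Xc %*% b) + mean(y))
}

# Naive per-frame hydrogen-bond counting oracle: explicit loops over
# frames, donors and acceptors with scalar geometry, independent of the
# package's vectorized detection path.  Returns total bonded frames per
# direction (the default interaction score).
hbond_count_oracle <- function(traj, criteria = hbond_criteria(),
                               directions = c("OH-S", "SH-O")) {
  top <- traj$topology
  atoms <- top$atoms
  box <- traj$box
  s_ids <- atoms$id[atoms$role == "sulfur"]
  o_ids <- atoms$id[atoms$role == "water_oxygen"]
  h_of <- lapply(seq_len(max(atoms$id)), function(i) integer(0))
  for (r in seq_len(nrow(top$bonds))) {
    a1 <- top$bonds$atom1[r]; a2 <- top$bonds$atom2[r]
    r1 <- atoms$role[match(a1, atoms$id)]
    r2 <- atoms$role[match(a2, atoms$id)]
    if (r2 %in% c("water_hydrogen", "sulfur_hydrogen")) {
      h_of[[a1]] <- c(h_of[[a1]], a2)
    }
    if (r1 %in% c("water_hydrogen", "sulfur_hydrogen")) {
      h_of[[a2]] <- c(h_of[[a2]], a1)
    }
  }
  mi <- function(d, L) d - L * round(d / L)
  dist3 <- function(p, q) {
    sqrt(mi(p[1] - q[1], box[1])^2 + mi(p[2] - q[2], box[2])^2 +
           mi(p[3] - q[3], box[3])^2)
  }
  ang3 <- function(d, h, a) {
    v1 <- c(mi(d[1] - h[1], box[1]), mi(d[2] - h[2], box[2]),
            mi(d[3] - h[3], box[3]))
    v2 <- c(mi(a[1] - h[1], box[1]), mi(a[2] - h[2], box[2]),
            mi(a[3] - h[3], box[3]))
    cosang <- sum(v1 * v2) / sqrt(sum(v1^2) * sum(v2^2))
    acos(min(1, max(-1, cosang))) * 180 / pi
  }
  tot <- c("OH-S" = 0, "SH-O" = 0)
  nf <- dim(traj$coords)[3]
  for (fr in seq_len(nf)) {
    fm <- traj$coords[, , fr]
    for (s in s_ids) {
      for (o in o_ids) {
        d <- dist3(fm[s, ], fm[o, ])
        if (d <= criteria$dist_OS) {
          if ("OH-S" %in% directions) {
            bonded <- FALSE
            for (h in h_of[[o]]) {
              if (ang3(fm[o, ], fm[h, ], fm[s, ]) >=
                  180 - criteria$angle_dev) bonded <- TRUE
            }
            if (bonded) tot[["OH-S"]] <- tot[["OH-S"]] + 1
          }
          if ("SH-O" %in% directions) {
            bonded <- FALSE
            for (h in h_of[[s]]) {
              if (ang3(fm[s, ], fm[h, ], fm[o, ]) >=
                  180 - criteria$angle_dev) bonded <- TRUE
            }
            if (bonded) tot[["SH-O"]] <- tot[["SH-O"]] + 1
          }
        }
      }
    }
  }
  tot
}

# Tiny hand-built trajectory: one thiol + a few waters at fixed positions.
# `water_pos` is a list of 3-vectors (oxygen positions); hydrogens point
# toward the sulfur when `donate = TRUE`, away otherwise.
fixed_water_trajectory <- function(water_pos, donate = TRUE,
                                   n_frames = 1L, box = c(30, 30, 30)) {
  n_w <- length(water_pos)
  centre <- box / 2
  atoms <- data.frame(
    id = seq_len(2L + 3L * n_w),
    element = c("S", "H", rep(c("O", "H", "H"), n_w)),
    role = c("sulfur", "sulfur_hydrogen",
             rep(c("water_oxygen", "water_hydrogen", "water_hydrogen"),
                 n_w)),
    mol = c(1L, 1L, rep(seq_len(n_w) + 1L, each = 3L)),
    stringsAsFactors = FALSE)
  o_ids <- 2L + 3L * (seq_len(n_w) - 1L) + 1L
  bonds <- data.frame(
    atom1 = c(1L, rep(o_ids, each = 2L)),
    atom2 = c(2L, rep(o_ids, each = 2L) + rep(1:2, n_w)))
  top <- topology(atoms, bonds)
  fm <- matrix(NA_real_, nrow(atoms), 3L)
  fm[1L, ] <- centre
  fm[2L, ] <- centre + c(1.34, 0, 0)
  for (w in seq_len(n_w)) {
    o <- centre + water_pos[[w]]
    u <- (centre - o) / sqrt(sum((centre - o)^2))   # toward sulfur
    v <- if (abs(u[3]) < 0.9) c(0, 0, 1) else c(0, 1, 0)
    v <- v - u * sum(v * u); v <- v / sqrt(sum(v^2))
    if (donate) {
      h1 <- o + 0.96 * u
      h2 <- o + 0.96 * (cos(104.5 * pi / 180) * u +
                          sin(104.5 * pi / 180) * v)
    } else {
      h1 <- o - 0.96 * u
      h2 <- o + 0.96 * (cos(104.5 * pi / 180) * -u +
                          sin(104.5 * pi / 180) * v)
    }
    base <- 2L + 3L * (w - 1L)
    fm[base + 1L, ] <- o
    fm[base + 2L, ] <- h1
    fm[base + 3L, ] <- h2
  }
  coords <- array(rep(fm, n_frames), c(nrow(atoms), 3L, n_frames))
  trajectory(coords, box, top)
}
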