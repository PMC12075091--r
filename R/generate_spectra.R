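#' Design of a synthetic concentration-series NIR experiment
#'
#' Captures the study layout the spectra generator emulates: a 1-10 mM
#' concentration series with 25 replicate measurements per level for each
#' analyte, on a 1100-2400 nm / 2 nm instrument grid, plus buffer blanks.
#' Noise terms: per-channel additive noise, per-spectrum multiplicative
#' scatter gain, per-spectrum baseline offset and tilt.
#'
#' @param analytes list of [analyte_signature()] objects (or analyte names
#'   resolved through the built-in templates).
#' @param concentrations_mM concentration levels in mM (default 1..10).
#' @param replicates_per_level replicate spectra per level (default 25).
#' @param grid c(start, stop, step) in nm (default c(1100, 2400, 2)).
#' @param noise_sd additive per-channel noise sd in absorbance units.
#' @param scatter_gain_sd sd of the multiplicative gain around 1.
#' @param baseline_offset_sd sd of the per-spectrum constant offset (AU).
#' @param baseline_slope_sd sd of the per-spectrum linear tilt (AU per nm).
#' @param outlier_fraction fraction of spectra to corrupt downstream via
#'   [inject_outliers()] (kept in the design for provenance; the generator
#'   itself produces clean spectra).
#' @param n_blanks number of buffer-only (PBS) spectra to generate.
#' @param mixture_table optional data.frame with one column per analyte
#'   name and one row per mixture level; overrides `concentrations_mM`.
#' @param seed integer RNG seed.
#' @return An object of class `experiment_design`.
#' @export
experiment_design <- function(analytes = list(analyte_signature("GSH"),
                                              analyte_signature("GSSG")),
                              concentrations_mM = 1:10,
                              replicates_per_level = 25L,
                              grid = c(1100, 2400, 2),
                              noise_sd = 1e-3,
                              scatter_gain_sd = 0.01,
                              baseline_offset_sd = 5e-4,
                              baseline_slope_sd = 5e-7,
                              outlier_fraction = 0,
                              n_blanks = 25L,
                              mixture_table = NULL,
                              seed = 1L) {
  analytes <- lapply(analytes, function(a) {
    if (inherits(a, "analyte_signature")) a else analyte_signature(a)
  })
  if (!length(analytes)) stop("need at least one analyte signature")
  if (is.null(mixture_table) && any(concentrations_mM <= 0)) {
    stop("concentrations must be positive")
  }
  if (replicates_per_level < 1L) stop("replicates_per_level must be >= 1")
  if (length(grid) != 3L || grid[3] <= 0 || grid[2] <= grid[1]) {
    stop("grid must be c(start, stop, step) with step > 0 and stop > start")
  }
  if (noise_sd < 0 || scatter_gain_sd < 0 || baseline_offset_sd < 0 ||
      baseline_slope_sd < 0) {
    stop("noise standard deviations must be >= 0")
  }
  if (outlier_fraction < 0 || outlier_fraction > 0.5) {
    stop("outlier_fraction must lie in [0, 0.5]")
  }
  if (!is.null(mixture_table)) {
    mixture_table <- as.data.frame(mixture_table)
    have <- vapply(analytes, `[[`, "", "name")
    miss <- setdiff(names(mixture_table), have)
    if (length(miss)) {
      stop("mixture_table columns without a signature: ",
           paste(miss, collapse = ", "))
    }
  }
  structure(
    list(analytes = analytes, concentrations_mM = as.numeric(concentrations_mM),
         replicates_per_level = as.integer(replicates_per_level),
         grid = as.numeric(grid), noise_sd = noise_sd,
         scatter_gain_sd = scatter_gain_sd,
         baseline_offset_sd = baseline_offset_sd,
         baseline_slope_sd = baseline_slope_sd,
         outlier_fraction = outlier_fraction,
         n_blanks = as.integer(n_blanks),
         mixture_table = mixture_table, seed = as.integer(seed)),
    class = "experiment_design"
  )
}

# Run `expr` under a fixed seed without disturbing the caller's RNG stream.
with_seed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())),
            add = TRUE)
  }
  set.seed(seed)
  expr
}

#' Generate a synthetic spectra set with ground truth
#'
#' Beer-Lambert mixing: each spectrum is
#' `gain * (background + sum_a conc_a * signature_a) + offset +
#' slope * (lambda - lambda_mid) + N(0, noise_sd)` per channel, with
#' `gain ~ N(1, scatter_gain_sd)`.  Reproducible given the design seed.
#'
#' @param design an [experiment_design()].
#' @return list with elements `set` (a `spectra_set`) and `truth` (list:
#'   per-sample true analyte/concentration/outlier flag, the noiseless
#'   background, and the per-analyte molar signatures on the grid).
#' @export
generate_spectra_set <- function(design) {
  stopifnot(inherits(design, "experiment_design"))
  grid <- seq(design$grid[1], design$grid[2], by = design$grid[3])
  bg <- pbs_background(grid)
  sig_names <- vapply(design$analytes, `[[`, "", "name")
  for (a in design$analytes) check_signature_on_grid(a, grid)
  sigs <- vapply(design$analytes, molar_signature, numeric(length(grid)),
                 grid = grid)
  colnames(sigs) <- sig_names

  # concentration matrix: one row per (level x replicate) sample,
  # one column per analyte
  if (is.null(design$mixture_table)) {
    levels_per_analyte <- length(design$concentrations_mM)
    reps <- design$replicates_per_level
    conc <- do.call(rbind, lapply(seq_along(sig_names), function(j) {
      m <- matrix(0, levels_per_analyte * reps, length(sig_names))
      m[, j] <- rep(design$concentrations_mM, each = reps)
      m
    }))
    analyte_lab <- rep(sig_names, each = levels_per_analyte * reps)
    conc_main <- rowSums(conc)
    replicate <- rep(rep(seq_len(reps), times = levels_per_analyte),
                     times = length(sig_names))
  } else {
    reps <- design$replicates_per_level
    mt <- design$mixture_table
    conc <- matrix(0, nrow(mt) * reps, length(sig_names))
    for (j in seq_along(sig_names)) {
      v <- if (sig_names[j] %in% names(mt)) mt[[sig_names[j]]] else
        rep(0, nrow(mt))
      conc[, j] <- rep(v, each = reps)
    }
    analyte_lab <- rep("mixture", nrow(conc))
    conc_main <- NA_real_
    replicate <- rep(rep(seq_len(reps), times = nrow(mt)))
  }

  # append buffer blanks
  n_samples <- nrow(conc)
  if (design$n_blanks > 0L) {
    conc <- rbind(conc, matrix(0, design$n_blanks, length(sig_names)))
    analyte_lab <- c(analyte_lab, rep("PBS", design$n_blanks))
    conc_main <- c(rep(conc_main, length.out = n_samples),
                   rep(0, design$n_blanks))
    replicate <- c(replicate, seq_len(design$n_blanks))
  } else {
    conc_main <- rep(conc_main, length.out = n_samples)
  }
  n <- nrow(conc)
  p <- length(grid)

  absorbance <- with_seed(design$seed, {
    gain <- stats::rnorm(n, 1, design$scatter_gain_sd)
    offset <- stats::rnorm(n, 0, design$baseline_offset_sd)
    slope <- stats::rnorm(n, 0, design$baseline_slope_sd)
    noise <- matrix(stats::rnorm(n * p, 0, design$noise_sd), n, p)
    clean <- matrix(bg, n, p, byrow = TRUE) + conc %*% t(sigs)
    lam <- grid - (min(grid) + max(grid)) / 2
    gain * clean + offset + outer(slope, lam) + noise
  })

  meta <- data.frame(
    id = sprintf("s%04d", seq_len(n)),
    analyte = analyte_lab,
    concentration_mM = conc_main,
    replicate = replicate,
    stringsAsFactors = FALSE
  )
  for (j in seq_along(sig_names)) {
    meta[[paste0("conc_", sig_names[j])]] <- conc[, j]
  }
  set <- spectra_set(grid, absorbance, meta)
  set <- add_transform_record(set, "generate_spectra_set",
                              list(seed = design$seed,
                                   analytes = sig_names))
  truth <- list(
    samples = data.frame(id = meta$id, analyte = meta$analyte,
                         concentration_mM = meta$concentration_mM,
                         outlier = FALSE, stringsAsFactors = FALSE),
    concentrations = conc,
    background = bg,
    signatures = sigs,
    grid = grid
  )
  list(set = set, truth = truth)
}

#' Inject screenable outlier spectra
#'
#' Corrupts a random subset of spectra with a large localized spike (a
#' Gaussian bump of the given magnitude at a random wavelength) so the
#' PCA/Mahalanobis screen has something to find.  A spike, unlike a flat
#' offset, survives SNV normalization.
#'
#' @param set a `spectra_set`.
#' @param fraction fraction of spectra to corrupt, in [0, 0.5].
#' @param magnitude spike height in absorbance units (must be positive).
#' @param seed RNG seed.
#' @return list with elements `set` (corrupted) and `flags` (logical vector
#'   marking the corrupted spectra).
#' @export
inject_outliers <- function(set, fraction, magnitude = 0.1, seed = 1L) {
  stopifnot(inherits(set, "spectra_set"))
  if (fraction < 0 || fraction > 0.5) stop("fraction must lie in [0, 0.5]")
  if (magnitude <= 0) stop("magnitude must be positive")
  n <- n_spectra(set)
  n_out <- floor(fraction * n)
  flags <- rep(FALSE, n)
  if (n_out > 0L) {
    with_seed(seed, {
      idx <- sample.int(n, n_out)
      centers <- stats::runif(n_out, min(set$grid), max(set$grid))
      for (k in seq_along(idx)) {
        bump <- magnitude * exp(-0.5 * ((set$grid - centers[k]) / 15)^2)
        set$absorbance[idx[k], ] <- set$absorbance[idx[k], ] + bump
      }
      flags[idx] <- TRUE
    })
  }
  set <- add_transform_record(set, "inject_outliers",
                              list(fraction = fraction,
                                   magnitude = magnitude, seed = seed,
                                   n_injected = n_out))
  list(set = set, flags = flags)
}
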