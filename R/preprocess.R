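#' Keep only wavelength regions of interest
#'
#' Retains the channels whose wavelength falls inside any of the closed
#' ranges, dropping everything else (the standard treatment for the noisy
#' sub-1100 nm and saturated 1850-2050 nm stretches of 1 mm path-length
#' water spectra).
#'
#' @param set a `spectra_set`.
#' @param include_ranges list of length-2 numeric vectors `c(lo, hi)` in nm.
#' @return The masked `spectra_set`.
#' @export
mask_regions <- function(set, include_ranges) {
  stopifnot(inherits(set, "spectra_set"))
  if (is.numeric(include_ranges) && length(include_ranges) == 2L) {
    include_ranges <- list(include_ranges)
  }
  keep <- rep(FALSE, length(set$grid))
  for (r in include_ranges) {
    if (length(r) != 2L || !is.numeric(r) || r[2] < r[1]) {
      stop("each include range must be numeric c(lo, hi) with lo <= hi")
    }
    keep <- keep | (set$grid >= r[1] & set$grid <= r[2])
  }
  if (!any(keep)) {
    stop("masking removed every channel: no wavelength lies inside ",
         "the requested ranges")
  }
  set$grid <- set$grid[keep]
  set$absorbance <- set$absorbance[, keep, drop = FALSE]
  set <- add_transform_record(set, "mask_regions",
                              list(include_ranges = include_ranges,
                                   channels_kept = sum(keep)))
  set
}

#' Standard normal variate transform
#'
#' Per-spectrum centering and scaling to unit standard deviation (n-1
#' denominator), removing multiplicative scatter gain and additive offset.
#'
#' @param set a `spectra_set` with at least two channels.
#' @return The transformed `spectra_set`: every row has mean 0 and sd 1.
#' @export
snv <- function(set) {
  stopifnot(inherits(set, "spectra_set"))
  p <- n_channels(set)
  if (p < 2L) stop("SNV needs at least 2 channels per spectrum")
  m <- rowMeans(set$absorbance)
  centred <- set$absorbance - m
  s <- sqrt(rowSums(centred^2) / (p - 1L))
  if (any(s <= 0)) {
    bad <- which(s <= 0)[1L]
    stop("constant spectrum (zero standard deviation) for sample ",
         set$meta$id[bad])
  }
  set$absorbance <- centred / s
  add_transform_record(set, "snv", list())
}

#' Savitzky-Golay smoothing / differentiation
#'
#' Local least-squares polynomial filtering of each spectrum.  Edge
#' channels are handled by the filter's polynomial-fit transients (a
#' polynomial fitted over the first/last window evaluated at the edge
#' points), so any spectrum that is globally a polynomial of degree
#' `<= polyorder` is reproduced exactly, edges included.
#'
#' A masked grid (e.g. 1100-1850 + 2050-2400 nm) is filtered one
#' contiguous uniformly spaced segment at a time, so the filter never
#' bridges an excluded region.
#'
#' @param set a `spectra_set`; the wavelength spacing must be uniform
#'   within each contiguous segment.
#' @param window odd number of channels in the moving window (default 15).
#' @param polyorder polynomial degree (default 2).
#' @param derivative derivative order (default 0 = smoothing); derivatives
#'   are returned per nm using the grid spacing.
#' @return The filtered `spectra_set`.
#' @export
savitzky_golay <- function(set, window = 15L, polyorder = 2L,
                           derivative = 0L) {
  stopifnot(inherits(set, "spectra_set"))
  window <- as.integer(window)
  if (window %% 2L == 0L) stop("window must be odd")
  if (window <= polyorder) stop("window must exceed polyorder")
  if (derivative > polyorder) stop("derivative order must be <= polyorder")
  p <- n_channels(set)
  if (window >= p) {
    stop("window (", window, ") must be smaller than the number of ",
         "channels (", p, ")")
  }
  steps <- diff(set$grid)
  step <- min(steps)
  breaks <- which(steps > step * (1 + 1e-8))
  seg_start <- c(1L, breaks + 1L)
  seg_end <- c(breaks, p)
  for (s in seq_along(seg_start)) {
    idx <- seg_start[s]:seg_end[s]
    if (length(idx) <= window) {
      stop("window (", window, ") must be smaller than the contiguous ",
           "grid segment ", set$grid[seg_start[s]], "-",
           set$grid[seg_end[s]], " nm (", length(idx), " channels)")
    }
    seg_steps <- diff(set$grid[idx])
    if (max(seg_steps) - min(seg_steps) > 1e-8 * max(seg_steps)) {
      stop("non-uniform wavelength spacing within segment ",
           set$grid[seg_start[s]], "-", set$grid[seg_end[s]], " nm")
    }
    set$absorbance[, idx] <- t(apply(
      set$absorbance[, idx, drop = FALSE], 1L,
      function(row) as.numeric(signal::sgolayfilt(
        row, p = polyorder, n = window, m = derivative,
        ts = seg_steps[1L]))))
  }
  add_transform_record(set, "savitzky_golay",
                       list(window = window, polyorder = polyorder,
                            derivative = derivative,
                            segments = length(seg_start)))
}

#' Difference spectra against a background set
#'
#' Subtracts the channel-wise mean of the background spectra (e.g. PBS
#' blanks) from every sample spectrum, isolating the solute and
#' hydration-change signal.
#'
#' @param set a `spectra_set` of sample spectra.
#' @param background a `spectra_set` of background spectra on the identical
#'   wavelength grid.
#' @return `set` with the mean background subtracted; metadata preserved.
#' @export
difference_spectra <- function(set, background) {
  stopifnot(inherits(set, "spectra_set"), inherits(background, "spectra_set"))
  if (length(set$grid) != length(background$grid) ||
      any(abs(set$grid - background$grid) > 1e-9)) {
    i <- if (length(set$grid) != length(background$grid)) 1L else
      which(abs(set$grid - background$grid) > 1e-9)[1L]
    stop("wavelength grids differ (first difference at ",
         format(set$grid[min(i, length(set$grid))]), " nm)")
  }
  bg_mean <- colMeans(background$absorbance)
  set$absorbance <- sweep(set$absorbance, 2L, bg_mean, "-")
  add_transform_record(set, "difference_spectra",
                       list(n_background = nrow(background$absorbance)))
}

#' Column standardization (autoscaling)
#'
#' Mean-centres and scales each wavelength channel to unit variance across
#' samples, returning the scaler so the identical transform can be applied
#' to held-out spectra.  Channels with zero variance are left
#' centred-only and flagged with a warning record in the scaler.
#'
#' @param set a `spectra_set` with at least 2 samples.
#' @return list with elements `set` (standardized) and `scaler`
#'   (means, sds, zero-variance flags).
#' @export
standardize_columns <- function(set) {
  stopifnot(inherits(set, "spectra_set"))
  if (nrow(set$absorbance) < 2L) stop("need at least 2 samples")
  mu <- colMeans(set$absorbance)
  sd_ <- apply(set$absorbance, 2L, stats::sd)
  zero_var <- sd_ <= .Machine$double.eps^0.5 * pmax(abs(mu), 1)
  scaler <- list(mean = mu, sd = ifelse(zero_var, 1, sd_),
                 zero_variance = zero_var, grid = set$grid)
  class(scaler) <- "column_scaler"
  if (any(zero_var)) {
    warning(sum(zero_var), " zero-variance channel(s) left centred-only")
  }
  out <- apply_column_scaler(set, scaler)
  list(set = out, scaler = scaler)
}

#' Apply a previously fitted column scaler
#'
#' @param set a `spectra_set` on the scaler's grid.
#' @param scaler a `column_scaler` from [standardize_columns()].
#' @return The standardized `spectra_set`.
#' @export
apply_column_scaler <- function(set, scaler) {
  stopifnot(inherits(set, "spectra_set"), inherits(scaler, "column_scaler"))
  if (length(set$grid) != length(scaler$grid) ||
      any(abs(set$grid - scaler$grid) > 1e-9)) {
    stop("spectra grid does not match the scaler's grid")
  }
  set$absorbance <- sweep(sweep(set$absorbance, 2L, scaler$mean, "-"),
                          2L, scaler$sd, "/")
  add_transform_record(set, "standardize_columns",
                       list(zero_variance = sum(scaler$zero_variance)))
}
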