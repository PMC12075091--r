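#' Locate informative bands in a regression vector
#'
#' Finds local extrema of `|b(lambda)|` inside a wavelength window and
#' ranks them by magnitude; a simple prominence (peak height above the
#' higher of the two flanking valleys of `|b|`) filters shoulders and
#' noise wiggles.  Used to read solvation-band positions (e.g. 1362/1381
#' nm) off a fitted model.
#'
#' @param model a `plsr_fit` or `pcr_fit` carrying a `grid` element (the
#'   workflow drivers attach it), or a plain numeric regression vector (in
#'   which case `grid` must be supplied).
#' @param window `c(lo, hi)` wavelength window in nm (default
#'   `c(1300, 1600)`, the water first overtone).
#' @param min_prominence minimum prominence of |b| to report (default 0,
#'   i.e. all local maxima).
#' @param grid wavelength grid matching the regression vector; only needed
#'   when `model` is a bare vector.
#' @param response for multi-response models, which regression vector to
#'   use (column index or name; default 1).
#' @return data.frame with columns `wavelength`, `sign`, `height`
#'   (`|b|`), `prominence`, sorted by height (descending).
#' @export
regression_vector_peaks <- function(model, window = c(1300, 1600),
                                    min_prominence = 0, grid = NULL,
                                    response = 1L) {
  if (is.numeric(model) && is.null(dim(model))) {
    b <- as.numeric(model)
    if (is.null(grid)) stop("grid must be supplied with a bare vector")
  } else if (inherits(model, "plsr_fit")) {
    b <- model$b
    if (is.null(grid)) grid <- model$grid
  } else if (inherits(model, "pcr_fit")) {
    b <- model$b[, response]
    if (is.null(grid)) grid <- model$grid
  } else {
    stop("model must be a plsr_fit, pcr_fit or numeric vector")
  }
  if (is.null(grid)) {
    stop("model carries no wavelength grid; pass `grid` explicitly")
  }
  if (length(grid) != length(b)) stop("grid/regression vector length mismatch")
  if (window[1] > max(grid) || window[2] < min(grid)) {
    stop("window ", window[1], "-", window[2],
         " nm lies outside the model grid")
  }
  inside <- grid >= window[1] & grid <= window[2]
  v <- abs(b[inside])
  wl <- grid[inside]
  sgn <- sign(b[inside])
  m <- length(v)
  if (m < 3L) {
    return(data.frame(wavelength = numeric(), sign = numeric(),
                      height = numeric(), prominence = numeric()))
  }
  is_peak <- c(FALSE, v[2:(m - 1)] > v[1:(m - 2)] &
                 v[2:(m - 1)] >= v[3:m], FALSE)
  idx <- which(is_peak)
  if (!length(idx)) {
    return(data.frame(wavelength = numeric(), sign = numeric(),
                      height = numeric(), prominence = numeric()))
  }
  prominence <- vapply(idx, function(i) {
    left <- v[seq_len(i - 1)]
    higher_l <- which(left > v[i])
    lmin <- if (length(higher_l)) {
      min(v[(max(higher_l) + 1):(i - 1)])
    } else min(left)
    right <- v[(i + 1):m]
    higher_r <- which(right > v[i])
    rmin <- if (length(higher_r)) {
      min(right[seq_len(min(higher_r) - 1)])
    } else min(right)
    v[i] - max(lmin, rmin)
  }, 0)
  out <- data.frame(wavelength = wl[idx], sign = sgn[idx],
                    height = v[idx], prominence = prominence)
  out <- out[out$prominence >= min_prominence, , drop = FALSE]
  out <- out[order(-out$height), , drop = FALSE]
  rownames(out) <- NULL
  out
}
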