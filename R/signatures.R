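#' Deterministic PBS background spectrum
#'
#' Smooth positive absorbance curve emulating a phosphate-buffered saline
#' blank in a 1 mm cell: the water first-overtone band near 1450 nm, the
#' combination-region band near 1940 nm (which sits inside the 1850-2050 nm
#' stretch later removed by masking) and a mild constant offset.
#'
#' @param grid numeric wavelength grid in nm, strictly increasing.
#' @return numeric vector of absorbance values, one per channel; identical
#'   on repeated calls.
#' @export
pbs_background <- function(grid) {
  grid <- as.numeric(grid)
  if (length(grid) == 0L) stop("empty wavelength grid")
  if (length(grid) > 1L && any(diff(grid) <= 0)) {
    stop("wavelength grid must be strictly increasing")
  }
  1.00 * exp(-0.5 * ((grid - 1450) / 60)^2) +
    0.85 * exp(-0.5 * ((grid - 1940) / 75)^2) +
    0.08
}

# Built-in solvation-band templates.  Amplitudes are free parameters (no
# molar absorptivities are established for these features); defaults are
# chosen so 10 mM features are ~1-3% of the background:
#  - GSH (thiol): sharp positive first-shell bands at 1362/1381 nm, a mild
#    negative water-displacement dip at 1450 nm, amide combination bands at
#    2175/2279 nm.
#  - GSSG (disulfide): no 1362/1381 features, a deeper 1450 nm dip, the
#    same amide bands.
#  - NADH / NAD+: same template with the reduced form carrying the
#    1362-1364 nm band and the oxidized form the 1382-1384 nm band.
.builtin_signatures <- list(
  GSH = list(centers = c(1362, 1381, 1450, 2175, 2279),
             widths = c(5, 5, 35, 15, 15),
             amps = c(0.0030, 0.0028, -0.0012, 0.0015, 0.0015)),
  GSSG = list(centers = c(1450, 2175, 2279),
              widths = c(35, 15, 15),
              amps = c(-0.0035, 0.0015, 0.0015)),
  NADH = list(centers = c(1363, 1450, 2175, 2279),
              widths = c(5, 35, 15, 15),
              amps = c(0.0030, -0.0015, 0.0012, 0.0012)),
  `NAD+` = list(centers = c(1383, 1450, 2175, 2279),
                widths = c(5, 35, 15, 15),
                amps = c(0.0028, -0.0030, 0.0012, 0.0012))
)

#' Analyte solvation-band signature
#'
#' Describes an analyte's difference-spectrum fingerprint as a sum of
#' Gaussian bands with per-mM amplitudes (negative amplitudes encode
#' water-displacement dips).  Calling with just a known name (`"GSH"`,
#' `"GSSG"`, `"NADH"`, `"NAD+"`) returns the built-in template.
#'
#' @param name analyte label.
#' @param band_centers wavelengths of the band centres (nm).
#' @param band_widths Gaussian sigmas (nm), all positive.
#' @param band_amplitudes_per_mM absorbance units per mM, one per band.
#' @return An object of class `analyte_signature`.
#' @export
analyte_signature <- function(name, band_centers = NULL, band_widths = NULL,
                              band_amplitudes_per_mM = NULL) {
  if (is.null(band_centers)) {
    tmpl <- .builtin_signatures[[name]]
    if (is.null(tmpl)) {
      stop("no built-in signature for '", name,
           "'; supply band_centers/band_widths/band_amplitudes_per_mM")
    }
    band_centers <- tmpl$centers
    band_widths <- tmpl$widths
    band_amplitudes_per_mM <- tmpl$amps
  }
  if (length(band_centers) != length(band_widths) ||
      length(band_centers) != length(band_amplitudes_per_mM)) {
    stop("band_centers, band_widths and band_amplitudes_per_mM must have ",
         "equal length")
  }
  if (any(band_widths <= 0)) stop("band widths must be positive")
  structure(
    list(name = name, band_centers = as.numeric(band_centers),
         band_widths = as.numeric(band_widths),
         band_amplitudes_per_mM = as.numeric(band_amplitudes_per_mM)),
    class = "analyte_signature"
  )
}

#' @export
print.analyte_signature <- function(x, ...) {
  cat("<analyte_signature> ", x$name, ": ", length(x$band_centers),
      " band(s) at ", paste(x$band_centers, collapse = ", "), " nm\n",
      sep = "")
  invisible(x)
}

#' Evaluate a molar signature on a wavelength grid
#'
#' @param signature an `analyte_signature`.
#' @param grid wavelength grid (nm).
#' @return absorbance per mM at each grid channel.
#' @export
molar_signature <- function(signature, grid) {
  stopifnot(inherits(signature, "analyte_signature"))
  out <- numeric(length(grid))
  for (i in seq_along(signature$band_centers)) {
    out <- out + signature$band_amplitudes_per_mM[i] *
      exp(-0.5 * ((grid - signature$band_centers[i]) /
                    signature$band_widths[i])^2)
  }
  out
}

# Error if any band centre lies outside the instrument grid span.
check_signature_on_grid <- function(signature, grid) {
  outside <- signature$band_centers < min(grid) |
    signature$band_centers > max(grid)
  if (any(outside)) {
    stop("signature '", signature$name, "' has band(s) at ",
         paste(signature$band_centers[outside], collapse = ", "),
         " nm outside the instrument grid (",
         min(grid), "-", max(grid), " nm)")
  }
  invisible(TRUE)
}
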