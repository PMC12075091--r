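#' Spectra container
#'
#' A `spectra_set` bundles a strictly increasing wavelength grid (nm), a
#' samples x channels absorbance matrix, per-sample metadata and a
#' provenance list recording every transform applied so far.
#'
#' @param grid numeric vector of wavelengths in nm, strictly increasing.
#' @param absorbance numeric matrix, one row per sample, one column per
#'   wavelength, in absorbance units.
#' @param meta data.frame with at least columns `id`, `analyte`,
#'   `concentration_mM` and `replicate`; one row per spectrum.  Additional
#'   columns (e.g. per-analyte concentrations for mixtures) are carried
#'   along untouched.
#' @param provenance list of transform records (see [transform_log()]).
#' @return An object of class `spectra_set`.
#' @export
spectra_set <- function(grid, absorbance, meta, provenance = list()) {
  grid <- as.numeric(grid)
  if (length(grid) == 0L) stop("empty wavelength grid")
  if (any(!is.finite(grid))) stop("non-finite wavelengths in grid")
  if (length(grid) > 1L && any(diff(grid) <= 0)) {
    stop("wavelength grid must be strictly increasing (duplicate or ",
         "decreasing wavelength at position ",
         which(diff(grid) <= 0)[1L] + 1L, ")")
  }
  absorbance <- as.matrix(absorbance)
  storage.mode(absorbance) <- "double"
  if (ncol(absorbance) != length(grid)) {
    stop("absorbance has ", ncol(absorbance), " columns but the grid has ",
         length(grid), " wavelengths")
  }
  meta <- as.data.frame(meta, stringsAsFactors = FALSE)
  if (nrow(meta) != nrow(absorbance)) {
    stop("meta has ", nrow(meta), " rows but absorbance has ",
         nrow(absorbance), " spectra")
  }
  required <- c("id", "analyte", "concentration_mM", "replicate")
  missing_cols <- setdiff(required, names(meta))
  if (length(missing_cols)) {
    stop("meta is missing required columns: ",
         paste(missing_cols, collapse = ", "))
  }
  if (any(!is.finite(absorbance))) stop("non-finite absorbance values")
  structure(
    list(grid = grid, absorbance = unname(absorbance), meta = meta,
         provenance = provenance),
    class = "spectra_set"
  )
}

#' @export
print.spectra_set <- function(x, ...) {
  cat("<spectra_set> ", nrow(x$absorbance), " spectra x ",
      length(x$grid), " channels (",
      format(min(x$grid)), "-", format(max(x$grid)), " nm)\n", sep = "")
  an <- table(x$meta$analyte)
  cat("  analytes: ",
      paste(sprintf("%s (%d)", names(an), as.integer(an)), collapse = ", "),
      "\n", sep = "")
  if (length(x$provenance)) {
    cat("  transforms: ",
        paste(vapply(x$provenance, `[[`, "", "transform"), collapse = " -> "),
        "\n", sep = "")
  }
  invisible(x)
}

#' Number of spectra / channels in a spectra_set
#' @param x a `spectra_set`.
#' @return integer count.
#' @export
n_spectra <- function(x) nrow(x$absorbance)

#' @rdname n_spectra
#' @export
n_channels <- function(x) length(x$grid)

# Append one provenance record; every transform calls this exactly once.
add_transform_record <- function(set, transform, params = list()) {
  rec <- list(transform = transform, params = params,
              timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"))
  set$provenance <- c(set$provenance, list(rec))
  set
}

#' Transform provenance of a spectra_set
#'
#' @param x a `spectra_set`.
#' @return data.frame with one row per applied transform, in application
#'   order.
#' @export
transform_log <- function(x) {
  if (!length(x$provenance)) {
    return(data.frame(transform = character(), timestamp = character()))
  }
  data.frame(
    transform = vapply(x$provenance, `[[`, "", "transform"),
    timestamp = vapply(x$provenance, `[[`, "", "timestamp"),
    stringsAsFactors = FALSE
  )
}

#' Write a spectra_set to CSV
#'
#' Layout: leading metadata columns (`id,analyte,concentration_mM,replicate`,
#' plus any extra meta columns), then one column per wavelength with the
#' wavelength in nm as header.  UTF-8, '.' decimal separator.
#'
#' @param set a `spectra_set`.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_spectra <- function(set, path) {
  stopifnot(inherits(set, "spectra_set"))
  mat <- as.data.frame(set$absorbance)
  names(mat) <- format(set$grid, trim = TRUE, scientific = FALSE)
  out <- cbind(set$meta, mat)
  utils::write.csv(out, path, row.names = FALSE, fileEncoding = "UTF-8")
  invisible(path)
}

#' Read a spectra table from CSV
#'
#' Inverse of [write_spectra()]: any column whose header parses as a number
#' is treated as a wavelength channel; the remaining columns are per-sample
#' metadata and must include `id`, `analyte`, `concentration_mM` and
#' `replicate`.
#'
#' @param path CSV file path.
#' @return A validated `spectra_set`.
#' @export
read_spectra <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  df <- utils::read.csv(path, check.names = FALSE, stringsAsFactors = FALSE,
                        fileEncoding = "UTF-8")
  if (!nrow(df)) stop("no spectra rows in ", path)
  wl <- suppressWarnings(as.numeric(names(df)))
  is_channel <- !is.na(wl)
  if (!any(is_channel)) stop("no wavelength columns found in ", path)
  grid <- wl[is_channel]
  if (anyDuplicated(grid)) {
    stop("duplicated wavelength column: ", grid[duplicated(grid)][1L], " nm")
  }
  if (any(diff(grid) <= 0)) {
    stop("wavelength columns are not strictly increasing")
  }
  absorbance <- as.matrix(df[, is_channel, drop = FALSE])
  if (any(!is.finite(absorbance))) {
    stop("unparseable or missing absorbance values in ", path)
  }
  meta <- df[, !is_channel, drop = FALSE]
  if ("concentration_mM" %in% names(meta) &&
      !is.numeric(meta$concentration_mM)) {
    conc <- suppressWarnings(as.numeric(meta$concentration_mM))
    bad <- !is.na(meta$concentration_mM) & is.na(conc)
    if (any(bad)) {
      stop("unparseable concentration_mM for sample(s): ",
           paste(utils::head(meta$id[bad], 3L), collapse = ", "))
    }
    meta$concentration_mM <- conc
  }
  spectra_set(grid, absorbance, meta)
}
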