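# Readers and writers for the supported plain-text and image formats.
# Unit conventions at the boundary: q in A^-1 and lengths in A for
# scattering; seconds and micrometers for FRAP; ppm for spectra; pixel
# size in nm for images.

#' Read a 1D scattering curve from ASCII
#'
#' Accepts whitespace- or comma-separated columns `q [A^-1]`, intensity,
#' and optionally 1-sigma uncertainty; lines starting with `#` (and blank
#' lines) are skipped. Rows are sorted ascending in `q`, intensities (and
#' sigmas) following their `q`.
#'
#' @param path File path.
#' @return A [scattering_curve()].
#' @export
read_scattering_curve <- function(path) {
  lines <- readLines(path, warn = FALSE)
  keep <- !grepl("^\\s*(#|$)", lines)
  lines <- lines[keep]
  lineno <- which(keep)
  if (length(lines) == 0L) stop("no data rows in ", path)
  rows <- lapply(seq_along(lines), function(i) {
    f <- strsplit(trimws(lines[i]), "[,[:space:]]+")[[1]]
    v <- suppressWarnings(as.numeric(f))
    if (length(v) < 2 || any(is.na(v)))
      stop(sprintf("non-numeric row at line %d of %s", lineno[i], path))
    v
  })
  ncols <- unique(vapply(rows, length, integer(1)))
  if (length(ncols) != 1L) stop("inconsistent column count in ", path)
  m <- do.call(rbind, rows)
  ord <- order(m[, 1])
  m <- m[ord, , drop = FALSE]
  scattering_curve(m[, 1], m[, 2],
                   sigma = if (ncols >= 3) m[, 3] else NULL)
}

#' Write a scattering curve as 3-column ASCII
#'
#' Emits the dialect [read_scattering_curve()] reads: a `#` header, then
#' whitespace-separated `q`, intensity, sigma (sigma column omitted when
#' absent), at 12 significant digits so that write/read round trips are
#' lossless to that precision.
#'
#' @param curve A [scattering_curve()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_scattering_curve <- function(curve, path) {
  stopifnot(inherits(curve, "scattering_curve"))
  if (is.null(curve$sigma)) {
    header <- "# q_invA intensity"
    body <- sprintf("%.12e %.12e", curve$q, curve$intensity)
  } else {
    header <- "# q_invA intensity sigma"
    body <- sprintf("%.12e %.12e %.12e", curve$q, curve$intensity,
                    curve$sigma)
  }
  writeLines(c(header, body), path)
  invisible(path)
}

#' Read a FRAP trace from CSV
#'
#' Requires columns `time_s` and `intensity`. Trace metadata
#' (`bleach_index`, `roi_radius_um`) may be supplied as extra columns
#' (constant per file) or as arguments (arguments win). Any further
#' columns are preserved in the `extras` attribute.
#'
#' @param path CSV path.
#' @param bleach_index,roi_radius_um Optional metadata overrides.
#' @return A [frap_trace()] with attribute `extras` (data frame of
#'   additional columns, or `NULL`).
#' @export
read_frap_trace <- function(path, bleach_index = NULL,
                            roi_radius_um = NULL) {
  df <- read.csv(path)
  need <- c("time_s", "intensity")
  missing_cols <- setdiff(need, names(df))
  if (length(missing_cols))
    stop("missing required columns: ", paste(missing_cols, collapse = ", "))
  if (is.null(bleach_index)) {
    if (!"bleach_index" %in% names(df))
      stop("bleach_index not given and not present as a column")
    bleach_index <- df$bleach_index[1]
  }
  if (is.null(roi_radius_um)) {
    if (!"roi_radius_um" %in% names(df))
      stop("roi_radius_um not given and not present as a column")
    roi_radius_um <- df$roi_radius_um[1]
  }
  extras <- df[setdiff(names(df), c(need, "bleach_index", "roi_radius_um"))]
  tr <- frap_trace(df$time_s, df$intensity, bleach_index, roi_radius_um)
  attr(tr, "extras") <- if (ncol(extras)) extras else NULL
  tr
}

#' Write a FRAP trace to CSV
#'
#' @param trace A [frap_trace()].
#' @param path Output path.
#' @param extras Optional data frame of extra columns to carry along.
#' @return `path`, invisibly.
#' @export
write_frap_trace <- function(trace, path, extras = NULL) {
  stopifnot(inherits(trace, "frap_trace"))
  df <- data.frame(time_s = trace$time, intensity = trace$intensity,
                   bleach_index = trace$bleach_index,
                   roi_radius_um = trace$roi_radius)
  if (!is.null(extras)) df <- cbind(df, extras)
  write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' Read a 31P spectrum from 2-column CSV
#'
#' Columns `ppm` and `intensity`; either ppm ordering is accepted (the
#' container stores ascending).
#'
#' @param path CSV path.
#' @return A [spectrum_31p()].
#' @export
read_spectrum <- function(path) {
  df <- read.csv(path)
  missing_cols <- setdiff(c("ppm", "intensity"), names(df))
  if (length(missing_cols))
    stop("missing required columns: ", paste(missing_cols, collapse = ", "))
  spectrum_31p(df$ppm, df$intensity)
}

#' Write a 31P spectrum to CSV
#'
#' @param spec A [spectrum_31p()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_spectrum <- function(spec, path) {
  stopifnot(inherits(spec, "spectrum_31p"))
  write.csv(data.frame(ppm = spec$ppm, intensity = spec$intensity), path,
            row.names = FALSE)
  invisible(path)
}

#' Read a single-channel micrograph from TIFF or PNG
#'
#' TIFF values are read natively (a 16-bit file yields integer gray
#' values 0..65535, preserved exactly on round trip through
#' [write_image()]); PNG values are returned on the 0..1 scale the format
#' decodes to. Multi-channel (RGB/RGBA) images are rejected: extract a
#' single channel upstream.
#'
#' @param path Path ending in `.tif`, `.tiff` or `.png`.
#' @param pixel_size_nm Pixel size, nm (default 64).
#' @return A [micrograph()].
#' @export
read_image <- function(path, pixel_size_nm = 64) {
  ext <- tolower(tools::file_ext(path))
  px <- switch(ext,
               tif = ,
               tiff = tiff::readTIFF(path, as.is = TRUE),
               png = png::readPNG(path),
               stop("unsupported image format: .", ext))
  if (length(dim(px)) == 3L)
    stop("multi-channel image: extract a single channel ",
         "(e.g. pixels[ , , 1]) before analysis")
  micrograph(matrix(as.numeric(px), nrow(px), ncol(px)), pixel_size_nm)
}

#' Write a micrograph as 16-bit grayscale TIFF
#'
#' Integer intensities in 0..65535 are stored exactly.
#'
#' @param img A [micrograph()].
#' @param path Output path (`.tif`/`.tiff`).
#' @return `path`, invisibly.
#' @export
write_image <- function(img, path) {
  stopifnot(inherits(img, "micrograph"))
  px <- img$pixels
  if (max(px) > 65535) stop("intensities exceed the 16-bit range")
  tiff::writeTIFF(px / 65535, path, bits.per.sample = 16)
  invisible(path)
}
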