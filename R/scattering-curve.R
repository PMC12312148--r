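#' One-dimensional scattering curve
#'
#' Container for an azimuthally averaged small-angle scattering curve:
#' momentum transfer `q` (inverse Angstrom), intensity (consistent units,
#' typically cm^-1 or arbitrary) and optional 1-sigma uncertainties.
#'
#' @param q Numeric vector of momentum transfer values, strictly increasing
#'   and positive (A^-1).
#' @param intensity Numeric vector of intensities, same length as `q`.
#' @param sigma Optional numeric vector of 1-sigma uncertainties, strictly
#'   positive, same length as `q`.
#'
#' @return An object of class `scattering_curve`: a list with elements
#'   `q`, `intensity` and `sigma` (`NULL` when absent).
#' @export
#' @examples
#' sc <- scattering_curve(q = c(0.01, 0.02), intensity = c(5, 2))
scattering_curve <- function(q, intensity, sigma = NULL) {
  q <- as.numeric(q)
  intensity <- as.numeric(intensity)
  if (length(q) == 0L) stop("empty scattering curve")
  if (length(q) != length(intensity))
    stop("q and intensity must have equal length")
  if (any(!is.finite(q)) || any(!is.finite(intensity)))
    stop("non-finite values in scattering curve")
  if (any(q <= 0)) stop("q must be strictly positive")
  if (is.unsorted(q, strictly = TRUE)) stop("q must be strictly increasing")
  if (!is.null(sigma)) {
    sigma <- as.numeric(sigma)
    if (length(sigma) != length(q)) stop("sigma length mismatch")
    if (any(!is.finite(sigma)) || any(sigma <= 0))
      stop("sigma must be strictly positive where present")
  }
  structure(list(q = q, intensity = intensity, sigma = sigma),
            class = "scattering_curve")
}

#' @export
print.scattering_curve <- function(x, ...) {
  cat(sprintf("<scattering_curve> %d points, q in [%g, %g] A^-1%s\n",
              length(x$q), min(x$q), max(x$q),
              if (is.null(x$sigma)) ", no uncertainties" else ""))
  invisible(x)
}

#' @export
as.data.frame.scattering_curve <- function(x, ...) {
  data.frame(q = x$q, intensity = x$intensity,
             sigma = if (is.null(x$sigma)) NA_real_ else x$sigma)
}
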