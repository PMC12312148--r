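# Static 31P powder lineshapes for lipid phase identification.
#
# For uniaxial chemical-shift anisotropy the resonance of a crystallite at
# angle theta to the field is delta(theta) = delta_perp +
# (delta_par - delta_perp) cos^2(theta). With cos(theta) uniform over the
# powder, the frequency density is p(delta) =
# 1 / (2 sqrt((delta - delta_perp)(delta_par - delta_perp))) between the
# two edges: an integrable singularity at delta_perp (the pattern maximum)
# and a shoulder extending to delta_par. Lamellar phases show the full
# anisotropy; fast lateral diffusion around the cylinders of an inverted
# hexagonal phase scales it by -1/2; isotropic tumbling collapses the
# pattern to a line at the isotropic shift.

#' 31P spectrum container
#'
#' @param ppm Chemical-shift grid, uniform spacing; stored ascending
#'   (descending input is reversed together with the intensities).
#' @param intensity Non-negative intensities, same length as `ppm`.
#' @return Object of class `spectrum_31p`.
#' @export
spectrum_31p <- function(ppm, intensity) {
  ppm <- as.numeric(ppm); intensity <- as.numeric(intensity)
  if (length(ppm) != length(intensity)) stop("ppm/intensity length mismatch")
  if (length(ppm) < 3) stop("spectrum too short")
  if (ppm[1] > ppm[length(ppm)]) {
    ppm <- rev(ppm); intensity <- rev(intensity)
  }
  d <- diff(ppm)
  if (any(d <= 0)) stop("ppm grid must be strictly monotone")
  if (max(d) - min(d) > 1e-6 * mean(d)) stop("ppm grid must be uniform")
  if (any(intensity < -1e-12)) stop("intensities must be non-negative")
  structure(list(ppm = ppm, intensity = pmax(intensity, 0)),
            class = "spectrum_31p")
}

#' Phase basis lineshape parameters
#'
#' @param kind One of `"lamellar"`, `"hexagonal"`, `"isotropic"`.
#' @param delta_perp,delta_par Perpendicular and parallel edges of the
#'   uniaxial powder pattern, ppm; must differ for non-isotropic kinds.
#'   Defaults encode the observed landmarks: lamellar maximum at -20 ppm
#'   with a shoulder toward +45 ppm; inverted-hexagonal maximum near
#'   +5 ppm with the shoulder on the low-ppm side (anisotropy of opposite
#'   sign and roughly half magnitude); isotropic line at 0 ppm.
#' @param sigma Gaussian broadening, ppm (default 1).
#' @param center Isotropic shift for `kind = "isotropic"`, ppm (default 0).
#' @return Object of class `phase_basis`.
#' @export
phase_basis <- function(kind = c("lamellar", "hexagonal", "isotropic"),
                        delta_perp = NULL, delta_par = NULL, sigma = 1,
                        center = 0) {
  kind <- match.arg(kind)
  if (sigma <= 0) stop("sigma must be positive")
  if (kind == "isotropic") {
    return(structure(list(kind = kind, delta_perp = center,
                          delta_par = center, sigma = sigma,
                          center = center),
                     class = "phase_basis"))
  }
  if (is.null(delta_perp) || is.null(delta_par)) {
    if (kind == "lamellar") {
      delta_perp <- -20; delta_par <- 45
    } else {
      delta_perp <- 5; delta_par <- -27.5
    }
  }
  if (delta_perp == delta_par)
    stop("zero anisotropy: delta_perp must differ from delta_par")
  structure(list(kind = kind, delta_perp = delta_perp,
                 delta_par = delta_par, sigma = sigma,
                 center = (2 * delta_perp + delta_par) / 3),
            class = "phase_basis")
}

#' Simulate a static uniaxial powder lineshape
#'
#' Computes the powder orientation density between `delta_perp` and
#' `delta_par` analytically per grid bin (via the cumulative distribution
#' `sqrt((delta - delta_perp) / (delta_par - delta_perp))`, exact even at
#' the edge singularity), convolves with a Gaussian of width `sigma`, and
#' normalizes to unit area. An isotropic basis gives a pure Gaussian at
#' its center.
#'
#' @param basis A [phase_basis()].
#' @param grid Uniform ppm grid on which to evaluate.
#' @return A [spectrum_31p()] with unit area (`sum(intensity) * dppm = 1`).
#' @export
powder_lineshape <- function(basis, grid = seq(-100, 100, by = 0.25)) {
  stopifnot(inherits(basis, "phase_basis"))
  grid <- sort(as.numeric(grid))
  h <- grid[2] - grid[1]
  if (basis$kind == "isotropic") {
    y <- dnorm(grid, mean = basis$center, sd = basis$sigma)
  } else {
    lo <- min(basis$delta_perp, basis$delta_par)
    hi <- max(basis$delta_perp, basis$delta_par)
    # CDF measured from delta_perp; oriented so mass accumulates from the
    # perpendicular edge regardless of sign of the anisotropy
    cdf <- function(x) {
      u <- (x - basis$delta_perp) / (basis$delta_par - basis$delta_perp)
      sqrt(pmin(pmax(u, 0), 1))
    }
    edges <- c(grid - h / 2, grid[length(grid)] + h / 2)
    ce <- cdf(pmin(pmax(edges, lo), hi))
    mass <- abs(diff(ce))
    # Gaussian broadening by discrete convolution
    kr <- ceiling(5 * basis$sigma / h)
    kern <- dnorm(seq(-kr, kr) * h, sd = basis$sigma)
    kern <- kern / sum(kern)
    y <- .conv_same(mass, kern) / h
  }
  area <- sum(y) * h
  if (area <= 0) stop("degenerate lineshape (grid misses the pattern)")
  spectrum_31p(grid, y / area)
}

.conv_same <- function(x, k) {
  n <- length(x); kr <- (length(k) - 1L) / 2L
  xp <- c(numeric(kr), x, numeric(kr))
  out <- numeric(n)
  for (i in seq_along(k)) out <- out + k[i] * xp[(i - 1L) + seq_len(n)]
  out
}

#' Weighted mixture of phase lineshapes
#'
#' Weighted sum of unit-area basis lineshapes; the result has total area
#' equal to the sum of the weights.
#'
#' @param bases List of [phase_basis()] objects.
#' @param weights Non-negative weights, one per basis.
#' @param grid Uniform ppm grid.
#' @return A [spectrum_31p()].
#' @export
mixture_spectrum <- function(bases, weights,
                             grid = seq(-100, 100, by = 0.25)) {
  if (length(bases) != length(weights)) stop("bases/weights length mismatch")
  if (any(weights < 0)) stop("weights must be non-negative")
  grid <- sort(as.numeric(grid))
  y <- numeric(length(grid))
  for (i in seq_along(bases)) {
    if (weights[i] > 0) {
      y <- y + weights[i] * powder_lineshape(bases[[i]], grid)$intensity
    }
  }
  spectrum_31p(grid, y)
}

#' Default three-phase basis set
#'
#' Lamellar, inverted-hexagonal and isotropic bases at the default
#' landmark positions (see [phase_basis()]).
#'
#' @param sigma Gaussian broadening applied to all three, ppm.
#' @return Named list of three [phase_basis()] objects.
#' @export
default_bases <- function(sigma = 1) {
  list(lamellar = phase_basis("lamellar", sigma = sigma),
       hexagonal = phase_basis("hexagonal", sigma = sigma),
       isotropic = phase_basis("isotropic", sigma = sigma))
}

#' Decompose a spectrum into phase fractions
#'
#' Non-negative least squares of the measured spectrum against unit-area
#' basis lineshapes evaluated on the same grid. Weights are in area units:
#' for a unit-area input spectrum they are the phase fractions.
#'
#' @param spec A [spectrum_31p()].
#' @param bases List of [phase_basis()] objects (default [default_bases()]).
#' @return List with `weights` (named when `bases` is named),
#'   `residual_norm` (relative: `||residual|| / ||spectrum||`) and
#'   `fitted` (a [spectrum_31p()]).
#' @export
decompose_spectrum <- function(spec, bases = default_bases()) {
  stopifnot(inherits(spec, "spectrum_31p"))
  A <- vapply(bases, function(b) powder_lineshape(b, spec$ppm)$intensity,
              numeric(length(spec$ppm)))
  if (qr(A)$rank < ncol(A))
    stop("basis lineshapes are linearly dependent on this grid")
  fit <- pracma::lsqnonneg(A, spec$intensity)
  w <- fit$x
  names(w) <- names(bases)
  fitted <- as.numeric(A %*% w)
  res <- sqrt(sum((spec$intensity - fitted)^2)) /
    sqrt(sum(spec$intensity^2))
  list(weights = w, residual_norm = res,
       fitted = spectrum_31p(spec$ppm, fitted))
}
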