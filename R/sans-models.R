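# Forward model: I(q) = s_bcc I_bcc + s_ves I_ves + s_lam I_lam + I_B.
#
# I_bcc = scale (dSLD)^2 V_p P(q) Z(q)   sphere form factor x BCC paracrystal
# I_ves = scale (phi/V_shell) A(q)^2      core-shell (hollow) sphere
# I_lam = scale P_bil(q) Z_N(q) / q^2     bilayer x stack paracrystal

# 3 j1(x)/x with j1(x) = (sin x - x cos x)/x^2; -> 1 as x -> 0.
.sphere_amp <- function(x) {
  out <- numeric(length(x))
  small <- abs(x) < 1e-4
  out[small] <- 1 - x[small]^2 / 10
  xl <- x[!small]
  out[!small] <- 3 * (sin(xl) - xl * cos(xl)) / xl^3
  out
}

#' Sphere form factor
#'
#' Normalized form factor of a homogeneous sphere,
#' `P(q) = [3 j1(qR)/(qR)]^2` with `j1(x) = (sin x - x cos x)/x^2`,
#' so that `P(0) = 1`.
#'
#' @param q Momentum transfer, A^-1, `>= 0`. Vectorized.
#' @param radius Sphere radius, A, `> 0`.
#' @return Dimensionless `P(q)` in `[0, 1]`.
#' @export
#' @examples
#' sphere_form_factor(0, 250)        # 1
#' sphere_form_factor(0.01, 250)
sphere_form_factor <- function(q, radius) {
  if (radius <= 0) stop("radius must be positive")
  if (any(q < 0)) stop("q must be >= 0")
  .sphere_amp(q * radius)^2
}

# Orientation average. The integrand is the product of three per-axis
# factors Z_k whose phases involve the primitive-cell vectors
# a/2 (-1,1,1), a/2 (1,-1,1), a/2 (1,1,-1) - three of the four cube body
# diagonals. The product is invariant under inversion and axis
# permutations but not under single sign flips (those swap in the fourth
# diagonal), so before restricting the domain we symmetrize: averaging
# the product over the four 3-subsets of the diagonals leaves the powder
# average unchanged and makes the integrand invariant under the full
# achiral cubic group. The symmetrized integrand is then integrated by a
# Gauss-Legendre product rule over the octant (cos(theta), phi in
# [0,1] x [0,pi/2]), which concentrates nodes where the sharp
# paracrystal ridges need them.
.orient_cache <- new.env(parent = emptyenv())

.orient_grid <- function(n_orient) {
  key <- as.character(n_orient)
  got <- .orient_cache[[key]]
  if (!is.null(got)) return(got)
  gu <- pracma::gaussLegendre(n_orient, 0, 1)        # u = cos(theta)
  gp <- pracma::gaussLegendre(n_orient, 0, pi / 2)   # phi
  u <- rep(gu$x, times = n_orient)
  phi <- rep(gp$x, each = n_orient)
  w <- rep(gu$w, times = n_orient) * rep(gp$w, each = n_orient)
  st <- sqrt(pmax(0, 1 - u^2))
  dirs <- cbind(st * cos(phi), st * sin(phi), u)
  grid <- list(bdot = .diag_dots(dirs), w = w / sum(w), symmetrize = TRUE)
  .orient_cache[[key]] <- grid
  grid
}

# dot products of unit directions with the four cube body diagonals
# (unnormalized, i.e. in units of a/2)
.diag_dots <- function(dirs) {
  cbind(-dirs[, 1] + dirs[, 2] + dirs[, 3],
        dirs[, 1] - dirs[, 2] + dirs[, 3],
        dirs[, 1] + dirs[, 2] - dirs[, 3],
        dirs[, 1] + dirs[, 2] + dirs[, 3])
}

# Z(q) for given diagonal phase terms; shared by quadrature and MC paths.
# bdot has 4 columns; when symmetrize is TRUE the four leave-one-out
# triple products are averaged, otherwise the first three columns (the
# primitive vectors) are used directly.
.bcc_z_given_dirs <- function(q, a, g, bdot, w, symmetrize = TRUE) {
  d_nn <- sqrt(3) / 2 * a
  delta_a <- g * d_nn
  f <- exp(-0.5 * delta_a^2 * q^2)
  f <- pmin(f, 1 - 1e-12)  # ideal-crystal limit g = 0 is singular on-peak
  vapply(seq_along(q), function(i) {
    qa <- q[i] * (a / 2)
    f2 <- f[i]^2
    one_m_f2 <- 1 - f2
    z1 <- one_m_f2 / (1 - 2 * f[i] * cos(qa * bdot[, 1]) + f2)
    z2 <- one_m_f2 / (1 - 2 * f[i] * cos(qa * bdot[, 2]) + f2)
    z3 <- one_m_f2 / (1 - 2 * f[i] * cos(qa * bdot[, 3]) + f2)
    if (symmetrize) {
      z4 <- one_m_f2 / (1 - 2 * f[i] * cos(qa * bdot[, 4]) + f2)
      zk <- (z1 * z2 * z3 + z1 * z2 * z4 + z1 * z3 * z4 + z2 * z3 * z4) / 4
    } else {
      zk <- z1 * z2 * z3
    }
    sum(w * zk)
  }, numeric(1))
}

#' Powder-averaged BCC paracrystal lattice factor
#'
#' Structure factor `Z(q)` of a body-centered-cubic paracrystal with
#' isotropic Gaussian lattice distortion, powder-averaged over orientations.
#' For each axis `k`, `Z_k = (1 - |F|^2) / (1 - 2|F| cos(a_k . q) + |F|^2)`
#' with `|F| = exp(-delta_a^2 q^2 / 2)` and `delta_a = g * d_nn`,
#' `d_nn = sqrt(3)/2 * a` the nearest-neighbor distance. The orientation
#' average uses a Gauss-Legendre product rule over the irreducible octant
#' (cubic symmetry). Peaks fall at the allowed BCC reflections
#' (`h + k + l` even); see [bragg_peaks()].
#'
#' @param q Momentum transfer, A^-1, `> 0`. Vectorized.
#' @param lattice_a Cubic lattice constant `a`, A.
#' @param g Distortion factor `g = delta_a / d_nn`, `>= 0`. Large `g`
#'   drives `Z -> 1` (uncorrelated particles).
#' @param n_orient Nodes per quadrature axis (total `n_orient^2`
#'   orientations). Default 150; minimum 8.
#' @return Dimensionless `Z(q)`, non-negative.
#' @export
bcc_lattice_factor <- function(q, lattice_a, g, n_orient = 150) {
  if (lattice_a <= 0) stop("lattice_a must be positive")
  if (g < 0) stop("distortion g must be >= 0")
  if (n_orient < 8) stop("n_orient must be at least 8")
  if (any(q <= 0)) stop("q must be strictly positive")
  grid <- .orient_grid(n_orient)
  .bcc_z_given_dirs(q, lattice_a, g, grid$bdot, grid$w, symmetrize = TRUE)
}

#' Monte-Carlo powder average of the BCC lattice factor
#'
#' Independent cross-check of the quadrature in [bcc_lattice_factor()]:
#' averages the same integrand over uniformly random orientations on the
#' sphere.
#'
#' @inheritParams bcc_lattice_factor
#' @param n_samples Number of random orientations.
#' @param seed Integer RNG seed.
#' @return Dimensionless `Z(q)`.
#' @export
bcc_lattice_factor_mc <- function(q, lattice_a, g, n_samples = 1e5,
                                  seed = 1) {
  if (lattice_a <= 0) stop("lattice_a must be positive")
  if (g < 0) stop("distortion g must be >= 0")
  withr::with_seed(seed, {
    u <- runif(n_samples, -1, 1)
    phi <- runif(n_samples, 0, 2 * pi)
    st <- sqrt(pmax(0, 1 - u^2))
    dirs <- cbind(st * cos(phi), st * sin(phi), u)
    .bcc_z_given_dirs(q, lattice_a, g, .diag_dots(dirs),
                      rep(1 / n_samples, n_samples), symmetrize = FALSE)
  })
}

#' BCC paracrystal intensity
#'
#' `I_bcc(q) = scale * (sld_particle - sld_solvent)^2 * V_p * P(q) * Z(q)`
#' with `V_p` the primary-particle volume, `P` the sphere form factor and
#' `Z` the powder-averaged paracrystal lattice factor.
#'
#' @param q Momentum transfer, A^-1, `> 0`.
#' @param p A [bcc_params()] object.
#' @param n_orient Orientation-average quadrature size, see
#'   [bcc_lattice_factor()].
#' @param Z Optional precomputed lattice factor on `q` (used by the fitter
#'   to avoid recomputing the orientation average when `lattice_a` and `g`
#'   are frozen).
#' @return Intensity, non-negative.
#' @export
bcc_intensity <- function(q, p, n_orient = 150, Z = NULL) {
  stopifnot(inherits(p, "bcc_params"))
  if (p$scale == 0) return(numeric(length(q)) + 0)
  if (is.null(Z)) Z <- bcc_lattice_factor(q, p$lattice_a, p$g, n_orient)
  vp <- 4 / 3 * pi * p$sphere_radius^3
  p$scale * (p$sld_particle - p$sld_solvent)^2 * vp *
    sphere_form_factor(q, p$sphere_radius) * Z
}

#' Core-shell vesicle intensity
#'
#' Scattering of large unilamellar vesicles (solvent-filled core-shell
#' sphere):
#' `A(q) = 3 V_core (rho_solv - rho_shell) j1(q R_core)/(q R_core)
#'       + 3 V_total (rho_shell - rho_solv) j1(q R_total)/(q R_total)`,
#' `I(q) = scale * (phi / V_shell) * A(q)^2`. At `q = 0` this reduces to
#' `scale * phi * V_shell * (rho_shell - rho_solv)^2`.
#'
#' @param q Momentum transfer, A^-1, `>= 0`.
#' @param p A [vesicle_params()] object.
#' @return Intensity, non-negative.
#' @export
vesicle_intensity <- function(q, p) {
  stopifnot(inherits(p, "vesicle_params"))
  r_tot <- p$r_core + p$thickness
  v_core <- 4 / 3 * pi * p$r_core^3
  v_tot <- 4 / 3 * pi * r_tot^3
  v_shell <- v_tot - v_core
  amp <- v_core * (p$sld_solvent - p$sld_shell) * .sphere_amp(q * p$r_core) +
    v_tot * (p$sld_shell - p$sld_solvent) * .sphere_amp(q * r_tot)
  p$scale * (p$phi / v_shell) * amp^2
}

#' Form factor of an infinite planar bilayer
#'
#' `P_bil(q) = (sin(q t) / (q t))^2`, equal to 1 at `q = 0`.
#'
#' @param q Momentum transfer, A^-1, `>= 0`.
#' @param thickness Bilayer thickness `t`, A, `> 0`.
#' @return Dimensionless, in `[0, 1]`.
#' @export
bilayer_form <- function(q, thickness) {
  if (thickness <= 0) stop("thickness must be positive")
  x <- q * thickness
  out <- numeric(length(x))
  small <- abs(x) < 1e-6
  out[small] <- 1
  out[!small] <- (sin(x[!small]) / x[!small])^2
  out
}

#' Lamellar-stack paracrystal interference function
#'
#' Interference term `Z_N(q)` of a one-dimensional paracrystal of `N`
#' bilayers at mean spacing `D` with a Gaussian spacing distribution of
#' width `sigma_d` (`w = exp(-sigma_d^2 q^2 / 2)`):
#' `Z_N = (1 - w^2)/(1 + w^2 - 2 w cos(qD)) + x_N S_N + (1 - x_N) S_{N+1}`
#' with `S_N = a_N / (N (1 + w^2 - 2 w cos(qD))^2)` and
#' `a_N = 4w^2 - 2(w^3 + w) cos(qD) - 4 w^{N+2} cos(NqD)
#'        + 2 w^{N+3} cos((N-1)qD) + 2 w^{N+1} cos((N+1)qD)`.
#' For non-integer `N` the convention `x_N = 1 - (N - floor(N))` mixes
#' stacks of `floor(N)` and `floor(N) + 1` layers. Identical to the direct
#' double sum `1 + (2/N) sum_{n=1}^{N-1} (N - n) w^n cos(n q D)`.
#'
#' @param q Momentum transfer, A^-1.
#' @param n_layers Mean number of layers `N`, real `>= 1`. `N = 1` gives
#'   `Z = 1` (no interference); `sigma_d -> Inf` likewise.
#' @param spacing_d Mean spacing `D`, A.
#' @param sigma_d Spacing standard deviation, A, `>= 0`.
#' @return Dimensionless `Z_N(q) >= 0`.
#' @export
stack_interference <- function(q, n_layers, spacing_d, sigma_d) {
  if (n_layers < 1) stop("n_layers must be >= 1")
  if (spacing_d <= 0) stop("spacing_d must be positive")
  if (sigma_d < 0) stop("sigma_d must be >= 0")
  w <- exp(-sigma_d^2 * q^2 / 2)
  cqd <- cos(q * spacing_d)
  den <- 1 + w^2 - 2 * w * cqd
  s_term <- function(n) {
    # valid from n = 1 (where it cancels the Lorentzian term: Z_1 = 1)
    an <- 4 * w^2 - 2 * (w^3 + w) * cqd -
      4 * w^(n + 2) * cos(n * q * spacing_d) +
      2 * w^(n + 3) * cos((n - 1) * q * spacing_d) +
      2 * w^(n + 1) * cos((n + 1) * q * spacing_d)
    an / (n * den^2)
  }
  n_lo <- floor(n_layers)
  x_n <- 1 - (n_layers - n_lo)
  z <- (1 - w^2) / den + x_n * s_term(n_lo) +
    (1 - x_n) * s_term(n_lo + 1)
  # near the paracrystal peaks (and the w -> 1 limit) the closed form
  # loses ~eps/den^2 digits to cancellation; the direct sum is stable
  bad <- den < 1e-2
  if (any(bad)) {
    z[bad] <- .stack_direct(q[bad], n_layers, spacing_d, sigma_d)
  }
  pmax(z, 0)
}

# Direct O(N) sum, also used as the test oracle for integer N.
.stack_direct <- function(q, n_layers, spacing_d, sigma_d) {
  w <- exp(-sigma_d^2 * q^2 / 2)
  one <- function(n) {
    s <- numeric(length(q))
    if (n >= 2) for (m in 1:(n - 1)) {
      s <- s + (n - m) * w^m * cos(m * q * spacing_d)
    }
    1 + 2 * s / n
  }
  n_lo <- floor(n_layers)
  x_n <- 1 - (n_layers - n_lo)
  x_n * one(n_lo) + (1 - x_n) * one(n_lo + 1)
}

#' Lamellar intensity
#'
#' `I_lam(q) = scale * P_bil(q) * Z_N(q) / q^2`; the physical prefactor
#' `2 pi drho^2 Gamma_m` is absorbed into `scale`. Diverges at `q = 0`, so
#' the evaluation domain is `q > 0`.
#'
#' @param q Momentum transfer, A^-1, strictly positive.
#' @param p A [lamellar_params()] object.
#' @return Intensity, non-negative.
#' @export
lamellar_intensity <- function(q, p) {
  stopifnot(inherits(p, "lamellar_params"))
  if (any(q <= 0)) stop("lamellar intensity requires q > 0")
  p$scale * bilayer_form(q, p$thickness) *
    stack_interference(q, p$n_layers, p$spacing_d, p$sigma_d) / q^2
}

#' Composite SANS intensity
#'
#' Linear superposition
#' `I(q) = I_bcc(q) + I_ves(q) + I_lam(q) + background`. Exactly linear in
#' each scale factor and in the background.
#'
#' @param q Momentum transfer, A^-1, strictly positive.
#' @param p A [composite_params()] object.
#' @inheritParams bcc_intensity
#' @return Intensity, non-negative for valid parameters.
#' @export
composite_intensity <- function(q, p, n_orient = 150, Z = NULL) {
  stopifnot(inherits(p, "composite_params"))
  bcc_intensity(q, p$bcc, n_orient = n_orient, Z = Z) +
    vesicle_intensity(q, p$vesicle) +
    lamellar_intensity(q, p$lamellar) +
    p$background
}

#' Allowed BCC Bragg reflections
#'
#' Positions `q_hkl = (2 pi / a) sqrt(h^2 + k^2 + l^2)` of the allowed
#' body-centered-cubic reflections (`h + k + l` even), deduplicated by
#' `h^2 + k^2 + l^2`, sorted ascending and truncated at `q_max`.
#'
#' @param lattice_a Cubic lattice constant `a`, A.
#' @param q_max Upper limit of returned peak positions, A^-1.
#' @return Data frame with columns `h`, `k`, `l` (a representative index
#'   with `h >= k >= l`) and `q` (A^-1).
#' @export
#' @examples
#' bragg_peaks(460, 0.05)  # (110) at 0.0193, (200) at 0.0273 A^-1
bragg_peaks <- function(lattice_a, q_max = 0.221) {
  if (lattice_a <= 0) stop("lattice_a must be positive")
  s_max <- (q_max * lattice_a / (2 * pi))^2
  h_max <- floor(sqrt(s_max))
  idx <- expand.grid(h = 0:h_max, k = 0:h_max, l = 0:h_max)
  idx <- idx[idx$h >= idx$k & idx$k >= idx$l, ]
  idx$s <- idx$h^2 + idx$k^2 + idx$l^2
  idx <- idx[idx$s > 0 & idx$s <= s_max & (idx$h + idx$k + idx$l) %% 2 == 0, ]
  idx <- idx[!duplicated(idx$s), ]
  idx <- idx[order(idx$s), ]
  data.frame(h = idx$h, k = idx$k, l = idx$l,
             q = 2 * pi / lattice_a * sqrt(idx$s))
}
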