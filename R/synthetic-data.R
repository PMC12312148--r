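# Seeded generators for every modality the analysis modules consume.
# Each generator is a pure function of its spec (including the seed) and
# returns the simulated data together with a ground-truth record, so tests
# can close the loop analysis(generate(spec)) ~ truth.

#' Generate a synthetic GUV ring micrograph
#'
#' The membrane is a radial Gaussian ring
#' `A * f(theta) * exp(-(r - R)^2 / (2 sigma_w^2))` over a flat
#' background, where `f(theta) = 1` outside domains and
#' `fold_amplitude` inside each (wrap-aware) angular domain interval.
#' Additive Gaussian noise is applied and the image clipped at zero.
#'
#' @param shape Image dimensions `c(nrow, ncol)`, px.
#' @param center Circle center `c(x, y)`, px.
#' @param radius Ring radius, px; `radius + 12` must fit inside the image.
#' @param membrane_width_sigma Radial Gaussian width of the membrane, px.
#' @param membrane_amplitude Peak membrane intensity above background.
#' @param background Background intensity.
#' @param domains List of `list(center_deg, width_deg, fold)` bright
#'   domains (`fold >= 1`), angles counterclockwise from +x, y up.
#' @param noise_sigma Additive Gaussian noise standard deviation.
#' @param seed Integer seed; identical seeds give bit-identical images.
#' @param pixel_size_nm Pixel size, nm.
#' @return List with `image` (a [micrograph()]) and `truth` (list with
#'   `circle`, a [vesicle_circle()], and `domains`).
#' @export
gen_guv_image <- function(shape = c(256, 256), center = c(128.5, 128.5),
                          radius = 60, membrane_width_sigma = 2,
                          membrane_amplitude = 100, background = 10,
                          domains = list(), noise_sigma = 0, seed = 1,
                          pixel_size_nm = 64) {
  if (center[1] - radius < 13 || center[2] - radius < 13 ||
      center[1] + radius > shape[2] - 12 ||
      center[2] + radius > shape[1] - 12)
    stop("circle (radius + 12 px margin) must fit inside the image")
  for (d in domains) {
    if (d$fold < 1) stop("domain fold_amplitude must be >= 1")
  }
  rows <- seq_len(shape[1]); cols <- seq_len(shape[2])
  xg <- matrix(cols, shape[1], shape[2], byrow = TRUE) - center[1]
  yg <- center[2] - matrix(rows, shape[1], shape[2])   # y up
  r <- sqrt(xg^2 + yg^2)
  theta <- (atan2(yg, xg) * 180 / pi) %% 360
  fmod <- matrix(1, shape[1], shape[2])
  for (d in domains) {
    dist <- abs((theta - d$center_deg + 180) %% 360 - 180)
    fmod[dist <= d$width_deg / 2] <- d$fold
  }
  img <- background + membrane_amplitude * fmod *
    exp(-(r - radius)^2 / (2 * membrane_width_sigma^2))
  if (noise_sigma > 0) {
    img <- withr::with_seed(seed, img + rnorm(length(img), 0, noise_sigma))
  }
  list(image = micrograph(pmax(img, 0), pixel_size_nm),
       truth = list(circle = vesicle_circle(center, radius),
                    domains = domains))
}

#' Uniform-disk FRAP recovery function
#'
#' Closed-form fractional recovery after bleaching a uniform disk of
#' radius `r`:
#' `f(t) = exp(-2 tau_D / t) * (I0(2 tau_D / t) + I1(2 tau_D / t))` with
#' `tau_D = r^2 / (4 D)` and `I0`, `I1` the modified Bessel functions.
#' The numeric root of `f = 1/2` gives `t_half = 0.224 r^2 / D`, the
#' relation used by [diffusion_coefficient()].
#'
#' @param t Time since bleach, s, `>= 0`. Vectorized.
#' @param D Diffusion coefficient, micrometer^2/s.
#' @param roi_radius ROI radius, micrometers.
#' @return Fractional recovery in `[0, 1)`; 0 at `t = 0`.
#' @export
soumpasis_recovery <- function(t, D, roi_radius) {
  if (D <= 0 || roi_radius <= 0) stop("D and roi_radius must be positive")
  tau <- roi_radius^2 / (4 * D)
  out <- numeric(length(t))
  pos <- t > 0
  x <- 2 * tau / t[pos]
  out[pos] <- besselI(x, 0, expon.scaled = TRUE) +
    besselI(x, 1, expon.scaled = TRUE)
  out
}

#' Generate a synthetic FRAP trace
#'
#' Pre-bleach plateau at `i_pre`, instantaneous bleach to
#' `i_0 = i_pre * (1 - bleach_depth)`, then diffusive recovery toward
#' `i_0 + mobile_fraction * (i_pre - i_0)` following the uniform-disk
#' recovery curve [soumpasis_recovery()], with additive Gaussian noise.
#'
#' @param D_true Diffusion coefficient, micrometer^2/s.
#' @param roi_radius ROI radius, micrometers.
#' @param i_pre Pre-bleach intensity, a.u.
#' @param bleach_depth Fraction of intensity removed by the bleach,
#'   `(0, 1]`.
#' @param mobile_fraction Mobile fraction in `[0, 1]`; the recovery
#'   fraction of the noise-free trace.
#' @param dt Sampling interval, s (default 0.04, i.e. 40 ms).
#' @param duration Post-bleach observation time, s; must exceed `dt`.
#' @param n_prebleach Number of pre-bleach samples (default 5).
#' @param noise_sigma Additive Gaussian noise, a.u.
#' @param seed Integer seed.
#' @return List with `trace` (a [frap_trace()]) and `truth` (list with
#'   `D`, `t_half` (the exact `0.224 r^2 / D`), `i_pre`, `i_0`,
#'   `mobile_fraction`).
#' @export
gen_frap_trace <- function(D_true = 2, roi_radius = 0.9, i_pre = 1,
                           bleach_depth = 0.8, mobile_fraction = 1,
                           dt = 0.04, duration = 4, n_prebleach = 5,
                           noise_sigma = 0, seed = 1) {
  if (bleach_depth <= 0 || bleach_depth > 1)
    stop("bleach_depth must be in (0, 1]")
  if (mobile_fraction < 0 || mobile_fraction > 1)
    stop("mobile_fraction must be in [0, 1]")
  if (dt >= duration) stop("dt must be smaller than duration")
  t_pre <- seq(0, by = dt, length.out = n_prebleach)
  t_post <- seq(t_pre[n_prebleach] + dt, by = dt,
                length.out = ceiling(duration / dt))
  i_0 <- i_pre * (1 - bleach_depth)
  i_plateau <- i_0 + mobile_fraction * (i_pre - i_0)
  f <- soumpasis_recovery(t_post - t_post[1], D_true, roi_radius)
  inten <- c(rep(i_pre, n_prebleach), i_0 + (i_plateau - i_0) * f)
  if (noise_sigma > 0) {
    inten <- withr::with_seed(seed,
                              inten + rnorm(length(inten), 0, noise_sigma))
  }
  list(trace = frap_trace(c(t_pre, t_post), inten,
                          bleach_index = n_prebleach + 1L,
                          roi_radius = roi_radius),
       truth = list(D = D_true, t_half = 0.224 * roi_radius^2 / D_true,
                    i_pre = i_pre, i_0 = i_0,
                    mobile_fraction = mobile_fraction))
}

#' Study-condition composite parameters
#'
#' Ground-truth parameter set used by the synthetic SANS generator:
#' microscopy-derived geometry (bilayer 30 A, BCC vesicle radius 250 A,
#' nearest-neighbor distance 450 A, i.e. lattice constant
#' `2/sqrt(3) * 450` A, large-vesicle radius 5000 A, lamellar spacing
#' 250 A) with scale factors balanced so that all three phases contribute
#' visibly over the 0.002-0.221 A^-1 window: the vesicle term dominates
#' the low-q shoulder, the BCC peaks stand out near their first two
#' reflections, the lamellar interference peak sits near `2 pi / D`, and
#' the flat background takes over at high q.
#'
#' @return A [composite_params()] object.
#' @export
sans_study_params <- function() {
  composite_params(
    bcc = bcc_params(scale = 1e5, sphere_radius = 250,
                     lattice_a = 2 / sqrt(3) * 450, g = 0.1),
    vesicle = vesicle_params(scale = 3e7, phi = 0.01, r_core = 4960,
                             thickness = 40),
    lamellar = lamellar_params(scale = 5e-4, thickness = 30, n_layers = 3,
                               spacing_d = 250, sigma_d = 25),
    background = 0.005)
}

#' Generate a synthetic SANS curve
#'
#' Evaluates the composite model on a log-spaced q grid and applies
#' multiplicative Gaussian noise: `I = I_true * (1 + rel * N(0,1))`, with
#' the uncertainty column `sigma = relative_noise * I_true`.
#'
#' @param params A [composite_params()] object (the ground truth).
#' @param q_min,q_max Measurement window, A^-1 (defaults 0.002, 0.221).
#' @param n_points Number of q points (`>= 50`, default 200).
#' @param relative_noise Relative noise level (0 gives the exact forward
#'   model and no sigma column).
#' @param seed Integer seed.
#' @param n_orient Orientation-average quadrature size for the BCC term.
#' @return List with `curve` (a [scattering_curve()]) and `truth` (list
#'   with `params` and the noise-free `intensity`).
#' @export
gen_sans_curve <- function(params = sans_study_params(), q_min = 0.002,
                           q_max = 0.221, n_points = 200,
                           relative_noise = 0.05, seed = 1,
                           n_orient = 150) {
  if (q_min <= 0 || q_min >= q_max) stop("need 0 < q_min < q_max")
  if (n_points < 50) stop("n_points must be at least 50")
  q <- exp(seq(log(q_min), log(q_max), length.out = n_points))
  i_true <- composite_intensity(q, params, n_orient = n_orient)
  if (relative_noise > 0) {
    i_obs <- withr::with_seed(seed,
                              i_true * (1 + relative_noise *
                                          rnorm(n_points)))
    curve <- scattering_curve(q, i_obs, sigma = relative_noise * i_true)
  } else {
    curve <- scattering_curve(q, i_true)
  }
  list(curve = curve, truth = list(params = params, intensity = i_true))
}

#' Generate a synthetic 31P spectrum
#'
#' Mixture of the default lamellar / inverted-hexagonal / isotropic basis
#' lineshapes with additive Gaussian noise (relative to the spectrum
#' maximum), clipped at zero.
#'
#' @param weights Non-negative weights for
#'   (lamellar, hexagonal, isotropic).
#' @param grid Uniform ppm grid.
#' @param sigma Basis Gaussian broadening, ppm.
#' @param relative_noise Noise standard deviation relative to the maximum
#'   intensity.
#' @param seed Integer seed.
#' @return List with `spectrum` (a [spectrum_31p()]) and `truth` (list
#'   with `weights` and `bases`).
#' @export
gen_nmr_spectrum <- function(weights = c(0.5, 0, 0.5),
                             grid = seq(-100, 100, by = 0.25), sigma = 1,
                             relative_noise = 0, seed = 1) {
  bases <- default_bases(sigma = sigma)
  spec <- mixture_spectrum(bases, weights, grid)
  if (relative_noise > 0) {
    y <- withr::with_seed(seed, {
      spec$intensity + rnorm(length(spec$ppm), 0,
                             relative_noise * max(spec$intensity))
    })
    spec <- spectrum_31p(spec$ppm, pmax(y, 0))
  }
  list(spectrum = spec,
       truth = list(weights = stats::setNames(weights, names(bases)),
                    bases = bases))
}
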