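# Parameter containers for the composite SANS model.
#
# Internal lengths are Angstrom, SLDs A^-2, q A^-1. The three scale factors
# are free amplitudes: they track, but are not equal to, phase volume
# fractions.

#' Parameters of the BCC paracrystal contribution
#'
#' Body-centered-cubic paracrystal of small spherical vesicles. The lattice
#' is parameterized by the cubic cell edge `lattice_a`; the nearest-neighbor
#' distance is `d_nn = sqrt(3)/2 * lattice_a`. The paracrystalline disorder
#' is the distortion factor `g = delta_a / d_nn`, with `delta_a` the
#' isotropic Gaussian displacement of lattice points.
#'
#' @param scale Dimensionless amplitude (absorbs the lattice/particle
#'   volume ratio). Non-negative.
#' @param sphere_radius Radius of the primary particle (small vesicle), A.
#' @param lattice_a Cubic lattice constant, A.
#' @param g Distortion factor, dimensionless, `>= 0`.
#' @param sld_particle,sld_solvent Scattering length densities, A^-2.
#'   Defaults: lipid 1e-6, D2O solvent 6.36e-6.
#' @return Object of class `bcc_params`.
#' @export
bcc_params <- function(scale = 1, sphere_radius = 250, lattice_a = 519.6,
                       g = 0.1, sld_particle = 1e-6, sld_solvent = 6.36e-6) {
  if (sphere_radius <= 0 || lattice_a <= 0) stop("lengths must be positive")
  if (g < 0) stop("distortion g must be >= 0")
  if (scale < 0) stop("scale must be >= 0")
  structure(list(scale = scale, sphere_radius = sphere_radius,
                 lattice_a = lattice_a, g = g,
                 sld_particle = sld_particle, sld_solvent = sld_solvent),
            class = "bcc_params")
}

#' Parameters of the large-vesicle contribution
#'
#' Core-shell sphere with solvent core (unilamellar vesicle). Total radius
#' is `r_core + thickness`.
#'
#' @param scale Dimensionless amplitude.
#' @param phi Volume fraction of shell material in `[0, 1]`. Degenerate with
#'   `scale` in fits; frozen by default.
#' @param r_core Core (lumen) radius, A.
#' @param thickness Shell (bilayer) thickness, A.
#' @param sld_shell,sld_solvent Scattering length densities, A^-2.
#' @return Object of class `vesicle_params`.
#' @export
vesicle_params <- function(scale = 1, phi = 0.01, r_core = 4960,
                           thickness = 40, sld_shell = 1e-6,
                           sld_solvent = 6.36e-6) {
  if (r_core <= 0) stop("r_core must be positive")
  if (thickness <= 0) stop("thickness must be positive")
  if (phi < 0 || phi > 1) stop("phi must be in [0, 1]")
  if (scale < 0) stop("scale must be >= 0")
  structure(list(scale = scale, phi = phi, r_core = r_core,
                 thickness = thickness, sld_shell = sld_shell,
                 sld_solvent = sld_solvent),
            class = "vesicle_params")
}

#' Parameters of the lamellar-stack contribution
#'
#' Stacks of `n_layers` planar bilayers of thickness `thickness` at mean
#' spacing `spacing_d` with Gaussian spacing spread `sigma_d`. The
#' `2 pi drho^2 Gamma_m` prefactor of the lamellar intensity is absorbed
#' into `scale`.
#'
#' @param scale Dimensionless amplitude.
#' @param thickness Bilayer thickness `t`, A.
#' @param n_layers Mean number of layers per stack, real `>= 1`. Non-integer
#'   values mix stacks of `floor(n)` and `floor(n) + 1` layers.
#' @param spacing_d Mean layer spacing `D`, A; must exceed `thickness`.
#' @param sigma_d Gaussian standard deviation of the spacing, A, `>= 0`.
#' @return Object of class `lamellar_params`.
#' @export
lamellar_params <- function(scale = 1, thickness = 30, n_layers = 3,
                            spacing_d = 250, sigma_d = 25) {
  if (thickness <= 0) stop("thickness must be positive")
  if (spacing_d <= thickness) stop("spacing_d must exceed thickness")
  if (n_layers < 1) stop("n_layers must be >= 1")
  if (sigma_d < 0) stop("sigma_d must be >= 0")
  if (scale < 0) stop("scale must be >= 0")
  structure(list(scale = scale, thickness = thickness, n_layers = n_layers,
                 spacing_d = spacing_d, sigma_d = sigma_d),
            class = "lamellar_params")
}

#' Parameters of the composite SANS model
#'
#' Linear superposition of BCC-paracrystal, large-vesicle and lamellar
#' scattering plus a flat incoherent background.
#'
#' @param bcc A [bcc_params()] object.
#' @param vesicle A [vesicle_params()] object.
#' @param lamellar A [lamellar_params()] object.
#' @param background Incoherent background intensity, `>= 0`.
#' @return Object of class `composite_params`.
#' @export
composite_params <- function(bcc = bcc_params(), vesicle = vesicle_params(),
                             lamellar = lamellar_params(), background = 0) {
  stopifnot(inherits(bcc, "bcc_params"), inherits(vesicle, "vesicle_params"),
            inherits(lamellar, "lamellar_params"))
  if (background < 0) stop("background must be >= 0")
  structure(list(bcc = bcc, vesicle = vesicle, lamellar = lamellar,
                 background = background),
            class = "composite_params")
}

# ---- flat parameter-vector view used by the fitter --------------------------

.par_names <- c(
  "bcc.scale", "bcc.sphere_radius", "bcc.lattice_a", "bcc.g",
  "bcc.sld_particle", "bcc.sld_solvent",
  "ves.scale", "ves.phi", "ves.r_core", "ves.thickness",
  "ves.sld_shell", "ves.sld_solvent",
  "lam.scale", "lam.thickness", "lam.n_layers", "lam.spacing_d",
  "lam.sigma_d", "background")

#' Flatten composite parameters to a named vector
#'
#' @param p A [composite_params()] object.
#' @return Named numeric vector with names like `"bcc.scale"`,
#'   `"lam.spacing_d"`, `"background"`.
#' @export
composite_to_vector <- function(p) {
  stopifnot(inherits(p, "composite_params"))
  v <- c(p$bcc$scale, p$bcc$sphere_radius, p$bcc$lattice_a, p$bcc$g,
         p$bcc$sld_particle, p$bcc$sld_solvent,
         p$vesicle$scale, p$vesicle$phi, p$vesicle$r_core,
         p$vesicle$thickness, p$vesicle$sld_shell, p$vesicle$sld_solvent,
         p$lamellar$scale, p$lamellar$thickness, p$lamellar$n_layers,
         p$lamellar$spacing_d, p$lamellar$sigma_d, p$background)
  names(v) <- .par_names
  v
}

#' Rebuild composite parameters from a named vector
#'
#' Inverse of [composite_to_vector()].
#'
#' @param v Named numeric vector covering all names in
#'   `composite_to_vector(composite_params())`.
#' @return A [composite_params()] object.
#' @export
vector_to_composite <- function(v) {
  stopifnot(all(.par_names %in% names(v)))
  composite_params(
    bcc = bcc_params(scale = v[["bcc.scale"]],
                     sphere_radius = v[["bcc.sphere_radius"]],
                     lattice_a = v[["bcc.lattice_a"]], g = v[["bcc.g"]],
                     sld_particle = v[["bcc.sld_particle"]],
                     sld_solvent = v[["bcc.sld_solvent"]]),
    vesicle = vesicle_params(scale = v[["ves.scale"]], phi = v[["ves.phi"]],
                             r_core = v[["ves.r_core"]],
                             thickness = v[["ves.thickness"]],
                             sld_shell = v[["ves.sld_shell"]],
                             sld_solvent = v[["ves.sld_solvent"]]),
    lamellar = lamellar_params(scale = v[["lam.scale"]],
                               thickness = v[["lam.thickness"]],
                               n_layers = v[["lam.n_layers"]],
                               spacing_d = v[["lam.spacing_d"]],
                               sigma_d = v[["lam.sigma_d"]]),
    background = v[["background"]])
}
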