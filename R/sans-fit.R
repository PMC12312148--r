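# Weighted least-squares fitting of the composite model.
#
# The BCC lattice factor dominates the cost of a model evaluation (an
# orientation average per q point), but depends only on (lattice_a, g,
# n_orient, q grid); it is memoized so fits with those frozen pay for it
# once.

.z_cache <- new.env(parent = emptyenv())

.z_cached <- function(q, a, g, n_orient) {
  key <- paste(c(signif(c(a, g), 15), n_orient, length(q),
                 signif(c(sum(q), q[1], q[length(q)]), 15)),
               collapse = "|")
  got <- .z_cache[[key]]
  if (!is.null(got)) return(got)
  z <- bcc_lattice_factor(q, a, g, n_orient)
  if (length(ls(.z_cache)) > 64) rm(list = ls(.z_cache), envir = .z_cache)
  .z_cache[[key]] <- z
  z
}

# Default frozen set: SLDs held at the D2O / phospholipid values, and the
# vesicle volume fraction (exactly degenerate with its scale factor).
.default_frozen <- c("bcc.sld_particle", "bcc.sld_solvent",
                     "ves.sld_shell", "ves.sld_solvent", "ves.phi")

.fit_bounds <- function(v, free) {
  lower <- numeric(length(free))
  upper <- rep(Inf, length(free))
  lengths <- c("bcc.sphere_radius", "bcc.lattice_a", "ves.r_core",
               "ves.thickness", "lam.thickness", "lam.spacing_d",
               "lam.sigma_d")
  for (i in seq_along(free)) {
    nm <- free[i]
    s <- v[[nm]]
    if (nm %in% lengths && s > 0) {
      lower[i] <- 0.1 * s
      upper[i] <- 10 * s
    } else if (nm == "lam.n_layers") {
      lower[i] <- 1
      upper[i] <- max(10 * s, 2)
    } else if (nm == "bcc.g") {
      lower[i] <- 1e-4
      upper[i] <- 10
    }
    # scales, background, sigma_d started at 0: [0, Inf)
  }
  list(lower = lower, upper = upper)
}

#' Fit the composite SANS model to a measured curve
#'
#' Weighted least squares (chi-square with the curve's uncertainties; unit
#' weights when absent) using bounded Levenberg-Marquardt. Parameters are
#' addressed by the flat names of [composite_to_vector()]; any subset can
#' be frozen. By default the scattering length densities are frozen at the
#' D2O solvent (6.36e-6 A^-2) and phospholipid (1e-6 A^-2) values, and the
#' vesicle volume fraction is frozen (it is exactly degenerate with the
#' vesicle scale factor). Length parameters are bounded to `[0.1, 10]`
#' times their starting value, scale factors and background to
#' `[0, Inf)`.
#'
#' @param curve A [scattering_curve()] with at least 10 points.
#' @param start A [composite_params()] object of starting values. The
#'   default [composite_start()] encodes the microscopy-derived starting
#'   geometry (bilayer 30 A, BCC vesicle radius 250 A, nearest-neighbor
#'   distance 450 A, large-vesicle radius 5000 A).
#' @param frozen Character vector of parameter names held fixed.
#' @param n_orient Orientation-average quadrature size for the BCC term.
#' @param max_iter Maximum Levenberg-Marquardt iterations.
#' @return Object of class `sans_fit`: list with `params` (fitted
#'   [composite_params()]), `chi2_reduced`, `param_uncertainties` (named,
#'   `NA` for frozen parameters), `converged`, `n_iterations`, `free`,
#'   `message`.
#' @export
fit_composite <- function(curve, start = composite_start(),
                          frozen = .default_frozen, n_orient = 150,
                          max_iter = 100) {
  stopifnot(inherits(curve, "scattering_curve"),
            inherits(start, "composite_params"))
  if (length(curve$q) < 10) stop("curve must have at least 10 points")
  if (all(curve$intensity == 0)) stop("degenerate curve: all intensities zero")
  bad <- setdiff(frozen, .par_names)
  if (length(bad)) stop("unknown parameter names: ", paste(bad, collapse = ", "))
  v0 <- composite_to_vector(start)
  free <- setdiff(.par_names, frozen)
  sig <- if (is.null(curve$sigma)) rep(1, length(curve$q)) else curve$sigma
  q <- curve$q

  model_at <- function(v) {
    p <- vector_to_composite(v)
    z <- if (p$bcc$scale > 0) {
      .z_cached(q, p$bcc$lattice_a, p$bcc$g, n_orient)
    } else NULL
    composite_intensity(q, p, n_orient = n_orient, Z = z)
  }
  resid_at <- function(x) {
    v <- v0
    v[free] <- x
    (model_at(v) - curve$intensity) / sig
  }

  if (length(free) == 0L) {
    r <- (model_at(v0) - curve$intensity) / sig
    unc <- rep(NA_real_, length(.par_names))
    names(unc) <- .par_names
    return(structure(list(params = start,
                          chi2_reduced = sum(r^2) / length(r),
                          param_uncertainties = unc, converged = TRUE,
                          n_iterations = 0L, free = character(),
                          message = "all parameters frozen"),
                     class = "sans_fit"))
  }

  b <- .fit_bounds(v0, free)
  fit <- minpack.lm::nls.lm(
    par = v0[free], fn = resid_at, lower = b$lower, upper = b$upper,
    control = minpack.lm::nls.lm.control(maxiter = max_iter))

  v_hat <- v0
  v_hat[free] <- fit$par
  r <- fit$fvec
  dof <- max(1L, length(r) - length(free))
  chi2_red <- sum(r^2) / dof
  unc <- rep(NA_real_, length(.par_names))
  names(unc) <- .par_names
  se <- tryCatch({
    cv <- chol2inv(chol(fit$hessian))
    sqrt(pmax(0, diag(cv)) * chi2_red)
  }, error = function(e) rep(NA_real_, length(free)))
  unc[free] <- se
  converged <- fit$info %in% 1:4 && fit$niter < max_iter
  structure(list(params = vector_to_composite(v_hat),
                 chi2_reduced = chi2_red, param_uncertainties = unc,
                 converged = converged, n_iterations = fit$niter,
                 free = free, message = fit$message),
            class = "sans_fit")
}

#' Default starting parameters for composite fits
#'
#' Starting geometry extrapolated from electron micrographs: bilayer
#' thickness 3 nm, BCC vesicle radius 25 nm, nearest-neighbor distance
#' 45 nm (converted to the primitive lattice constant
#' `a = 2/sqrt(3) * 450 A`), large-vesicle radius 500 nm; unit scale
#' factors and zero background.
#'
#' @param scale_bcc,scale_ves,scale_lam Starting scale factors.
#' @param background Starting background intensity.
#' @return A [composite_params()] object.
#' @export
composite_start <- function(scale_bcc = 1, scale_ves = 1, scale_lam = 1,
                            background = 0) {
  composite_params(
    bcc = bcc_params(scale = scale_bcc, sphere_radius = 250,
                     lattice_a = 2 / sqrt(3) * 450, g = 0.1),
    vesicle = vesicle_params(scale = scale_ves, r_core = 4960,
                             thickness = 40),
    lamellar = lamellar_params(scale = scale_lam, thickness = 30,
                               n_layers = 3, spacing_d = 250, sigma_d = 25),
    background = background)
}

#' @export
print.sans_fit <- function(x, ...) {
  cat(sprintf("<sans_fit> chi2_red = %.4g, %s after %d iterations\n",
              x$chi2_reduced,
              if (x$converged) "converged" else "NOT converged",
              x$n_iterations))
  v <- composite_to_vector(x$params)
  for (nm in x$free) {
    cat(sprintf("  %-18s %.6g (+/- %.3g)\n", nm, v[[nm]],
                x$param_uncertainties[[nm]]))
  }
  invisible(x)
}
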