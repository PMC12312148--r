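# Shared fixtures built in code.

# Ring image with angle-dependent radius and amplitude, for tests that
# need geometry the standard generator does not produce (bulges, decoys).
make_ring_image <- function(shape = c(256, 256), center = c(128.5, 128.5),
                            radius_fun = function(theta_deg) 40,
                            amplitude_fun = function(theta_deg) 100,
                            width_sigma = 2, background = 10) {
  rows <- seq_len(shape[1]); cols <- seq_len(shape[2])
  xg <- matrix(cols, shape[1], shape[2], byrow = TRUE) - center[1]
  yg <- center[2] - matrix(rows, shape[1], shape[2])
  r <- sqrt(xg^2 + yg^2)
  th <- (atan2(yg, xg) * 180 / pi) %% 360
  ring_r <- matrix(radius_fun(as.vector(th)), shape[1], shape[2])
  amp <- matrix(amplitude_fun(as.vector(th)), shape[1], shape[2])
  micrograph(background + amp * exp(-(r - ring_r)^2 / (2 * width_sigma^2)))
}

# Independent double-sum paracrystal oracle:
# Z_N(q) = (1/N) sum_{j,k=1..N} w^|j-k| cos((j-k) q D), integer N.
stack_double_sum <- function(q, n, spacing_d, sigma_d) {
  w <- exp(-sigma_d^2 * q^2 / 2)
  z <- numeric(length(q))
  for (j in seq_len(n)) for (k in seq_len(n)) {
    z <- z + w^abs(j - k) * cos((j - k) * q * spacing_d)
  }
  z / n
}

# Free-scales fit setup shared by fit tests and the acceptance script.
scale_names <- c("bcc.scale", "ves.scale", "lam.scale")
free_scale_fit <- function(curve, start, n_orient = 150) {
  frozen <- setdiff(names(composite_to_vector(start)),
                    c(scale_names, "background"))
  fit_composite(curve, start = start, frozen = frozen, n_orient = n_orient)
}

perturbed_scale_start <- function(truth) {
  start <- truth
  start$bcc$scale <- 2 * truth$bcc$scale
  start$vesicle$scale <- 0.5 * truth$vesicle$scale
  start$lamellar$scale <- 2 * truth$lamellar$scale
  start$background <- 4 * truth$background
  start
}
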