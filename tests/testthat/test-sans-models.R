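test_that("sphere form factor has unit forward limit and the tan(x)=x zero", {
  expect_equal(sphere_form_factor(0, 250), 1)
  expect_equal(sphere_form_factor(0, 40), 1)
  # first zero of 3 j1(x)/x at the first positive root of tan x = x,
  # located independently by bisection on sin(x) - x cos(x)
  x_star <- uniroot(function(x) sin(x) - x * cos(x),
                    c(pi, 1.5 * pi), tol = 1e-12)$root
  expect_equal(x_star, 4.4934, tolerance = 1e-4)
  r <- 250
  expect_lt(sphere_form_factor(x_star / r, r), 1e-12)
  # monotone decreasing between the forward limit and the first zero
  qs <- seq(1e-4, x_star / r - 1e-4, length.out = 400)
  expect_true(all(diff(sphere_form_factor(qs, r)) < 0))
  expect_error(sphere_form_factor(0.01, -1), "positive")
  expect_error(sphere_form_factor(-0.01, 10), "q must")
})

test_that("bilayer form factor matches closed-form values", {
  t <- 30
  expect_equal(bilayer_form(0, t), 1)
  expect_equal(bilayer_form(pi / t, t), 0, tolerance = 1e-25)
  expect_equal(bilayer_form(pi / 2 / t, t), (2 / pi)^2)
  expect_error(bilayer_form(0.1, -3), "positive")
})

test_that("stack interference equals the double-sum oracle to 1e-10", {
  q <- seq(0.002, 0.221, length.out = 200)
  for (n in 2:10) {
    zc <- stack_interference(q, n, 250, 10)
    zo <- stack_double_sum(q, n, 250, 10)
    expect_lt(max(abs(zc - zo) / abs(zo)), 1e-10)
  }
})

test_that("stack interference handles degenerate and non-integer cases", {
  q <- seq(0.002, 0.221, length.out = 100)
  # single layer and fully uncorrelated layers carry no interference
  expect_equal(stack_interference(q, 1, 250, 10), rep(1, length(q)))
  expect_equal(stack_interference(q, 5, 250, 1e5), rep(1, length(q)),
               tolerance = 1e-10)
  # non-integer N mixes floor and ceiling stacks with x_N = 1 - frac(N)
  z <- stack_interference(q, 3.25, 250, 10)
  zo <- 0.75 * stack_double_sum(q, 3, 250, 10) +
    0.25 * stack_double_sum(q, 4, 250, 10)
  expect_equal(z, zo, tolerance = 1e-10)
  # w -> 1 region (q -> 0 with small sigma) falls back gracefully
  expect_equal(stack_interference(1e-9, 4, 250, 0.1), 4, tolerance = 1e-5)
  expect_error(stack_interference(q, 0.5, 250, 10), ">= 1")
})

test_that("BCC lattice factor peaks at the (110) reflection and flattens at large g", {
  q <- seq(0.002, 0.221, length.out = 400)
  z <- bcc_lattice_factor(q, 460, 0.05, n_orient = 150)
  q_peak <- q[which.max(z)]
  expect_lt(abs(q_peak - 2 * pi * sqrt(2) / 460), q[2] - q[1])
  # large distortion destroys lattice correlations: Z -> 1
  zb <- bcc_lattice_factor(c(0.01, 0.05, 0.2), 460, 10, n_orient = 60)
  expect_equal(zb, rep(1, 3), tolerance = 1e-6)
  expect_error(bcc_lattice_factor(q, 460, -0.1), ">= 0")
  expect_error(bcc_lattice_factor(q, 460, 0.1, n_orient = 4), "at least 8")
  expect_error(bcc_lattice_factor(c(0, 0.01), 460, 0.1), "positive")
})

test_that("quadrature orientation average is stable and matches Monte Carlo", {
  # doubling the angular grid changes Z by < 0.1% on the validated window
  q <- exp(seq(log(0.006), log(0.221), length.out = 40))
  z1 <- bcc_lattice_factor(q, 519.6, 0.1, n_orient = 150)
  z2 <- bcc_lattice_factor(q, 519.6, 0.1, n_orient = 300)
  expect_lt(max(abs(z1 - z2) / z2), 1e-3)
  # unsymmetrized full-sphere MC agrees where its standard error allows 1%
  qs <- c(0.05, 0.1, 0.2)
  zq <- bcc_lattice_factor(qs, 460, 0.05, n_orient = 150)
  zm <- bcc_lattice_factor_mc(qs, 460, 0.05, n_samples = 1e5, seed = 11)
  expect_lt(max(abs(zq - zm) / zm), 0.01)
  # near the sharp (110) ridge the MC estimate is noisier; 5% at 4e5 draws
  zq1 <- bcc_lattice_factor(0.0193, 460, 0.05, n_orient = 150)
  zm1 <- bcc_lattice_factor_mc(0.0193, 460, 0.05, n_samples = 4e5, seed = 11)
  expect_lt(abs(zq1 - zm1) / zm1, 0.05)
})

test_that("BCC intensity reduces to sphere scattering and scales linearly", {
  q <- seq(0.005, 0.2, length.out = 50)
  p0 <- bcc_params(scale = 0)
  expect_equal(bcc_intensity(q, p0, n_orient = 60), rep(0, length(q)))
  # g -> infinity: Z == 1, pure sphere scattering
  p <- bcc_params(scale = 2, sphere_radius = 250, lattice_a = 460, g = 10)
  vp <- 4 / 3 * pi * 250^3
  expect_equal(bcc_intensity(q, p, n_orient = 60),
               2 * (p$sld_particle - p$sld_solvent)^2 * vp *
                 sphere_form_factor(q, 250),
               tolerance = 1e-6)
  # intensity ratios are independent of the scale factor
  p1 <- bcc_params(scale = 1, g = 0.1)
  p2 <- bcc_params(scale = 7.3, g = 0.1)
  i1 <- bcc_intensity(c(0.01, 0.05), p1, n_orient = 60)
  i2 <- bcc_intensity(c(0.01, 0.05), p2, n_orient = 60)
  expect_equal(i1[1] / i1[2], i2[1] / i2[2])
})

test_that("vesicle intensity has the correct forward limit and zero contrast", {
  p <- vesicle_params(scale = 3, phi = 0.01, r_core = 4960, thickness = 40)
  r_tot <- 5000
  v_shell <- 4 / 3 * pi * (r_tot^3 - 4960^3)
  drho <- p$sld_shell - p$sld_solvent
  expect_equal(vesicle_intensity(0, p), 3 * 0.01 * v_shell * drho^2)
  p0 <- vesicle_params(sld_shell = 6.36e-6, sld_solvent = 6.36e-6)
  expect_equal(vesicle_intensity(seq(0, 0.2, 0.01), p0), rep(0, 21))
  expect_error(vesicle_params(r_core = -5), "positive")
  expect_error(vesicle_params(thickness = 0), "positive")
})

test_that("vesicle first minimum matches a radial shell-integration oracle", {
  p <- vesicle_params(r_core = 4960, thickness = 40)
  q <- seq(1e-4, 3e-3, length.out = 600)
  # brute-force amplitude: A(q) = 4 pi int_{Rc}^{Rt} drho r^2 sinc(qr) dr
  amp_num <- vapply(q, function(qi) {
    f <- function(r) (p$sld_shell - p$sld_solvent) * r^2 *
      sin(qi * r) / (qi * r)
    4 * pi * integrate(f, 4960, 5000, rel.tol = 1e-10)$value
  }, numeric(1))
  v_shell <- 4 / 3 * pi * (5000^3 - 4960^3)
  i_num <- (p$phi / v_shell) * amp_num^2
  i_mod <- vesicle_intensity(q, p)
  first_min <- function(y) {
    j <- which(diff(sign(diff(y))) > 0) + 1L
    j[1]
  }
  expect_lte(abs(first_min(i_mod) - first_min(i_num)), 1L)
  # and the curves themselves agree
  expect_equal(i_mod, i_num, tolerance = 1e-6)
})

test_that("lamellar intensity peaks near 2 pi / D and is linear in scale", {
  p <- lamellar_params(scale = 1, thickness = 30, n_layers = 20,
                       spacing_d = 250, sigma_d = 1)
  q <- seq(0.015, 0.04, length.out = 1000)
  i <- lamellar_intensity(q, p)
  expect_lt(abs(q[which.max(i)] - 2 * pi / 250), q[2] - q[1])
  p2 <- p; p2$scale <- 2
  expect_equal(lamellar_intensity(q, p2), 2 * i)
  # with interference switched off (huge sigma_d), I q^2 is the bilayer form
  pf <- lamellar_params(scale = 1, thickness = 30, n_layers = 4,
                        spacing_d = 250, sigma_d = 1e5)
  expect_equal(lamellar_intensity(q, pf) * q^2, bilayer_form(q, 30),
               tolerance = 1e-10)
  expect_error(lamellar_intensity(c(0, 0.01), p), "q > 0")
})

test_that("composite intensity is an exact linear superposition", {
  p <- sans_study_params()
  q <- exp(seq(log(0.002), log(0.221), length.out = 80))
  z <- bcc_lattice_factor(q, p$bcc$lattice_a, p$bcc$g, 60)
  total <- composite_intensity(q, p, n_orient = 60)
  expect_equal(total,
               bcc_intensity(q, p$bcc, Z = z) +
                 vesicle_intensity(q, p$vesicle) +
                 lamellar_intensity(q, p$lamellar) + p$background)
  # all scales zero: flat background
  p0 <- p
  p0$bcc$scale <- 0; p0$vesicle$scale <- 0; p0$lamellar$scale <- 0
  expect_equal(composite_intensity(q, p0, n_orient = 60),
               rep(p$background, length(q)))
  # doubling one scale doubles exactly that contribution
  p2 <- p; p2$lamellar$scale <- 2 * p$lamellar$scale
  expect_equal(composite_intensity(q, p2, n_orient = 60) - total,
               lamellar_intensity(q, p$lamellar))
  # nonnegative over the measurement window
  expect_true(all(total >= 0))
})

test_that("Bragg peak table respects the BCC selection rule and scaling", {
  pk <- bragg_peaks(460, 0.221)
  expect_equal(pk$q[1], 2 * pi * sqrt(2) / 460)
  expect_equal(pk$q[2], 2 * pi * 2 / 460)
  expect_equal(round(pk$q[1], 2), 0.02)
  expect_equal(round(pk$q[2], 3), 0.027)
  # h + k + l odd (e.g. (100), (111)) never appears
  expect_true(all((pk$h + pk$k + pk$l) %% 2 == 0))
  s <- pk$h^2 + pk$k^2 + pk$l^2
  expect_false(any(s %in% c(1, 3, 9)))
  expect_true(all(diff(pk$q) > 0))
  expect_true(all(pk$q <= 0.221))
  # doubling the lattice constant halves every reflection
  pk2 <- bragg_peaks(920, 0.221)
  expect_equal(pk2$q[seq_along(pk$q)], pk$q / 2)
})

test_that("parameter containers validate their invariants", {
  expect_error(bcc_params(g = -0.1), ">= 0")
  expect_error(bcc_params(lattice_a = 0), "positive")
  expect_error(lamellar_params(spacing_d = 20, thickness = 30), "exceed")
  expect_error(lamellar_params(n_layers = 0.5), ">= 1")
  expect_error(vesicle_params(phi = 1.5), "\\[0, 1\\]")
  expect_error(composite_params(background = -1), ">= 0")
  v <- composite_to_vector(sans_study_params())
  expect_equal(vector_to_composite(v), sans_study_params())
})
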