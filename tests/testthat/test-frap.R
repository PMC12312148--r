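test_that("pre-bleach normalization is exact and idempotent", {
  tr <- frap_trace(0:4, rep(5, 5), bleach_index = 3, roi_radius = 1)
  expect_equal(normalize_trace(tr)$intensity, rep(1, 5))
  tr2 <- frap_trace(0:2, c(2, 2, 1), bleach_index = 3, roi_radius = 1)
  expect_equal(normalize_trace(tr2)$intensity, c(1, 1, 0.5))
  expect_equal(normalize_trace(normalize_trace(tr2)), normalize_trace(tr2))
  bad <- frap_trace(0:2, c(0, 0, 1), bleach_index = 3, roi_radius = 1)
  expect_error(normalize_trace(bad), "positive")
})

test_that("half-time estimation follows the nearest-sample rule", {
  tr <- frap_trace(time = c(-0.1, 0, 0.1, 0.2, 0.3, 0.4),
                   intensity = c(1, 0.2, 0.45, 0.5, 0.7, 0.8),
                   bleach_index = 2, roi_radius = 1)
  ht <- estimate_half_time(tr)
  expect_equal(ht$i_0, 0.2)
  expect_equal(ht$i_inf, 0.8)
  expect_equal(ht$t_half, 0.2)
  # exact tie between two samples resolves to the earlier one
  tie <- frap_trace(time = 0:4, intensity = c(1, 0, 0.4, 0.6, 1),
                    bleach_index = 2, roi_radius = 1)
  expect_equal(estimate_half_time(tie)$t_half, 1)  # 0.4 beats 0.6 by order
  # no recovery flags instead of raising
  dead <- frap_trace(0:4, c(1, 0.5, 0.4, 0.35, 0.3), bleach_index = 2,
                     roi_radius = 1)
  ht2 <- estimate_half_time(dead)
  expect_false(ht2$recovered)
  expect_true(is.na(ht2$t_half))
})

test_that("half time of a noise-free uniform-disk curve matches 0.224 r^2 / D", {
  gen <- gen_frap_trace(D_true = 2, roi_radius = 1, dt = 0.005,
                        duration = 25, noise_sigma = 0)
  ht <- estimate_half_time(normalize_trace(gen$trace))
  expect_lt(abs(ht$t_half - 0.224 / 2), 0.005)  # within one sample
})

test_that("diffusion coefficient relation and scaling laws hold", {
  expect_equal(diffusion_coefficient(1, 0.224), 1)
  expect_equal(diffusion_coefficient(0.9, 0.1008), 1.8)
  expect_equal(diffusion_coefficient(2, 0.5), 4 * diffusion_coefficient(1, 0.5))
  # strictly decreasing in t_half, strictly increasing in r
  expect_true(all(diff(diffusion_coefficient(1, seq(0.1, 1, 0.1))) < 0))
  expect_true(all(diff(diffusion_coefficient(seq(0.4, 1.8, 0.2), 1)) > 0))
  expect_error(diffusion_coefficient(-1, 0.1), "positive")
  expect_error(diffusion_coefficient(1, 0), "positive")
})

test_that("recovery fraction covers full, zero and partial recovery", {
  expect_equal(recovery_fraction(1, 0.2, 1), 1)
  expect_equal(recovery_fraction(1, 0.2, 0.2), 0)
  expect_equal(recovery_fraction(1, 0.2, 0.8), 0.75)
  expect_error(recovery_fraction(1, 1, 0.5), "undefined")
})

test_that("D estimation is accurate across the measured radius and D range", {
  for (d_true in c(0.5, 2, 5)) {
    for (r in c(0.4, 0.9, 1.8)) {
      th <- 0.224 * r^2 / d_true
      gen <- gen_frap_trace(D_true = d_true, roi_radius = r, dt = th / 15,
                            duration = 150 * th, noise_sigma = 0)
      res <- frap_analyze(gen$trace)
      expect_lt(abs(res$D - d_true) / d_true, 0.05)
    }
  }
})

test_that("normalization leaves half time and recovery fraction invariant", {
  gen <- gen_frap_trace(D_true = 1.5, roi_radius = 0.9, dt = 0.01,
                        duration = 15, mobile_fraction = 0.8,
                        noise_sigma = 0.003, seed = 8, i_pre = 37)
  raw <- estimate_half_time(gen$trace)
  nrm <- estimate_half_time(normalize_trace(gen$trace))
  expect_equal(raw$t_half, nrm$t_half)
  pre_raw <- mean(gen$trace$intensity[1:5])
  expect_equal(recovery_fraction(pre_raw, raw$i_0, raw$i_inf),
               recovery_fraction(1, nrm$i_0, nrm$i_inf))
})

test_that("group comparison reproduces means, ratio and paired sign counts", {
  mk <- function(d) list(D = d)
  inside <- lapply(c(1.6, 1.8, 2.0), mk)
  outside <- lapply(c(3.2, 3.4, 3.6), mk)
  cmp <- compare_frap_groups(inside, outside)
  expect_equal(cmp$mean_inside, 1.8)
  expect_equal(cmp$mean_outside, 3.4)
  expect_equal(round(cmp$ratio_outside_inside, 1), 1.9)
  expect_equal(cmp$n_inside, 3L)
  expect_equal(cmp$sd_inside, sd(c(1.6, 1.8, 2.0)))
  # identical groups: unit ratio, no strict inequalities
  same <- lapply(c(2, 3), mk)
  cmp2 <- compare_frap_groups(same, same, inside_vesicle = c("a", "b"),
                              outside_vesicle = c("a", "b"))
  expect_equal(cmp2$ratio_outside_inside, 1)
  expect_equal(cmp2$n_slower_inside, 0L)
  expect_error(compare_frap_groups(list(), same), "at least one")
})

test_that("paired synthetic vesicles show slower inside-domain diffusion", {
  set.seed(42)
  n_ves <- 30
  d_in <- 1.8 * exp(rnorm(n_ves, 0, 0.25))
  d_out <- 3.4 * exp(rnorm(n_ves, 0, 0.25))
  inside <- lapply(d_in, function(d) list(D = d))
  outside <- lapply(d_out, function(d) list(D = d))
  ids <- sprintf("v%02d", seq_len(n_ves))
  cmp <- compare_frap_groups(inside, outside, ids, ids)
  expect_equal(cmp$n_paired, n_ves)
  expect_gte(cmp$n_slower_inside, ceiling(0.9 * n_ves))
})
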