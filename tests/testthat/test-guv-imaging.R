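test_that("Gaussian smoothing preserves totals and has an identity limit", {
  g <- gen_guv_image(radius = 40, noise_sigma = 0)
  img <- g$image
  expect_identical(smooth_image(img, 0)$pixels, img$pixels)
  const <- micrograph(matrix(7, 64, 64))
  expect_equal(smooth_image(const, 1.5)$pixels, const$pixels)
  # single bright pixel: peak reduced, total conserved by kernel
  # normalization (reflective boundary keeps mass in the image)
  spot <- matrix(0, 64, 64); spot[32, 32] <- 100
  sm <- smooth_image(micrograph(spot), 1)
  expect_lt(max(sm$pixels), 100)
  expect_equal(sum(sm$pixels), 100, tolerance = 1e-6)
  # the input object is not mutated
  expect_equal(spot[32, 32], 100)
})

test_that("Hough detection recovers a synthetic ring to sub-pixel accuracy", {
  g <- gen_guv_image(center = c(128.5, 128.5), radius = 40,
                     membrane_amplitude = 100, noise_sigma = 10, seed = 3)
  circle <- detect_vesicle_circle(smooth_image(g$image, 1), c(20, 80))
  expect_lt(abs(circle$center[1] - 128.5), 1)
  expect_lt(abs(circle$center[2] - 128.5), 1)
  expect_lt(abs(circle$radius - 40), 1)
  # featureless image: classed detection failure
  expect_error(detect_vesicle_circle(micrograph(matrix(5, 128, 128))),
               class = "guv_detection_error")
})

test_that("Hough detection is translation-equivariant", {
  g1 <- gen_guv_image(center = c(120.5, 130.5), radius = 40,
                      noise_sigma = 10, seed = 4)
  g2 <- gen_guv_image(center = c(125.5, 127.5), radius = 40,
                      noise_sigma = 10, seed = 4)
  c1 <- detect_vesicle_circle(smooth_image(g1$image, 1), c(20, 80))
  c2 <- detect_vesicle_circle(smooth_image(g2$image, 1), c(20, 80))
  expect_lt(abs((c2$center[1] - c1$center[1]) - 5), 1)
  expect_lt(abs((c2$center[2] - c1$center[2]) - (-3)), 1)
})

test_that("radial maximum search finds the membrane and tracks bulges", {
  perfect <- make_ring_image(radius_fun = function(th) rep(40, length(th)))
  circle <- vesicle_circle(c(128.5, 128.5), 40)
  pts <- radial_max_positions(perfect, circle, n_angles = 360)
  expect_true(all(abs(pts$r - 40) <= 0.5))
  # +3 px bulge over 20 degrees around 90 degrees is followed
  bulged <- make_ring_image(radius_fun = function(th) {
    40 + 3 * (abs((th - 90 + 180) %% 360 - 180) <= 10)
  })
  ptsb <- radial_max_positions(bulged, circle, n_angles = 360)
  on_bulge <- abs((ptsb$angle_deg - 90 + 180) %% 360 - 180) <= 8
  off_bulge <- abs((ptsb$angle_deg - 90 + 180) %% 360 - 180) >= 15
  expect_true(all(abs(ptsb$r[on_bulge] - 43) <= 0.75))
  expect_true(all(abs(ptsb$r[off_bulge] - 40) <= 0.75))
})

test_that("a decoy ring outside the search window is never selected", {
  decoy <- make_ring_image(
    radius_fun = function(th) rep(40, length(th)),
    amplitude_fun = function(th) rep(100, length(th)))
  bright <- make_ring_image(
    radius_fun = function(th) rep(60, length(th)),
    amplitude_fun = function(th) rep(300, length(th)), background = 0)
  both <- micrograph(decoy$pixels + bright$pixels)
  pts <- radial_max_positions(both, vesicle_circle(c(128.5, 128.5), 40),
                              n_angles = 360, window_px = 10)
  expect_true(all(pts$r <= 50))
  expect_true(all(abs(pts$r - 40) <= 0.5))
})

test_that("membrane mask skeletonizes to a single closed 1-px loop", {
  g <- gen_guv_image(radius = 40, noise_sigma = 5, seed = 6)
  sm <- smooth_image(g$image, 1)
  circle <- detect_vesicle_circle(sm, c(20, 80))
  pts <- radial_max_positions(sm, circle, n_angles = 360)
  mask <- build_membrane_mask(pts, dim(sm$pixels))
  expect_true(attr(mask, "closed"))
  sk <- matrix(as.logical(mask), nrow(mask))
  # one 8-connected skeleton component (flood fill from any pixel reaches
  # all), and exactly two 4-connected complement components (inside +
  # outside): the topology of a single closed loop
  seed <- matrix(FALSE, nrow(sk), ncol(sk))
  seed[which(sk)[1]] <- TRUE
  repeat {
    grown <- seed
    for (dr in -1:1) for (dc in -1:1) {
      grown <- grown | memphase:::.shift_mat(seed, dr, dc)
    }
    grown <- grown & sk
    if (identical(grown, seed)) break
    seed <- grown
  }
  expect_identical(seed, sk)
  expect_equal(max(EBImage::bwlabel(matrix(as.numeric(!sk), nrow(sk)))), 2)
  # 1 px wide: no solid 2x2 block
  blocks <- sk[-1, -1] & sk[-nrow(sk), -1] & sk[-1, -ncol(sk)] &
    sk[-nrow(sk), -ncol(sk)]
  expect_false(any(blocks))
  # skeleton stays within ~1 px (raster quantization) of the input points
  idx <- which(sk)
  rr <- (idx - 1) %% nrow(sk) + 1
  cc <- (idx - 1) %/% nrow(sk) + 1
  dmin <- vapply(seq_along(rr), function(i) {
    min(sqrt((pts$x - cc[i])^2 + (pts$y - rr[i])^2))
  }, numeric(1))
  expect_lt(max(dmin), 1.5)
  # thinning an already-thin curve is the identity
  expect_identical(memphase:::.thin_zhangsuen(sk), sk)
  expect_error(build_membrane_mask(pts[1:2, ], dim(sm$pixels)), "at least 3")
})

test_that("angular profile is flat for uniform rings and elevated on domains", {
  g <- gen_guv_image(radius = 40, noise_sigma = 10, seed = 7)  # SNR 10
  res <- guv_profile_pipeline(g$image, r_range = c(20, 80))
  cv <- sd(res$profile$intensity) / mean(res$profile$intensity)
  expect_lt(cv, 0.05)
  expect_gte(diff(range(res$profile$angle_deg)), 350)
  expect_equal(nrow(res$domains), 0L)
  # a 2x bright 30-degree arc produces one contiguous elevated interval
  g2 <- gen_guv_image(radius = 40,
                      domains = list(list(center_deg = 200, width_deg = 30,
                                          fold = 2.5)),
                      noise_sigma = 10, seed = 8)
  res2 <- guv_profile_pipeline(g2$image, r_range = c(20, 80))
  expect_equal(nrow(res2$domains), 1L)
  expect_lt(abs(res2$domains$center_deg - 200), 5)
  expect_lt(abs(res2$domains$span_deg - 30), 5)
  expect_gt(res2$domains$mean_fold, 2)
})

test_that("domain detection respects threshold monotonicity", {
  g <- gen_guv_image(radius = 40,
                     domains = list(list(center_deg = 45, width_deg = 40,
                                         fold = 2.2),
                                    list(center_deg = 225, width_deg = 20,
                                         fold = 3)),
                     noise_sigma = 5, seed = 9)
  res <- guv_profile_pipeline(g$image, r_range = c(20, 80))
  counts <- vapply(c(1.5, 2, 2.5, 3.2),
                   function(f) nrow(detect_domains(res$profile, f)),
                   numeric(1))
  expect_true(all(diff(counts) <= 0))
  expect_equal(nrow(detect_domains(res$profile, 2)), 2L)
})

test_that("profile extraction is rotation-consistent", {
  g <- gen_guv_image(radius = 40,
                     domains = list(list(center_deg = 0, width_deg = 30,
                                         fold = 2.5)),
                     noise_sigma = 5, seed = 10)
  res <- guv_profile_pipeline(g$image, r_range = c(20, 80))
  m <- g$image$pixels
  rot <- t(m)[nrow(m):1, ]   # 90-degree rotation, counterclockwise in x/y-up
  res90 <- guv_profile_pipeline(micrograph(rot), r_range = c(20, 80))
  # circular cross-correlation of the two profiles on a common 1-deg grid
  grid <- 0:359
  p1 <- approx(res$profile$angle_deg, res$profile$intensity, xout = grid,
               rule = 2)$y
  p2 <- approx(res90$profile$angle_deg, res90$profile$intensity, xout = grid,
               rule = 2)$y
  cc <- vapply(grid, function(s) {
    sum(p1 * p2[((grid + s) %% 360) + 1])
  }, numeric(1))
  lag <- grid[which.max(cc)]
  expect_lte(min(abs(lag - 90), abs(lag - 90 + 360), abs(lag - 90 - 360)), 2)
})
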