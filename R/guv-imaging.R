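# GUV membrane profiling: smooth -> circular Hough detection -> radial
# maximum search -> mask / skeleton -> per-angle intensity -> bright-domain
# detection.
#
# Coordinate convention: a micrograph is a matrix with rows = image rows
# (top row first) and columns = x. Physical coordinates are x = column,
# y up, so the angle of pixel (row, col) about center (cx, cy) is
# atan2(cy - row, col - cx), counterclockwise from the +x axis.

#' Single-channel fluorescence micrograph
#'
#' @param pixels Numeric matrix of non-negative intensities (rows = image
#'   rows, columns = x); both dimensions at least 64 px.
#' @param pixel_size_nm Pixel size, nm (default 64).
#' @return Object of class `micrograph`.
#' @export
micrograph <- function(pixels, pixel_size_nm = 64) {
  if (!is.matrix(pixels) || !is.numeric(pixels)) stop("pixels must be a numeric matrix")
  if (any(dim(pixels) < 64L)) stop("image must be at least 64 x 64 px")
  if (any(pixels < 0)) stop("intensities must be non-negative")
  if (pixel_size_nm <= 0) stop("pixel_size_nm must be positive")
  structure(list(pixels = pixels, pixel_size_nm = pixel_size_nm),
            class = "micrograph")
}

#' @export
print.micrograph <- function(x, ...) {
  cat(sprintf("<micrograph> %d x %d px, %g nm/px\n",
              nrow(x$pixels), ncol(x$pixels), x$pixel_size_nm))
  invisible(x)
}

#' Detected vesicle circle
#'
#' @param center Numeric `c(x, y)` in pixel coordinates (x = column,
#'   y = row index), sub-pixel.
#' @param radius Radius, px.
#' @return Object of class `vesicle_circle`.
#' @export
vesicle_circle <- function(center, radius) {
  if (length(center) != 2L || radius <= 0) stop("invalid circle")
  structure(list(center = as.numeric(center), radius = as.numeric(radius)),
            class = "vesicle_circle")
}

# reflective padding, separable convolution
.reflect_pad_idx <- function(n, r) {
  c(rev(seq_len(r) + 1L), seq_len(n), n - seq_len(r))
}

.conv1_rows <- function(m, k) {
  r <- (length(k) - 1L) / 2L
  pm <- m[.reflect_pad_idx(nrow(m), r), , drop = FALSE]
  out <- matrix(0, nrow(m), ncol(m))
  for (i in seq_along(k)) {
    out <- out + k[i] * pm[(i - 1L) + seq_len(nrow(m)), , drop = FALSE]
  }
  out
}

#' Gaussian smoothing of a micrograph
#'
#' Separable Gaussian convolution with reflective boundary handling; the
#' kernel is normalized to unit sum, so constant images are unchanged and
#' total intensity is conserved. `sigma = 0` is the identity.
#'
#' @param img A [micrograph()].
#' @param sigma Gaussian standard deviation, px, `>= 0`.
#' @return A smoothed [micrograph()]; the input is not modified.
#' @export
smooth_image <- function(img, sigma = 1) {
  stopifnot(inherits(img, "micrograph"))
  if (sigma < 0) stop("sigma must be >= 0")
  if (sigma == 0) return(img)
  r <- max(1L, ceiling(4 * sigma))
  k <- dnorm(seq(-r, r), sd = sigma)
  k <- k / sum(k)
  sm <- .conv1_rows(img$pixels, k)
  sm <- t(.conv1_rows(t(sm), k))
  micrograph(pmax(sm, 0), img$pixel_size_nm)
}

.conv1_cols <- function(m, k) t(.conv1_rows(t(m), k))

# Sobel gradients (x = column direction, y = row direction, increasing down)
.sobel <- function(m) {
  kd <- c(-1, 0, 1) / 2
  ks <- c(1, 2, 1) / 4
  gx <- .conv1_rows(.conv1_cols(m, kd), ks)  # d/dx, smoothed across rows
  gy <- .conv1_cols(.conv1_rows(m, kd), ks)  # d/dy, smoothed across cols
  list(gx = gx, gy = gy)
}

#' Detect a vesicle as a circle by circular Hough transform
#'
#' Sobel gradients are computed, strong-gradient pixels vote for circle
#' centers at `p +/- r * grad_hat` for each candidate radius, and the
#' highest-scoring accumulator cell over all radii wins. The center is
#' refined to sub-pixel precision by a vote-weighted centroid and the
#' radius by the mean distance of nearby edge pixels.
#'
#' @param img A [micrograph()] (smooth first for noisy data, see
#'   [smooth_image()]).
#' @param r_range Numeric `c(min, max)` candidate radius range, px.
#' @param edge_quantile Gradient-magnitude quantile above which pixels
#'   vote (default 0.97).
#' @param min_votes_frac Detection threshold: the best 5x5 accumulator
#'   neighborhood must collect at least this fraction of the voting edge
#'   pixels (default 0.1).
#' @return A [vesicle_circle()].
#' @section Errors: throws an error of class `guv_detection_error` when no
#'   accumulator peak exceeds the threshold (e.g. a featureless image).
#' @export
detect_vesicle_circle <- function(img, r_range = c(20, 120),
                                  edge_quantile = 0.97,
                                  min_votes_frac = 0.1) {
  stopifnot(inherits(img, "micrograph"))
  m <- img$pixels
  g <- .sobel(m)
  mag <- sqrt(g$gx^2 + g$gy^2)
  mmax <- max(mag)
  fail <- function(msg) stop(structure(class = c("guv_detection_error",
                                                 "error", "condition"),
                                       list(message = msg, call = NULL)))
  if (mmax <= 0) fail("no intensity gradients: detection failed")
  thr <- max(quantile(mag, edge_quantile), 0.1 * mmax)
  sel <- which(mag >= thr & mag > 0)
  if (length(sel) < 20) fail("too few edge pixels: detection failed")
  er <- (sel - 1L) %% nrow(m) + 1L
  ec <- (sel - 1L) %/% nrow(m) + 1L
  ux <- g$gx[sel] / mag[sel]
  uy <- g$gy[sel] / mag[sel]
  radii <- seq(round(r_range[1]), round(r_range[2]), by = 1)
  nr <- nrow(m); nc <- ncol(m)
  box5 <- rep(1, 5)
  best <- list(score = -1)
  for (r in radii) {
    cx <- round(c(ec - r * ux, ec + r * ux))
    cy <- round(c(er - r * uy, er + r * uy))
    ok <- cx >= 1 & cx <= nc & cy >= 1 & cy <= nr
    if (!any(ok)) next
    counts <- tabulate((cx[ok] - 1L) * nr + cy[ok], nbins = nr * nc)
    acc <- matrix(counts, nr, nc)
    # votes disperse over neighboring cells (sub-pixel center, finite ring
    # width): score 5x5 neighborhood sums, not single cells
    sm <- .conv1_rows(.conv1_cols(acc, box5), box5)
    s <- max(sm)
    if (s > best$score) {
      i <- which.max(sm)
      best <- list(score = s, r = r,
                   cy = (i - 1L) %% nr + 1L, cx = (i - 1L) %/% nr + 1L,
                   counts = counts)
    }
  }
  if (best$score < max(10, min_votes_frac * length(sel)))
    fail("no accumulator peak above threshold: detection failed")
  # sub-pixel center: vote-weighted centroid in a 7x7 window at the best r
  acc <- matrix(best$counts, nr, nc)
  win <- 3L
  rr <- max(1L, best$cy - win):min(nr, best$cy + win)
  cc <- max(1L, best$cx - win):min(nc, best$cx + win)
  wts <- acc[rr, cc]
  cy <- sum(rr * rowSums(wts)) / sum(wts)
  cx <- sum(cc * colSums(wts)) / sum(wts)
  # radius refinement: the gradient shells flank the intensity ridge, so
  # take the argmax of the angular-mean radial intensity profile instead
  rr <- seq(max(1, best$r - 5), best$r + 5, by = 0.25)
  th <- seq(0, 2 * pi, length.out = 181L)[-181L]
  prof <- vapply(rr, function(r) {
    xs <- cx + r * cos(th)
    ys <- cy - r * sin(th)
    inb <- xs >= 1 & xs <= nc & ys >= 1 & ys <= nr
    mean(.bilinear(m, xs[inb], ys[inb]))
  }, numeric(1))
  vesicle_circle(center = c(cx, cy), radius = rr[which.max(prof)])
}

.bilinear <- function(m, x, y) {
  # x = column, y = row, 1-based continuous coordinates
  x0 <- floor(x); y0 <- floor(y)
  x1 <- x0 + 1; y1 <- y0 + 1
  x0 <- pmin(pmax(x0, 1), ncol(m)); x1 <- pmin(pmax(x1, 1), ncol(m))
  y0 <- pmin(pmax(y0, 1), nrow(m)); y1 <- pmin(pmax(y1, 1), nrow(m))
  fx <- x - floor(x); fy <- y - floor(y)
  m[cbind(y0, x0)] * (1 - fx) * (1 - fy) +
    m[cbind(y0, x1)] * fx * (1 - fy) +
    m[cbind(y1, x0)] * (1 - fx) * fy +
    m[cbind(y1, x1)] * fx * fy
}

#' Radial maximum-intensity positions around a circle perimeter
#'
#' At equal angular increments, intensity is sampled (bilinear) along the
#' ray through the circle center, and the position of maximum intensity
#' within `+/- window_px` of the perimeter radius is returned. Rays have
#' total length `ray_factor` times the radius, which always covers the
#' search window. Angles whose sample points leave the image are skipped
#' and recorded in the `skipped_angles` attribute.
#'
#' @param img A [micrograph()] (typically smoothed).
#' @param circle A [vesicle_circle()].
#' @param n_angles Number of angular increments (`>= 36`; default 360).
#' @param window_px Half-width of the radial search window around the
#'   perimeter, px (default 10).
#' @param ray_factor Total ray length in units of the circle radius
#'   (default 5).
#' @param step Radial sampling step, px (default 0.25).
#' @return Data frame with columns `angle_deg` (counterclockwise from +x,
#'   y up), `x`, `y` (px, sub-pixel), `r` (px) and `intensity`; attribute
#'   `skipped_angles` lists skipped angles (degrees).
#' @export
radial_max_positions <- function(img, circle, n_angles = 360,
                                 window_px = 10, ray_factor = 5,
                                 step = 0.25) {
  stopifnot(inherits(img, "micrograph"), inherits(circle, "vesicle_circle"))
  if (n_angles < 36) stop("n_angles must be at least 36")
  m <- img$pixels
  cx <- circle$center[1]; cy <- circle$center[2]
  r0 <- circle$radius
  half_ray <- ray_factor * r0 / 2
  lo <- max(r0 - window_px, 0.5)
  hi <- min(r0 + window_px, half_ray)
  rs <- seq(lo, hi, by = step)
  angles <- (seq_len(n_angles) - 1L) * 360 / n_angles
  out <- vector("list", n_angles)
  skipped <- numeric(0)
  for (i in seq_len(n_angles)) {
    th <- angles[i] * pi / 180
    xs <- cx + rs * cos(th)
    ys <- cy - rs * sin(th)   # y up: increasing angle moves to lower rows
    if (any(xs < 1 | xs > ncol(m) | ys < 1 | ys > nrow(m))) {
      skipped <- c(skipped, angles[i])
      next
    }
    v <- .bilinear(m, xs, ys)
    j <- which.max(v)
    out[[i]] <- c(angles[i], xs[j], ys[j], rs[j], v[j])
  }
  out <- do.call(rbind, out[!vapply(out, is.null, logical(1))])
  df <- as.data.frame(out)
  names(df) <- c("angle_deg", "x", "y", "r", "intensity")
  attr(df, "skipped_angles") <- skipped
  df
}

# binary morphology helpers -------------------------------------------------

.disk_offsets <- function(radius) {
  d <- expand.grid(dr = -radius:radius, dc = -radius:radius)
  d[d$dr^2 + d$dc^2 <= radius^2, ]
}

.shift_mat <- function(m, dr, dc, fill = FALSE) {
  nr <- nrow(m); nc <- ncol(m)
  out <- matrix(fill, nr, nc)
  rs <- max(1, 1 + dr):min(nr, nr + dr)
  cs <- max(1, 1 + dc):min(nc, nc + dc)
  out[rs, cs] <- m[rs - dr, cs - dc]
  out
}

.dilate_disk <- function(mask, radius) {
  off <- .disk_offsets(radius)
  out <- matrix(FALSE, nrow(mask), ncol(mask))
  for (i in seq_len(nrow(off))) {
    out <- out | .shift_mat(mask, off$dr[i], off$dc[i])
  }
  out
}

.fill_small_holes <- function(mask, max_hole_px) {
  comp <- EBImage::bwlabel(matrix(as.numeric(!mask), nrow(mask)))
  labs <- as.integer(comp)
  if (!any(labs > 0)) return(mask)
  border_labs <- unique(c(comp[1, ], comp[nrow(comp), ],
                          comp[, 1], comp[, ncol(comp)]))
  sizes <- tabulate(labs)
  fill <- setdiff(which(sizes <= max_hole_px), border_labs)
  if (length(fill)) mask[matrix(labs %in% fill, nrow(mask))] <- TRUE
  mask
}

# Zhang-Suen thinning to a 1-px-wide 8-connected skeleton.
.thin_zhangsuen <- function(mask) {
  m <- mask
  repeat {
    changed <- FALSE
    for (pass in 1:2) {
      p2 <- .shift_mat(m, 1, 0);  p3 <- .shift_mat(m, 1, -1)
      p4 <- .shift_mat(m, 0, -1); p5 <- .shift_mat(m, -1, -1)
      p6 <- .shift_mat(m, -1, 0); p7 <- .shift_mat(m, -1, 1)
      p8 <- .shift_mat(m, 0, 1);  p9 <- .shift_mat(m, 1, 1)
      b <- p2 + p3 + p4 + p5 + p6 + p7 + p8 + p9
      a <- (!p2 & p3) + (!p3 & p4) + (!p4 & p5) + (!p5 & p6) +
        (!p6 & p7) + (!p7 & p8) + (!p8 & p9) + (!p9 & p2)
      if (pass == 1) {
        cond <- m & b >= 2 & b <= 6 & a == 1 &
          !(p2 & p4 & p6) & !(p4 & p6 & p8)
      } else {
        cond <- m & b >= 2 & b <= 6 & a == 1 &
          !(p2 & p4 & p8) & !(p2 & p6 & p8)
      }
      if (any(cond)) {
        m[cond] <- FALSE
        changed <- TRUE
      }
    }
    if (!changed) break
  }
  m
}

#' Build a skeletonized membrane mask from perimeter points
#'
#' Rasterizes the membrane points, dilates with a disk, fills small
#' enclosed holes (the vesicle interior, a large hole, is preserved), and
#' thins the result to a one-pixel-wide curve. A closed input ring yields
#' a single closed loop.
#'
#' @param points Data frame with `x`, `y` columns (px), e.g. from
#'   [radial_max_positions()]; at least 3 points.
#' @param dim Output mask dimensions `c(nrow, ncol)`.
#' @param dilate_radius Disk radius for the dilation, px (default 2;
#'   closes 1-px sampling gaps at 1-degree angular steps).
#' @param max_hole_px Maximum area of holes that get filled, px^2
#'   (default 50).
#' @return Logical matrix of class `membrane_mask` with attribute
#'   `closed`: `TRUE` when every skeleton pixel has at least two
#'   8-neighbors (closed contour), else `FALSE` (flagged open contour).
#' @export
build_membrane_mask <- function(points, dim, dilate_radius = 2,
                                max_hole_px = 50) {
  if (nrow(points) < 3) stop("need at least 3 membrane points")
  mask <- matrix(FALSE, dim[1], dim[2])
  rr <- pmin(pmax(round(points$y), 1), dim[1])
  cc <- pmin(pmax(round(points$x), 1), dim[2])
  mask[cbind(rr, cc)] <- TRUE
  mask <- .dilate_disk(mask, dilate_radius)
  mask <- .fill_small_holes(mask, max_hole_px)
  sk <- .thin_zhangsuen(mask)
  nb <- Reduce(`+`, lapply(seq_len(nrow(.eight_off)), function(i) {
    .shift_mat(sk, .eight_off$dr[i], .eight_off$dc[i])
  }))
  closed <- all(nb[sk] >= 2)
  structure(sk, class = c("membrane_mask", class(sk)), closed = closed)
}

.eight_off <- expand.grid(dr = -1:1, dc = -1:1)
.eight_off <- .eight_off[!(.eight_off$dr == 0 & .eight_off$dc == 0), ]

#' Per-angle membrane intensity profile
#'
#' For each skeleton pixel, the angle with respect to the circle centroid
#' (counterclockwise from +x, y up, degrees in `[0, 360)`) and the image
#' gray value at that pixel are recorded. The output is sorted by angle;
#' coincident angles are averaged.
#'
#' @param img A [micrograph()] supplying the gray values (by default the
#'   pipeline passes the smoothed image).
#' @param skeleton A [build_membrane_mask()] result (or any logical
#'   matrix of membrane pixels).
#' @param circle A [vesicle_circle()] giving the centroid.
#' @return Object of class `guv_profile`: data frame with `angle_deg`,
#'   `intensity`, `x`, `y`; attributes `circle` and `closed`.
#' @export
angular_profile <- function(img, skeleton, circle) {
  stopifnot(inherits(img, "micrograph"), inherits(circle, "vesicle_circle"))
  idx <- which(skeleton)
  if (length(idx) == 0L) stop("empty skeleton")
  rr <- (idx - 1L) %% nrow(skeleton) + 1L
  cc <- (idx - 1L) %/% nrow(skeleton) + 1L
  ang <- (atan2(circle$center[2] - rr, cc - circle$center[1]) * 180 / pi) %% 360
  val <- img$pixels[idx]
  ord <- order(ang)
  df <- data.frame(angle_deg = ang[ord], intensity = val[ord],
                   x = cc[ord], y = rr[ord])
  if (anyDuplicated(df$angle_deg)) {
    agg <- aggregate(df[c("intensity", "x", "y")],
                     by = list(angle_deg = df$angle_deg), FUN = mean)
    df <- agg[order(agg$angle_deg),
              c("angle_deg", "intensity", "x", "y")]
    rownames(df) <- NULL
  }
  structure(df, class = c("guv_profile", "data.frame"),
            circle = circle,
            closed = isTRUE(attr(skeleton, "closed")))
}

#' Detect bright membrane domains in an angular profile
#'
#' The baseline is the median profile intensity; contiguous angular runs
#' (circular, wrap-aware) at or above `fold_threshold` times the baseline
#' and spanning at least `min_span_deg` are reported.
#'
#' @param profile A [angular_profile()] result.
#' @param fold_threshold Intensity elevation threshold relative to the
#'   median baseline (default 2.0).
#' @param min_span_deg Minimum angular span of a reported domain, degrees
#'   (default 5).
#' @return Data frame with one row per domain: `start_deg`, `end_deg`
#'   (counterclockwise interval, `end` may wrap past 360), `center_deg`,
#'   `span_deg`, `mean_fold` (mean intensity / baseline over the run).
#' @export
detect_domains <- function(profile, fold_threshold = 2, min_span_deg = 5) {
  stopifnot(nrow(profile) > 0)
  base <- median(profile$intensity)
  empty <- data.frame(start_deg = numeric(0), end_deg = numeric(0),
                      center_deg = numeric(0), span_deg = numeric(0),
                      mean_fold = numeric(0))
  if (base <= 0) return(empty)
  above <- profile$intensity >= fold_threshold * base
  n <- length(above)
  if (!any(above)) return(empty)
  if (all(above)) {
    return(data.frame(start_deg = 0, end_deg = 360, center_deg = 180,
                      span_deg = 360,
                      mean_fold = mean(profile$intensity) / base))
  }
  # rotate so the sequence starts on a below-threshold sample
  shift <- which(!above)[1]
  rot <- function(v) c(v[shift:n], v[seq_len(shift - 1L)])
  a <- rot(above)
  ang <- rot(profile$angle_deg)
  inten <- rot(profile$intensity)
  runs <- rle(a)
  ends <- cumsum(runs$lengths)
  starts <- ends - runs$lengths + 1L
  out <- list()
  for (k in which(runs$values)) {
    i1 <- starts[k]; i2 <- ends[k]
    a1 <- ang[i1]; a2 <- ang[i2]
    span <- (a2 - a1) %% 360
    # pad by half the local angular sampling step on each side
    if (i2 < n || i1 > 1) {
      step <- 360 / n
      span <- span + step
    }
    if (span < min_span_deg) next
    center <- (a1 + ((a2 - a1) %% 360) / 2) %% 360
    out[[length(out) + 1L]] <- data.frame(
      start_deg = a1, end_deg = a1 + (a2 - a1) %% 360,
      center_deg = center, span_deg = span,
      mean_fold = mean(inten[i1:i2]) / base)
  }
  if (!length(out)) return(empty)
  do.call(rbind, out)
}

#' Full GUV membrane profiling pipeline
#'
#' Smooth (Gaussian, `sigma = 1` by default), detect the vesicle circle,
#' sample radial maxima, build the skeletonized membrane mask, extract the
#' angular intensity profile (from the smoothed image), and detect bright
#' domains.
#'
#' @param img A [micrograph()].
#' @param r_range Candidate radius range for the Hough detection, px.
#' @param sigma Smoothing sigma, px.
#' @param n_angles Angular sampling density.
#' @param fold_threshold Domain detection threshold.
#' @param window_px Radial search half-window, px.
#' @return List with `circle`, `points`, `mask`, `profile`, `domains`.
#' @export
guv_profile_pipeline <- function(img, r_range = c(20, 120), sigma = 1,
                                 n_angles = 360, fold_threshold = 2,
                                 window_px = 10) {
  stopifnot(inherits(img, "micrograph"))
  sm <- smooth_image(img, sigma)
  circle <- detect_vesicle_circle(sm, r_range)
  pts <- radial_max_positions(sm, circle, n_angles = n_angles,
                              window_px = window_px)
  mask <- build_membrane_mask(pts, dim(img$pixels))
  prof <- angular_profile(sm, mask, circle)
  doms <- detect_domains(prof, fold_threshold)
  list(circle = circle, points = pts, mask = mask, profile = prof,
       domains = doms)
}
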