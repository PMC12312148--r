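# FRAP analysis: half-time of recovery from a bleached circular ROI,
# diffusion coefficient D = 0.224 r^2 / t_half (uniform-disk model), and
# mobile fraction R = (I_inf - I_0) / (I_pre - I_0).

#' FRAP time-intensity trace
#'
#' @param time Acquisition times, s, strictly increasing (arbitrary,
#'   possibly non-uniform grids are accepted).
#' @param intensity Mean ROI intensities, arbitrary units.
#' @param bleach_index Index (1-based) of the first post-bleach sample;
#'   must leave at least one pre-bleach sample before it.
#' @param roi_radius ROI radius, micrometers, in `(0, 10]`.
#' @return Object of class `frap_trace`.
#' @export
frap_trace <- function(time, intensity, bleach_index, roi_radius) {
  time <- as.numeric(time)
  intensity <- as.numeric(intensity)
  if (length(time) != length(intensity)) stop("time/intensity length mismatch")
  if (is.unsorted(time, strictly = TRUE)) stop("time must be strictly increasing")
  bleach_index <- as.integer(bleach_index)
  if (bleach_index < 2L || bleach_index > length(time))
    stop("bleach_index must leave at least one pre-bleach sample")
  if (!is.finite(roi_radius) || roi_radius <= 0 || roi_radius > 10)
    stop("roi_radius must be in (0, 10] micrometers")
  structure(list(time = time, intensity = intensity,
                 bleach_index = bleach_index, roi_radius = roi_radius),
            class = "frap_trace")
}

#' Normalize a FRAP trace by its pre-bleach intensity
#'
#' Divides all intensities by the mean of the samples before the bleach,
#' so the normalized pre-bleach mean is exactly 1. Idempotent; half-time
#' and recovery fraction are invariant under this scaling.
#'
#' @param trace A [frap_trace()].
#' @return A [frap_trace()] with dimensionless intensities.
#' @export
normalize_trace <- function(trace) {
  stopifnot(inherits(trace, "frap_trace"))
  pre <- mean(trace$intensity[seq_len(trace$bleach_index - 1L)])
  if (!is.finite(pre) || pre <= 0) stop("pre-bleach mean must be positive")
  frap_trace(trace$time, trace$intensity / pre, trace$bleach_index,
             trace$roi_radius)
}

#' Estimate the half-recovery time of a FRAP trace
#'
#' `I_0` is the intensity directly after bleaching (the sample at
#' `bleach_index`), `I_inf` the last measurement point. The half time is
#' the time, measured from the `I_0` sample, of the post-bleach sample
#' whose intensity is closest to `(I_0 + I_inf)/2`; exact ties go to the
#' earlier sample. No interpolation or asymptote fitting is performed.
#'
#' @param trace A [frap_trace()] with at least 3 post-bleach samples.
#' @return List with `t_half` (s), `i_0`, `i_inf`, and `recovered`
#'   (`FALSE`, with `t_half = NA`, when `I_inf <= I_0`, i.e. no recovery).
#' @export
estimate_half_time <- function(trace) {
  stopifnot(inherits(trace, "frap_trace"))
  post <- seq.int(trace$bleach_index, length(trace$time))
  if (length(post) < 3L) stop("need at least 3 post-bleach samples")
  i0 <- trace$intensity[trace$bleach_index]
  iinf <- trace$intensity[length(trace$intensity)]
  if (iinf <= i0) {
    return(list(t_half = NA_real_, i_0 = i0, i_inf = iinf,
                recovered = FALSE))
  }
  target <- (i0 + iinf) / 2
  dev <- abs(trace$intensity[post] - target)
  j <- post[which.min(dev)]  # which.min takes the first = earlier on ties
  list(t_half = trace$time[j] - trace$time[trace$bleach_index],
       i_0 = i0, i_inf = iinf, recovered = TRUE)
}

#' Diffusion coefficient from ROI radius and half-recovery time
#'
#' Uniform-disk relation `D = 0.224 * r^2 / t_half`.
#'
#' @param roi_radius ROI radius `r`, micrometers, `> 0`.
#' @param t_half Half-recovery time, s, `> 0`.
#' @return Diffusion coefficient, micrometer^2 per second.
#' @export
#' @examples
#' diffusion_coefficient(1, 0.224)  # 1
diffusion_coefficient <- function(roi_radius, t_half) {
  if (any(roi_radius <= 0) || any(t_half <= 0))
    stop("roi_radius and t_half must be positive")
  0.224 * roi_radius^2 / t_half
}

#' Mobile (recovery) fraction
#'
#' `R = (I_inf - I_0) / (I_pre - I_0)`: 1 for full recovery, 0 for none.
#'
#' @param i_pre Mean pre-bleach intensity.
#' @param i_0 Intensity directly after bleaching; must differ from `i_pre`.
#' @param i_inf Intensity at the last measurement point.
#' @return Dimensionless recovery fraction.
#' @export
recovery_fraction <- function(i_pre, i_0, i_inf) {
  if (any(i_pre == i_0)) stop("recovery undefined when i_pre equals i_0")
  (i_inf - i_0) / (i_pre - i_0)
}

#' Full FRAP analysis of a single trace
#'
#' Normalizes by the pre-bleach mean, estimates the half time, and derives
#' the diffusion coefficient and recovery fraction.
#'
#' @param trace A [frap_trace()].
#' @return Object of class `frap_result`: list with `t_half`, `D`,
#'   `recovery_R`, `i_pre`, `i_0`, `i_inf`, `roi_radius`, `recovered`.
#'   When the trace shows no recovery, `D` and `t_half` are `NA` and
#'   `recovered` is `FALSE`.
#' @export
frap_analyze <- function(trace) {
  stopifnot(inherits(trace, "frap_trace"))
  nt <- normalize_trace(trace)
  ht <- estimate_half_time(nt)
  d <- if (ht$recovered && ht$t_half > 0) {
    diffusion_coefficient(nt$roi_radius, ht$t_half)
  } else NA_real_
  r <- recovery_fraction(1, ht$i_0, ht$i_inf)
  structure(list(t_half = ht$t_half, D = d, recovery_R = r,
                 i_pre = 1, i_0 = ht$i_0, i_inf = ht$i_inf,
                 roi_radius = nt$roi_radius, recovered = ht$recovered),
            class = "frap_result")
}

#' Compare inside-domain and outside-domain FRAP populations
#'
#' Group means and sample standard deviations of the diffusion
#' coefficient, the ratio of outside to inside mean, and (when vesicle
#' identifiers are given) per-vesicle paired counts of strictly slower
#' inside-domain diffusion.
#'
#' @param inside,outside Lists of [frap_analyze()] results (or plain lists
#'   with a `D` element), one group each; both nonempty.
#' @param inside_vesicle,outside_vesicle Optional vectors of vesicle
#'   identifiers parallel to `inside` / `outside`. For vesicles measured
#'   in both groups, per-vesicle mean D values are paired.
#' @return List with `mean_inside`, `sd_inside`, `n_inside`,
#'   `mean_outside`, `sd_outside`, `n_outside`, `ratio_outside_inside`,
#'   and, when pairing is possible, `n_paired` and `n_slower_inside`
#'   (vesicles with strictly `D_inside < D_outside`).
#' @export
compare_frap_groups <- function(inside, outside, inside_vesicle = NULL,
                                outside_vesicle = NULL) {
  d_in <- vapply(inside, function(x) as.numeric(x$D), numeric(1))
  d_out <- vapply(outside, function(x) as.numeric(x$D), numeric(1))
  d_in <- d_in[is.finite(d_in)]
  d_out <- d_out[is.finite(d_out)]
  if (length(d_in) == 0L || length(d_out) == 0L)
    stop("both groups must contain at least one finite D")
  out <- list(mean_inside = mean(d_in),
              sd_inside = if (length(d_in) > 1) sd(d_in) else NA_real_,
              n_inside = length(d_in),
              mean_outside = mean(d_out),
              sd_outside = if (length(d_out) > 1) sd(d_out) else NA_real_,
              n_outside = length(d_out),
              ratio_outside_inside = mean(d_out) / mean(d_in))
  if (!is.null(inside_vesicle) && !is.null(outside_vesicle)) {
    din <- vapply(inside, function(x) as.numeric(x$D), numeric(1))
    dout <- vapply(outside, function(x) as.numeric(x$D), numeric(1))
    min <- tapply(din, inside_vesicle, mean, na.rm = TRUE)
    mout <- tapply(dout, outside_vesicle, mean, na.rm = TRUE)
    common <- intersect(names(min), names(mout))
    out$n_paired <- length(common)
    out$n_slower_inside <- sum(min[common] < mout[common])
  }
  out
}
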