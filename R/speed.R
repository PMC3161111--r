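#' Convert a spectral peak angle to RBC speed
#'
#' The dominant orientation of the power spectrum of a line-scan image is a
#' central line perpendicular (in frequency space) to the dark RBC streaks.
#' With `theta` the angle between that line and the temporal-frequency axis,
#' the mean RBC speed is
#' \deqn{v = \frac{\Delta x}{\Delta t}\,|\cot\theta|}
#' and, since \eqn{\mu m/ms = mm/s}, expressing \eqn{\Delta x} in um/pixel
#' and \eqn{\Delta t} in ms/pixel yields mm/s directly. `theta = +-pi/2`
#' corresponds to stationary streaks (v = 0); `theta = 0` would imply an
#' unbounded speed (streaks parallel to the space axis cannot be resolved)
#' and is rejected.
#'
#' @param theta Angle in radians, in `[-pi/2, pi/2]`, measured from the
#'   temporal-frequency axis in physical (cycles/pixel) frequency units.
#' @param dx_um Spatial sampling interval (um/pixel, > 0).
#' @param dt_ms Temporal sampling interval (ms/pixel, > 0).
#' @return Speed in mm/s (non-negative).
#' @examples
#' speed_from_angle(pi / 4, dx_um = 1, dt_ms = 1)     # 1 mm/s
#' speed_from_angle(pi / 2, dx_um = 1, dt_ms = 1)     # 0 mm/s
#' @export
speed_from_angle <- function(theta, dx_um, dt_ms) {
  if (!is.numeric(dx_um) || dx_um <= 0 || !is.numeric(dt_ms) || dt_ms <= 0)
    stop("`dx_um` and `dt_ms` must be positive")
  if (!is.numeric(theta) || length(theta) != 1L || !is.finite(theta))
    stop("`theta` must be a single finite angle in radians")
  if (theta < -pi / 2 || theta > pi / 2)
    stop(sprintf("`theta` = %.4f rad outside [-pi/2, pi/2]", theta))
  if (theta == 0)
    stop(paste("speed out of measurable range: theta = 0 means streaks",
               "parallel to the space axis (unbounded speed)"))
  if (abs(abs(theta) - pi / 2) < .Machine$double.eps * 4) return(0)
  (dx_um / dt_ms) * abs(1 / tan(theta))
}

# Convert a peak angle on the index-space angular grid to the physical
# (cycles/pixel) angle. For an Ns x Nt image, one index step corresponds to
# 1/Ns cycles/pixel along the space axis and 1/Nt along the time axis, so
# the two agree only for square images.
index_angle_to_physical <- function(theta_idx, n_space, n_time) {
  atan2(sin(theta_idx) / n_space, cos(theta_idx) / n_time)
}

#' Estimate mean RBC speed from a line-scan image (2D FFT method)
#'
#' Pipeline: mean-subtracted 2D power spectrum ([compute_power_spectrum()]),
#' polar summation over a half circle of directions ([polar_sum()]), peak
#' angle detection ([find_peak_angle()]), and conversion to speed
#' ([speed_from_angle()]). For non-square images (e.g. short temporal
#' windows) the peak angle found on the index-space grid is converted to
#' physical frequency units before the speed conversion, so the estimate is
#' independent of the aspect ratio.
#'
#' With `window_pixels` set, the image is split into temporal windows of
#' that length (stride `stride_pixels`, default non-overlapping) and one
#' estimate is returned per window as a data frame. Temporal extents below
#' 8 pixels are rejected; extents of 8-31 pixels produce a warning, since
#' estimates from windows shorter than 32 pixels are unstable.
#'
#' @param img A [linescan_image()].
#' @param n_angles Angular resolution of the polar summation (default 180,
#'   i.e. pi/180).
#' @param R Radial summation limit; `NULL` for the per-window default
#'   `floor(min(dim)/2) - 1`.
#' @param window_pixels Optional temporal window length in pixels.
#' @param stride_pixels Window stride; defaults to `window_pixels`.
#' @param hann Logical; apply a Hann taper along both axes before the FFT
#'   to suppress rectangular-window leakage (default `FALSE`: the raw
#'   spectrum is used).
#' @return A `speed_estimate` (list with `speed_mm_s`, `theta_peak`
#'   (physical radians), `theta_index` (grid radians), `flow_sign`,
#'   `peak_prominence`, `window_pixels`, `method`, `profile`), or a data
#'   frame of per-window estimates when `window_pixels` is given.
#' @examples
#' sc <- streak_scene(speed_mm_s = 1, n_space = 64, n_time = 64,
#'                    noise_sd = 0, seed = 1)
#' est <- estimate_speed(make_linescan(sc)$image)
#' est$speed_mm_s
#' @export
estimate_speed <- function(img, n_angles = 180L, R = NULL,
                           window_pixels = NULL, stride_pixels = NULL,
                           hann = FALSE) {
  stopifnot(inherits(img, "linescan_image"))
  if (is.null(window_pixels)) {
    check_window_length(ncol(img$intensity))
    return(estimate_speed_once(img, n_angles, R, hann))
  }
  window_pixels <- as.integer(window_pixels)
  check_window_length(window_pixels)
  if (window_pixels > ncol(img$intensity))
    stop("`window_pixels` exceeds the temporal extent of the image")
  if (is.null(stride_pixels)) stride_pixels <- window_pixels
  starts <- seq(1L, ncol(img$intensity) - window_pixels + 1L,
                by = as.integer(stride_pixels))
  rows <- lapply(starts, function(s) {
    sub <- linescan_image(
      img$intensity[, s:(s + window_pixels - 1L), drop = FALSE],
      img$dx_um, img$dt_ms)
    est <- estimate_speed_once(sub, n_angles, R, hann)
    data.frame(window_start = s, window_pixels = window_pixels,
               speed_mm_s = est$speed_mm_s, theta_rad = est$theta_peak,
               flow_sign = est$flow_sign,
               peak_prominence = est$peak_prominence)
  })
  do.call(rbind, rows)
}

check_window_length <- function(w) {
  if (w < 8L)
    stop(sprintf("temporal window of %d pixels rejected: minimum is 8", w))
  if (w < 32L)
    warning(sprintf(paste(
      "temporal window of %d pixels: estimates from windows shorter than",
      "32 pixels are unstable"), w))
  invisible(w)
}

estimate_speed_once <- function(img, n_angles, R, hann) {
  work <- img
  if (isTRUE(hann)) {
    m <- img$intensity
    wr <- 0.5 - 0.5 * cos(2 * pi * (seq_len(nrow(m)) - 1) / (nrow(m) - 1))
    wc <- 0.5 - 0.5 * cos(2 * pi * (seq_len(ncol(m)) - 1) / (ncol(m) - 1))
    work <- linescan_image((m - mean(m)) * outer(wr, wc) + mean(m),
                           img$dx_um, img$dt_ms)
  }
  ps <- compute_power_spectrum(work)
  prof <- polar_sum(ps, n_angles = n_angles, R = R)
  pk <- find_peak_angle(prof)
  th <- index_angle_to_physical(pk$theta, nrow(img$intensity),
                                ncol(img$intensity))
  speed <- if (th == 0) {
    no_signal_error(
      "speed out of measurable range: spectral peak on the temporal axis")
  } else speed_from_angle(th, img$dx_um, img$dt_ms)
  structure(
    list(speed_mm_s = speed, theta_peak = th, theta_index = pk$theta,
         flow_sign = if (abs(abs(th) - pi / 2) < 1e-12) 0L else
           if (th < 0) 1L else -1L,
         peak_prominence = pk$prominence,
         window_pixels = ncol(img$intensity), method = "fft",
         profile = prof),
    class = "speed_estimate")
}

#' @export
print.speed_estimate <- function(x, ...) {
  cat(sprintf(
    "<speed_estimate> %.4g mm/s  [%s method]\n", x$speed_mm_s, x$method))
  cat(sprintf(
    "  theta = %.4f rad (%.2f deg), prominence %.3g, window %d px\n",
    x$theta_peak, x$theta_peak * 180 / pi, x$peak_prominence,
    x$window_pixels))
  invisible(x)
}

#' Frequency-domain bandpass filter for line-scan images
#'
#' Applies an annular mask `r_lo <= rho <= r_hi` (radial frequency rho in
#' cycles/pixel) to the spectrum and inverse-transforms. Useful for
#' suppressing slowly varying non-vascular background (high-pass) or
#' high-frequency noise (low-pass) before speed estimation or before
#' cell-level analyses.
#'
#' @param img A [linescan_image()].
#' @param r_lo,r_hi Radial band edges in cycles/pixel, `0 <= r_lo < r_hi`.
#'   The maximum meaningful radius is `sqrt(0.5)` (the spectrum corner), so
#'   `r_lo = 0, r_hi >= sqrt(0.5)` is the identity.
#' @return A filtered `linescan_image` (real-valued; intensities may dip
#'   below zero once the background band is removed).
#' @export
bandpass_filter <- function(img, r_lo, r_hi) {
  stopifnot(inherits(img, "linescan_image"))
  if (!is.numeric(r_lo) || !is.numeric(r_hi) || r_lo < 0 || r_lo >= r_hi)
    stop("need 0 <= r_lo < r_hi (cycles/pixel)")
  m <- img$intensity
  rho <- sqrt(outer(unshifted_freq(nrow(m))^2, unshifted_freq(ncol(m))^2,
                    "+"))
  mask <- rho >= r_lo & rho <= r_hi
  out <- Re(stats::fft(stats::fft(m) * mask, inverse = TRUE)) / length(m)
  structure(list(intensity = out, dx_um = img$dx_um, dt_ms = img$dt_ms),
            class = "linescan_image")
}

# Frequencies in fft() output order (DC first), cycles/pixel.
unshifted_freq <- function(n) {
  k <- 0:(n - 1)
  ifelse(k <= n / 2, k, k - n) / n
}
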