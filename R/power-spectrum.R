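#' Centered 2D power spectrum of a line-scan image
#'
#' Subtracts the image mean and returns the squared modulus of the 2D
#' discrete Fourier transform, reordered so the zero-frequency bin sits at
#' the array center. Mean subtraction makes the zero-frequency bin exactly
#' zero, so the radial summation is not dominated by the DC term.
#'
#' @param img A [linescan_image()].
#' @return An object of class `power_spectrum`: list with `power` (matrix,
#'   same shape as the image, all values >= 0), `f_space`, `f_time`
#'   (centered frequency axes in cycles/pixel) and `center` (row, col index
#'   of the zero-frequency bin).
#' @examples
#' img <- linescan_image(matrix(sin(2 * pi * (1:32) / 8), 32, 32),
#'                       dx_um = 0.2, dt_ms = 1)
#' ps <- compute_power_spectrum(img)
#' sum(ps$power > 1e-6)  # a pure sinusoid gives two symmetric peaks
#' @export
compute_power_spectrum <- function(img) {
  stopifnot(inherits(img, "linescan_image"))
  m <- img$intensity - mean(img$intensity)
  p <- fftshift2(Mod(stats::fft(m))^2)
  structure(
    list(power = p,
         f_space = freq_axis(nrow(p)),
         f_time = freq_axis(ncol(p)),
         center = c(floor(nrow(p) / 2) + 1L, floor(ncol(p) / 2) + 1L)),
    class = "power_spectrum")
}

#' @export
print.power_spectrum <- function(x, ...) {
  cat(sprintf("<power_spectrum> %d x %d, center (%d, %d), total power %.4g\n",
              nrow(x$power), ncol(x$power), x$center[1], x$center[2],
              sum(x$power)))
  invisible(x)
}

#' Angular profile of a power spectrum (polar summation)
#'
#' Converts the centered power spectrum to polar coordinates by bilinear
#' interpolation and sums it along rays from the center:
#' \deqn{g(\theta) = \sum_{r=1}^{R} F(r, \theta)}
#' over a half circle of directions (antipodal rays are equivalent because
#' the spectrum of a real image is point-symmetric). The angle is measured
#' from the temporal-frequency axis (array index units); `theta = 0` points
#' along the positive time-frequency axis, `+pi/2` along the positive
#' space-frequency axis. Radius `r = 0` (the DC bin) is excluded. Samples
#' falling outside the array contribute zero.
#'
#' @param ps A [compute_power_spectrum()] result.
#' @param n_angles Number of direction bins over `[-pi/2, pi/2)`;
#'   default 180 (resolution pi/180).
#' @param R Radial summation limit in pixels. Defaults to
#'   `floor(min(dim)/2) - 1`, the largest radius guaranteed inside the
#'   array (255 for a 512 x 512 image).
#' @return Object of class `angular_profile`: list with `theta_grid`
#'   (radians), `g` (summed power per angle), `R` and `n_angles`.
#' @export
polar_sum <- function(ps, n_angles = 180L, R = NULL) {
  stopifnot(inherits(ps, "power_spectrum"))
  if (!is.numeric(n_angles) || n_angles < 2L)
    stop("`n_angles` must be at least 2")
  n_angles <- as.integer(n_angles)
  r_max <- floor(min(dim(ps$power)) / 2) - 1L
  if (is.null(R)) R <- r_max
  if (R < 1L || R > r_max)
    stop(sprintf("`R` must be in [1, %d] for a %d x %d spectrum",
                 r_max, nrow(ps$power), ncol(ps$power)))
  theta <- -pi / 2 + (seq_len(n_angles) - 1L) * pi / n_angles
  r <- seq_len(R)
  ri <- ps$center[1] + outer(r, sin(theta))   # R x n_angles
  ci <- ps$center[2] + outer(r, cos(theta))
  f <- matrix(bilinear_sample(ps$power, as.vector(ri), as.vector(ci)),
              nrow = R)
  structure(
    list(theta_grid = theta, g = colSums(f), R = as.integer(R),
         n_angles = n_angles),
    class = "angular_profile")
}

#' @export
print.angular_profile <- function(x, ...) {
  k <- which.max(x$g)
  cat(sprintf(
    "<angular_profile> %d bins, R = %d; peak g = %.4g at %.4f rad (%.1f deg)\n",
    x$n_angles, x$R, x$g[k], x$theta_grid[k], x$theta_grid[k] * 180 / pi))
  invisible(x)
}

#' Angle of maximum summed spectral power
#'
#' Returns the grid angle maximising `g(theta)`. Ties are broken
#' deterministically in favour of the smallest angle index. The peak
#' prominence (peak over median of `g`) is attached as a diagnostic of how
#' strongly oriented the image is.
#'
#' @param profile An [polar_sum()] result.
#' @return List with `theta` (radians, in `[-pi/2, pi/2)`), `index` (1-based
#'   bin) and `prominence` (`g(theta)/median(g)`; `Inf` when the median is
#'   zero but the peak is not).
#' @export
find_peak_angle <- function(profile) {
  stopifnot(inherits(profile, "angular_profile"))
  g <- profile$g
  if (all(g <= 0) || !any(is.finite(g)) || max(g) == 0)
    no_signal_error(
      "no orientation signal: angular power profile is identically zero")
  k <- which.max(g)  # first maximum wins on ties
  med <- stats::median(g)
  list(theta = profile$theta_grid[k], index = k,
       prominence = if (med > 0) g[k] / med else Inf)
}
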