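#' @export
plot.linescan_image <- function(x, main = "line-scan image", ...) {
  graphics::image(
    x = (seq_len(ncol(x$intensity)) - 1) * x$dt_ms,
    y = (seq_len(nrow(x$intensity)) - 1) * x$dx_um,
    z = t(x$intensity), col = grDevices::hcl.colors(64, "Greens 3"),
    xlab = "time (ms)", ylab = "position (um)", main = main,
    useRaster = TRUE, ...)
  invisible(x)
}

#' @export
plot.power_spectrum <- function(x, main = "power spectrum (log)", ...) {
  graphics::image(x = x$f_time, y = x$f_space, z = t(log1p(x$power)),
                  col = grDevices::hcl.colors(64, "Inferno"),
                  xlab = "temporal frequency (cycles/px)",
                  ylab = "spatial frequency (cycles/px)", main = main,
                  useRaster = TRUE, ...)
  invisible(x)
}

#' @export
plot.angular_profile <- function(x, main = "angular power profile", ...) {
  graphics::plot(x$theta_grid * 180 / pi, x$g, type = "l",
                 xlab = "theta (deg from temporal axis)",
                 ylab = "summed power g(theta)", main = main, ...)
  k <- which.max(x$g)
  graphics::points(x$theta_grid[k] * 180 / pi, x$g[k], pch = 25,
                   bg = "red")
  invisible(x)
}

#' @export
plot.appearance_map <- function(x, main = "appearance time (s)", ...) {
  m <- x$t_appear
  m[!x$valid] <- NA
  graphics::image(t(m)[, rev(seq_len(nrow(m)))],
                  col = grDevices::hcl.colors(64, "Spectral"),
                  axes = FALSE, main = main, useRaster = TRUE, ...)
  invisible(x)
}

#' Three-panel summary of a speed estimation
#'
#' Raw image, centered log power spectrum, and the angular power profile
#' with its detected peak.
#'
#' @param img A [linescan_image()].
#' @param est Optional precomputed [estimate_speed()] result.
#' @param ... Passed to the panel plots.
#' @return The `speed_estimate`, invisibly.
#' @export
plot_speed_summary <- function(img, est = NULL, ...) {
  if (is.null(est)) est <- estimate_speed(img)
  old <- graphics::par(mfrow = c(1, 3))
  on.exit(graphics::par(old))
  plot(img, ...)
  plot(compute_power_spectrum(img))
  plot(est$profile,
       main = sprintf("g(theta): %.2f mm/s", est$speed_mm_s))
  invisible(est)
}
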