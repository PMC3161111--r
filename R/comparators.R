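# Comparator streak-angle estimators. Both recover the streak angle in
# image (pixel) space, where a streak of speed v has slope
# m = v * dt / dx rows per column, so v = (dx/dt) * |tan(phi)| with phi
# the streak angle measured from the time axis. The equivalent spectral
# angle is phi -/+ pi/2 wrapped into [-pi/2, pi/2).

#' Radon-transform variance profile of a line-scan image
#'
#' Projects the mean-subtracted image along a grid of directions (by
#' rotating with bilinear interpolation and summing columns) and records
#' the variance of each projection. The variance is maximal when the
#' integration direction is parallel to the RBC streaks.
#'
#' @param img A [linescan_image()].
#' @param n_angles Number of candidate streak angles over
#'   `[-pi/2, pi/2)` (default 180).
#' @return Object of class `radon_profile`: list with `theta_grid`
#'   (candidate streak angles from the time axis, radians) and
#'   `variance_per_angle`.
#' @export
radon_profile <- function(img, n_angles = 180L) {
  stopifnot(inherits(img, "linescan_image"))
  m <- img$intensity - mean(img$intensity)
  theta <- -pi / 2 + (seq_len(n_angles) - 1L) * pi / n_angles
  v <- vapply(theta, function(phi) {
    # align direction phi with the row axis, then integrate over rows
    stats::var(colSums(rotate_matrix(m, pi / 2 - phi)))
  }, numeric(1))
  structure(list(theta_grid = theta, variance_per_angle = v),
            class = "radon_profile")
}

#' Estimate RBC speed by the Radon-transform method
#'
#' Comparator for [estimate_speed()]: picks the projection direction of
#' maximal variance from [radon_profile()] and converts the streak angle
#' to speed through the same sampling geometry as the spectral method.
#' Ties break toward the smallest angle index.
#'
#' @inheritParams radon_profile
#' @return A `speed_estimate` (see [estimate_speed()]); `theta_peak` holds
#'   the equivalent spectral angle, `peak_prominence` the max/median
#'   variance ratio, and `profile` the `radon_profile`.
#' @export
radon_speed <- function(img, n_angles = 180L) {
  prof <- radon_profile(img, n_angles)
  v <- prof$variance_per_angle
  if (all(!is.finite(v)) || max(v, na.rm = TRUE) <= 0)
    no_signal_error("no orientation signal: flat projection variance")
  k <- which.max(v)
  phi <- prof$theta_grid[k]
  speed <- (img$dx_um / img$dt_ms) * abs(tan(phi))
  med <- stats::median(v)
  structure(
    list(speed_mm_s = speed, theta_peak = wrap_half_circle(phi - pi / 2),
         theta_image = phi,
         flow_sign = if (phi == 0) 0L else if (phi > 0) 1L else -1L,
         peak_prominence = if (med > 0) v[k] / med else Inf,
         window_pixels = ncol(img$intensity), method = "radon",
         profile = prof),
    class = "speed_estimate")
}

#' Estimate RBC speed by the rotation/SVD method
#'
#' Comparator for [estimate_speed()]: rotates the mean-subtracted image
#' over a grid of candidate streak angles and computes the singular value
#' spectrum of each rotation. When the streaks are axis-aligned the image
#' is nearly separable (rank one), so the fraction of energy in the
#' leading singular value — the separability `sigma_1 / sum(sigma)` — is
#' maximal. The winning angle is converted to speed as in
#' [radon_speed()].
#'
#' @inheritParams radon_profile
#' @return A `speed_estimate` with `separability` attached; `profile` is a
#'   list with `theta_grid` and `separability_per_angle`.
#' @export
svd_speed <- function(img, n_angles = 180L) {
  stopifnot(inherits(img, "linescan_image"))
  m <- img$intensity - mean(img$intensity)
  if (max(abs(m)) == 0)
    no_signal_error("no orientation signal: constant image")
  theta <- -pi / 2 + (seq_len(n_angles) - 1L) * pi / n_angles
  sep <- vapply(theta, function(phi) {
    d <- svd(rotate_matrix(m, pi / 2 - phi), nu = 0, nv = 0)$d
    if (sum(d) == 0) 0 else d[1] / sum(d)
  }, numeric(1))
  if (max(sep) <= 0)
    no_signal_error("no orientation signal: zero singular values")
  k <- which.max(sep)
  phi <- theta[k]
  # separability is invariant under quarter-turn rotations (a separable
  # image stays separable rotated by 90 degrees), so the winning angle is
  # ambiguous between phi and phi +- pi/2; disambiguate by projection
  # variance, maximal when the integration axis runs along the streaks
  phi2 <- wrap_half_circle(phi + pi / 2)
  pvar <- function(p) stats::var(colSums(rotate_matrix(m, pi / 2 - p)))
  if (pvar(phi2) > pvar(phi)) phi <- phi2
  speed <- (img$dx_um / img$dt_ms) * abs(tan(phi))
  structure(
    list(speed_mm_s = speed, theta_peak = wrap_half_circle(phi - pi / 2),
         theta_image = phi,
         flow_sign = if (phi == 0) 0L else if (phi > 0) 1L else -1L,
         peak_prominence = sep[k] / stats::median(sep),
         separability = sep[k],
         window_pixels = ncol(img$intensity), method = "svd",
         profile = list(theta_grid = theta, separability_per_angle = sep)),
    class = "speed_estimate")
}
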