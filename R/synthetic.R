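#' Parameters for a synthetic line-scan streak scene
#'
#' Describes a kymograph of a single capillary: a bright plasma background
#' crossed by dark RBC streaks of known slope. Defaults emulate a
#' representative capillary acquisition: 512 x 512 pixels at
#' 0.20 um/pixel and 1 ms/pixel, RBC dark streaks of 4 um width (about the
#' size of a rat RBC; target vessels are capillaries under 6 um), a linear
#' RBC density of 80 cells/mm, a 50% intensity dip per streak and 5%
#' additive Gaussian noise.
#'
#' @param speed_mm_s True RBC speed (>= 0), mm/s.
#' @param dx_um,dt_ms Sampling intervals (um/pixel, ms/pixel).
#' @param n_space,n_time Image dimensions in pixels.
#' @param streak_width_um Full width at half maximum of the Gaussian streak
#'   cross-profile, um.
#' @param linear_density_per_mm Expected RBC count per mm of vessel.
#' @param contrast Fractional intensity dip of a streak, in `(0, 1]`.
#' @param noise_sd Additive Gaussian noise SD relative to the unit
#'   background.
#' @param nonvascular_fraction Fraction of spatial rows (taken from the
#'   bottom of the image) replaced by uncorrelated non-vascular noise;
#'   0 means a fully cropped vessel.
#' @param nonvascular_noise_sd Noise SD of the non-vascular rows.
#' @param nonvascular_dim Brightness deficit of the non-vascular rows
#'   relative to the vessel-band mean (tissue autofluorescence is
#'   slightly dimmer than the labelled plasma); default 0.08 of the unit
#'   background.
#' @param shot_noise Logical; also apply Poisson (photon-counting) noise.
#' @param photons_per_unit Poisson scaling when `shot_noise = TRUE`.
#' @param streak_x0_um Optional fixed streak intercepts (um, position of
#'   each streak at time zero); overrides the Poisson draw. Useful for
#'   scenes with a known, small number of streaks.
#' @param seed RNG seed; identical parameters and seed give bit-identical
#'   scenes.
#' @return A list of class `streak_scene` for [make_linescan()].
#' @export
streak_scene <- function(speed_mm_s = 1.0, dx_um = 0.20, dt_ms = 1.0,
                         n_space = 512L, n_time = 512L,
                         streak_width_um = 4, linear_density_per_mm = 80,
                         contrast = 0.5, noise_sd = 0.05,
                         nonvascular_fraction = 0,
                         nonvascular_noise_sd = 0.3,
                         nonvascular_dim = 0.08,
                         shot_noise = FALSE, photons_per_unit = 100,
                         streak_x0_um = NULL, seed = 1L) {
  if (speed_mm_s < 0) stop("`speed_mm_s` must be >= 0")
  if (contrast <= 0 || contrast > 1) stop("`contrast` must be in (0, 1]")
  if (nonvascular_fraction < 0 || nonvascular_fraction >= 1)
    stop("`nonvascular_fraction` must be in [0, 1)")
  if (dx_um <= 0 || dt_ms <= 0) stop("sampling intervals must be positive")
  structure(as.list(environment()), class = "streak_scene")
}

#' Generate a synthetic line-scan image with known streak slope
#'
#' Streaks follow lines `x = x0 + v t` in physical units, i.e. pixel-space
#' lines of slope `m = v dt / dx` rows per column, with a Gaussian
#' cross-profile. Streak intercepts are drawn as a Poisson process at the
#' given linear density over a range wide enough that streaks entering or
#' leaving the window are included (and clipped at the window edges, as in
#' a real acquisition). Optionally the bottom rows are replaced with
#' uncorrelated noise, emulating an uncropped field of view containing
#' non-vascular tissue.
#'
#' @param params A [streak_scene()].
#' @return List with `image` (a [linescan_image()]) and `truth`, a list
#'   holding the exact streak geometry: `slope_px_per_px` (m),
#'   `theta_image` (streak angle from the time axis in image space),
#'   `theta_spectral` (expected spectral peak angle in `[-pi/2, pi/2)`;
#'   feeding it to [speed_from_angle()] returns `speed_mm_s` exactly),
#'   `speed_mm_s`, `n_streaks`, and `vessel_rows`.
#' @export
make_linescan <- function(params) {
  stopifnot(inherits(params, "streak_scene"))
  p <- params
  set.seed(p$seed)
  m_slope <- p$speed_mm_s * p$dt_ms / p$dx_um   # rows per column
  n_vessel <- as.integer(round(p$n_space * (1 - p$nonvascular_fraction)))
  if (n_vessel < 8L) stop("vessel band thinner than 8 rows")
  if (p$speed_mm_s > 0 && m_slope * (p$n_time - 1) < 1)
    warning(paste("total streak displacement below one pixel:",
                  "angle indistinguishable from stationary streaks"))

  sigma_px <- (p$streak_width_um / p$dx_um) / (2 * sqrt(2 * log(2)))
  pad <- 3 * sigma_px
  # intercept range such that any streak intersecting the window is kept
  lo <- -m_slope * (p$n_time - 1) - pad
  hi <- (n_vessel - 1) + pad
  if (!is.null(p$streak_x0_um)) {
    i0 <- p$streak_x0_um / p$dx_um
  } else {
    mean_count <- p$linear_density_per_mm * (hi - lo) * p$dx_um / 1000
    n_streaks <- stats::rpois(1L, mean_count)
    i0 <- stats::runif(n_streaks, lo, hi)
  }
  jj <- 0:(p$n_time - 1)
  rows <- 0:(n_vessel - 1)
  dip <- matrix(0, n_vessel, p$n_time)
  for (k in seq_along(i0)) {
    ik <- i0[k] + m_slope * jj                     # streak center per column
    keep <- ik > -pad & ik < n_vessel - 1 + pad
    if (!any(keep)) next
    d <- outer(rows, ik[keep], "-")
    dip[, keep] <- dip[, keep] + exp(-d^2 / (2 * sigma_px^2))
  }
  vessel <- 1 - p$contrast * pmin(dip, 1)
  img <- matrix(1, p$n_space, p$n_time)
  img[seq_len(n_vessel), ] <- vessel
  if (n_vessel < p$n_space) {
    # non-vascular tissue: uncorrelated noise around a brightness close
    # to (slightly below) the vessel-band mean, emulating unlabelled
    # tissue autofluorescence
    n_nv <- p$n_space - n_vessel
    img[(n_vessel + 1L):p$n_space, ] <-
      mean(vessel) - p$nonvascular_dim +
      stats::rnorm(n_nv * p$n_time, sd = p$nonvascular_noise_sd)
  }
  if (p$noise_sd > 0)
    img <- img + stats::rnorm(length(img), sd = p$noise_sd)
  if (isTRUE(p$shot_noise)) {
    lam <- pmax(img, 0) * p$photons_per_unit
    img <- matrix(stats::rpois(length(lam), lam) / p$photons_per_unit,
                  nrow(img), ncol(img))
  }
  img <- pmax(img, 0)
  truth <- list(
    slope_px_per_px = m_slope,
    theta_image = atan(m_slope),
    theta_spectral = if (m_slope == 0) -pi / 2 else atan(-1 / m_slope),
    speed_mm_s = p$speed_mm_s,
    n_streaks = length(i0),
    vessel_rows = n_vessel)
  list(image = linescan_image(img, p$dx_um, p$dt_ms), truth = truth)
}

#' Parameters for a synthetic bolus time-lapse scene
#'
#' Describes a field of view containing disjoint arterial and venous
#' vessel segments imaged while a fluorescent dye bolus washes in. Each
#' vessel pixel is assigned a dye-arrival time drawn from its segment's
#' truncated normal distribution (truncated at zero); non-vessel pixels
#' stay at baseline. Defaults match a representative cortical-surface
#' acquisition: 14.2 frames/s with arterial arrivals of 0.29 +/- 0.28 s
#' and venous arrivals of 1.43 +/- 0.48 s.
#'
#' When masks are not supplied, a default geometry is used: the arterial
#' segment is a vertical band covering the left quarter of the image and
#' the venous segment a band covering the right 40%, mimicking the roughly
#' 1:2 arterial:venous area ratio seen on the cortical surface.
#'
#' @param frame_rate_hz Frame rate (frames/s).
#' @param n_frames,height,width Stack dimensions.
#' @param baseline_frames Pre-injection frames (>= 5).
#' @param arterial_mask,venous_mask Logical matrices `height x width`,
#'   disjoint; `NULL` for the default bands.
#' @param arterial_arrival_mean_s,arterial_arrival_sd_s Arterial arrival
#'   distribution (s), truncated at 0.
#' @param venous_arrival_mean_s,venous_arrival_sd_s Venous arrival
#'   distribution (s), truncated at 0.
#' @param rise_time_s Dye wash-in time constant (s); 0 gives a step.
#' @param baseline_level,amplitude Baseline intensity and full wash-in
#'   amplitude (arbitrary units).
#' @param noise_sd Additive Gaussian noise SD (same units).
#' @param seed RNG seed.
#' @return A list of class `bolus_scene` for [make_bolus_stack()].
#' @export
bolus_scene <- function(frame_rate_hz = 14.2, n_frames = 70L,
                        height = 96L, width = 96L, baseline_frames = 10L,
                        arterial_mask = NULL, venous_mask = NULL,
                        arterial_arrival_mean_s = 0.29,
                        arterial_arrival_sd_s = 0.28,
                        venous_arrival_mean_s = 1.43,
                        venous_arrival_sd_s = 0.48,
                        rise_time_s = 0.1, baseline_level = 100,
                        amplitude = 100, noise_sd = 2, seed = 1L) {
  if (frame_rate_hz <= 0) stop("`frame_rate_hz` must be positive")
  if (baseline_frames < 5L) stop("`baseline_frames` must be >= 5")
  if (baseline_frames >= n_frames)
    stop("`baseline_frames` must be below `n_frames`")
  if (is.null(arterial_mask))
    arterial_mask <- matrix(rep(seq_len(width) <= round(width * 0.25),
                                each = height), height, width)
  if (is.null(venous_mask))
    venous_mask <- matrix(rep(seq_len(width) > round(width * 0.60),
                              each = height), height, width)
  arterial_mask <- arterial_mask > 0   # accept 0/1 matrices
  venous_mask <- venous_mask > 0
  stopifnot(identical(dim(arterial_mask), dim(venous_mask)),
            identical(dim(arterial_mask), c(as.integer(height),
                                            as.integer(width))))
  if (any(arterial_mask & venous_mask))
    stop("arterial and venous masks must be disjoint")
  structure(as.list(environment()), class = "bolus_scene")
}

# Exact truncated-normal sampler (lower bound 0) by inverse-CDF.
rtrunc_norm0 <- function(n, mean, sd) {
  u <- stats::runif(n, stats::pnorm(0, mean, sd), 1)
  stats::qnorm(u, mean, sd)
}

#' Generate a synthetic bolus time-lapse stack with known arrival times
#'
#' Vessel pixels follow a sharp-onset saturating-exponential wash-in:
#' intensity is `baseline` before the pixel's arrival time `t_a` and
#' `baseline + amplitude * (1 - exp(-(t - t_a)/rise_time))` after it
#' (a step when `rise_time_s = 0`), plus Gaussian noise. Arrival times are
#' measured relative to the first post-baseline frame. Non-vessel pixels
#' stay at baseline + noise and should never cross the detection
#' threshold.
#'
#' @param params A [bolus_scene()].
#' @return List with `stack` (a [timelapse_stack()]) and `truth`: a list
#'   with `t_arrival` (matrix of seconds, `NA` off-vessel), `reachable`
#'   (logical matrix: arrival early enough to be detectable with the
#'   default persistence rule before the stack ends), and the masks.
#' @export
make_bolus_stack <- function(params) {
  stopifnot(inherits(params, "bolus_scene"))
  p <- params
  set.seed(p$seed)
  H <- as.integer(p$height); W <- as.integer(p$width)
  FR <- as.integer(p$n_frames); B <- as.integer(p$baseline_frames)
  dt <- 1 / p$frame_rate_hz
  t_arr <- matrix(NA_real_, H, W)
  t_arr[p$arterial_mask] <- rtrunc_norm0(sum(p$arterial_mask),
                                         p$arterial_arrival_mean_s,
                                         p$arterial_arrival_sd_s)
  t_arr[p$venous_mask] <- rtrunc_norm0(sum(p$venous_mask),
                                       p$venous_arrival_mean_s,
                                       p$venous_arrival_sd_s)
  rel_t <- ((B + 1):FR - B - 1) * dt     # time of each post-baseline frame
  frames <- array(p$baseline_level, dim = c(H, W, FR))
  vessel <- !is.na(t_arr)
  ta <- t_arr[vessel]
  for (f in seq_along(rel_t)) {
    el <- rel_t[f] - ta
    wash <- if (p$rise_time_s > 0) {
      ifelse(el >= 0, 1 - exp(-el / p$rise_time_s), 0)
    } else as.numeric(el >= 0)
    fr <- frames[, , B + f]
    fr[vessel] <- p$baseline_level + p$amplitude * wash
    frames[, , B + f] <- fr
  }
  if (p$noise_sd > 0)
    frames <- frames + stats::rnorm(length(frames), sd = p$noise_sd)
  duration_post <- (FR - B - 1) * dt
  truth <- list(
    t_arrival = t_arr,
    reachable = vessel & !is.na(t_arr) &
      (t_arr <= duration_post - 6 * dt),   # room for the 6-frame run
    arterial_mask = p$arterial_mask,
    venous_mask = p$venous_mask)
  stack <- timelapse_stack(frames, frame_interval_s = dt,
                           baseline_frames = B)
  list(stack = stack, truth = truth)
}
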