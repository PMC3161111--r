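test_that("noise-free streaks are recovered within angular quantization", {
  cases <- list(c(speed = 1.0, dt = 1.0), c(speed = 0.4, dt = 1.0),
                c(speed = 2.2, dt = 0.5))
  for (cs in cases) {
    sc <- streak_scene(speed_mm_s = cs[["speed"]], dx_um = 0.2,
                       dt_ms = cs[["dt"]], n_space = 256, n_time = 256,
                       noise_sd = 0, seed = 2)
    sim <- make_linescan(sc)
    est <- estimate_speed(sim$image)
    expect_lt(abs(est$theta_index - sim$truth$theta_spectral), pi / 180)
    expect_lt(abs(est$speed_mm_s - cs[["speed"]]) / cs[["speed"]], 0.05)
  }
})

test_that("stationary streaks give zero speed via the spatial-axis peak", {
  sim <- make_linescan(clean_scene(speed = 0, n = 128))
  est <- estimate_speed(sim$image)
  expect_equal(est$speed_mm_s, 0)
  expect_equal(abs(est$theta_index), pi / 2)
  expect_equal(est$flow_sign, 0L)
})

test_that("the estimate is invariant under affine intensity maps", {
  sim <- make_linescan(clean_scene(n = 64, seed = 9))
  e1 <- estimate_speed(sim$image)
  scaled <- linescan_image(3.7 * sim$image$intensity + 11, 0.2, 1)
  e2 <- estimate_speed(scaled)
  expect_identical(e2$theta_index, e1$theta_index)
  expect_identical(e2$speed_mm_s, e1$speed_mm_s)
})

test_that("transposed images give reciprocal-consistent estimates", {
  # swapping the axes and the sampling intervals turns slope m into 1/m
  # and theta into pi/2 - theta, so the estimated speeds (in um/ms)
  # multiply to 1: v * v_transposed = (dx/dt m)(dt/dx 1/m)
  sim <- make_linescan(clean_scene(speed = 0.2, n = 128, seed = 3))
  e1 <- estimate_speed(sim$image)
  e2 <- estimate_speed(t(sim$image))
  expect_lt(abs(e1$speed_mm_s * e2$speed_mm_s - 1), 0.05)
})

test_that("non-square windows use physical frequency units (aspect correction)", {
  sc <- streak_scene(speed_mm_s = 1.0, dx_um = 0.2, dt_ms = 1,
                     n_space = 128, n_time = 64, noise_sd = 0, seed = 5)
  sim <- make_linescan(sc)
  est <- estimate_speed(sim$image)
  expect_lt(abs(est$speed_mm_s - 1.0), 0.12)
})

test_that("sliding windows return one estimate per window", {
  sc <- streak_scene(speed_mm_s = 1.0, n_space = 64, n_time = 256,
                     noise_sd = 0.02, seed = 6)
  sim <- make_linescan(sc)
  win <- estimate_speed(sim$image, window_pixels = 64)
  expect_s3_class(win, "data.frame")
  expect_equal(nrow(win), 4L)
  expect_equal(win$window_start, c(1L, 65L, 129L, 193L))
  expect_true(all(abs(win$speed_mm_s - 1.0) < 0.15))
  # stride control
  win2 <- estimate_speed(sim$image, window_pixels = 64, stride_pixels = 32)
  expect_equal(nrow(win2), 7L)
})

test_that("short temporal windows warn below 32 pixels and fail below 8", {
  sc <- streak_scene(speed_mm_s = 1.0, n_space = 64, n_time = 64,
                     noise_sd = 0, seed = 7)
  sim <- make_linescan(sc)
  expect_warning(estimate_speed(sim$image, window_pixels = 16),
                 "shorter than\\s+32")
  expect_error(estimate_speed(sim$image, window_pixels = 4), "minimum is 8")
})

test_that("a constant image raises a no-orientation-signal error", {
  img <- linescan_image(matrix(5, 64, 64), 0.2, 1)
  expect_no_signal(estimate_speed(img))
})

test_that("all-pass bandpass is the identity and stop-bands remove tones", {
  sim <- make_linescan(clean_scene(n = 64, seed = 8))
  out <- bandpass_filter(sim$image, 0, sqrt(0.5))
  expect_equal(out$intensity, sim$image$intensity, tolerance = 1e-9)
  # a pure low-frequency sinusoid is annihilated by a high-pass band
  n <- 64
  tone <- matrix(sin(2 * pi * 2 * (0:(n - 1)) / n), n, n)
  filt <- bandpass_filter(linescan_image(tone + 2, 1, 1), 0.2, sqrt(0.5))
  expect_lt(max(abs(filt$intensity)), 1e-9)
  expect_error(bandpass_filter(sim$image, 0.3, 0.2), "r_lo < r_hi")
})

test_that("bandpass filtering rescues estimation from low-frequency background", {
  sim <- make_linescan(clean_scene(speed = 1.0, n = 128, seed = 10))
  n <- 128
  # strong static spatial profile: energy on the spatial-frequency axis
  bg <- matrix(0.8 * sin(2 * pi * 3 * (0:(n - 1)) / n), n, n)
  corrupted <- linescan_image(sim$image$intensity + bg, 0.2, 1)
  est_raw <- estimate_speed(corrupted)
  expect_gt(abs(est_raw$speed_mm_s - 1.0), 0.5)       # peak hijacked
  cleaned <- bandpass_filter(corrupted, 0.05, sqrt(0.5))
  est_bp <- estimate_speed(cleaned)
  expect_lt(abs(est_bp$speed_mm_s - 1.0), 0.1)
})
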