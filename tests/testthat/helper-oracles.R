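# Independent oracles and shared fixtures for the test suite.

# Direct evaluation of the 2D DFT power by the O(N^4) definition sum;
# returns the centered power matrix. Only for tiny instances.
direct_dft_power <- function(m) {
  m <- m - mean(m)
  nr <- nrow(m); nc <- ncol(m)
  p <- matrix(0, nr, nc)
  for (kr in 0:(nr - 1)) for (kc in 0:(nc - 1)) {
    s <- 0
    for (ir in 0:(nr - 1)) for (ic in 0:(nc - 1))
      s <- s + m[ir + 1, ic + 1] *
        exp(-2i * pi * (kr * ir / nr + kc * ic / nc))
    p[kr + 1, kc + 1] <- Mod(s)^2
  }
  # shift zero frequency to (floor(nr/2)+1, floor(nc/2)+1)
  ri <- c((ceiling(nr / 2) + 1):nr, 1:ceiling(nr / 2))
  ci <- c((ceiling(nc / 2) + 1):nc, 1:ceiling(nc / 2))
  p[ri, ci]
}

# Least-squares fit of the streak-centroid displacement per scan line:
# independent slope oracle for a single-streak image. Uses the intensity
# dip (background minus intensity) as centroid weight, keeping only
# columns where the streak is fully inside the window (edge-clipped
# columns bias the centroid toward the image center).
centroid_slope_speed <- function(img, bg = 1) {
  m <- img$intensity
  n <- nrow(m)
  w <- pmax(bg - m, 0)
  tot <- colSums(w)
  cent <- colSums(w * seq_len(n)) / tot
  use <- tot > 0.9 * max(tot) & cent > n / 4 & cent < 3 * n / 4
  j <- seq_len(ncol(m))
  fit <- stats::lm(cent[use] ~ j[use])
  slope <- abs(stats::coef(fit)[2])           # rows per column
  unname(slope * img$dx_um / img$dt_ms)       # mm/s
}

# Small clean streak scene used across tests.
clean_scene <- function(speed = 1.0, n = 128L, seed = 1L, ...) {
  streak_scene(speed_mm_s = speed, dx_um = 0.2, dt_ms = 1.0,
               n_space = n, n_time = n, contrast = 0.5, noise_sd = 0,
               seed = seed, ...)
}

# Wrap an angle difference into [-pi/2, pi/2) (angles modulo pi).
wrap_angle <- function(theta) (theta + pi / 2) %% pi - pi / 2

expect_no_signal <- function(expr) {
  testthat::expect_error(expr, class = "microvel_no_signal")
}
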