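# Internal numeric helpers shared by the spectral and comparator paths.

# Reorder a matrix so the zero-frequency bin of fft() output sits at
# (floor(nr/2)+1, floor(nc/2)+1).
fftshift2 <- function(m) {
  nr <- nrow(m); nc <- ncol(m)
  ri <- c((ceiling(nr / 2) + 1L):nr, 1L:ceiling(nr / 2))
  ci <- c((ceiling(nc / 2) + 1L):nc, 1L:ceiling(nc / 2))
  m[ri, ci, drop = FALSE]
}

# Centered frequency coordinates (cycles/pixel) matching fftshift2.
freq_axis <- function(n) (seq_len(n) - 1L - floor(n / 2)) / n

# Vectorised bilinear sampling of matrix `m` at fractional (row, col)
# positions; points outside the array contribute exactly 0.
bilinear_sample <- function(m, ri, ci) {
  nr <- nrow(m); nc <- ncol(m)
  out <- numeric(length(ri))
  ok <- ri >= 1 & ri <= nr & ci >= 1 & ci <= nc
  if (!any(ok)) return(out)
  r <- ri[ok]; c <- ci[ok]
  r0 <- pmin(floor(r), nr - 1L); c0 <- pmin(floor(c), nc - 1L)
  fr <- r - r0; fc <- c - c0
  v <- (1 - fr) * (1 - fc) * m[cbind(r0, c0)] +
    fr * (1 - fc) * m[cbind(r0 + 1L, c0)] +
    (1 - fr) * fc * m[cbind(r0, c0 + 1L)] +
    fr * fc * m[cbind(r0 + 1L, c0 + 1L)]
  out[ok] <- v
  out
}

# Rotate a matrix about its center by `alpha` radians (row/col coordinate
# rotation, bilinear interpolation, zero fill). Output has the same shape.
rotate_matrix <- function(m, alpha) {
  nr <- nrow(m); nc <- ncol(m)
  cr <- (nr + 1) / 2; cc <- (nc + 1) / 2
  dr <- rep(seq_len(nr) - cr, times = nc)
  dc <- rep(seq_len(nc) - cc, each = nr)
  ca <- cos(alpha); sa <- sin(alpha)
  src_r <- cr + ca * dr - sa * dc
  src_c <- cc + sa * dr + ca * dc
  matrix(bilinear_sample(m, src_r, src_c), nr, nc)
}

# Wrap an angle into [-pi/2, pi/2) modulo pi.
wrap_half_circle <- function(theta) {
  th <- (theta + pi / 2) %% pi - pi / 2
  th[th >= pi / 2] <- th[th >= pi / 2] - pi
  th
}

no_signal_error <- function(msg) {
  stop(errorCondition(msg,
                      class = c("microvel_no_signal", "error", "condition")))
}
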