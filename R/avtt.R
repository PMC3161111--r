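#' Bolus time-lapse stack
#'
#' A sequence of frames acquired while a fluorescent dye bolus passes
#' through the cortical vasculature. Stored as a 3D array indexed
#' `(row, column, frame)`; the first `baseline_frames` frames are the
#' pre-injection baseline used to set per-pixel detection thresholds.
#'
#' @param frames Numeric 3D array `(row, col, frame)` of non-negative
#'   intensities.
#' @param frame_interval_s Seconds per frame (> 0). Alternatively supply
#'   `frame_rate_hz`.
#' @param baseline_frames Number of pre-injection frames (>= 2, < total).
#' @param frame_rate_hz Optional frame rate; used when
#'   `frame_interval_s` is missing.
#' @return Object of class `timelapse_stack`.
#' @export
timelapse_stack <- function(frames, frame_interval_s = NULL,
                            baseline_frames, frame_rate_hz = NULL) {
  if (is.null(frame_interval_s)) {
    if (is.null(frame_rate_hz))
      stop("supply `frame_interval_s` or `frame_rate_hz`")
    frame_interval_s <- 1 / frame_rate_hz
  }
  if (!is.array(frames) || length(dim(frames)) != 3L)
    stop("`frames` must be a 3D array (row, col, frame)")
  if (any(!is.finite(frames))) stop("non-finite intensity in stack")
  if (frame_interval_s <= 0) stop("`frame_interval_s` must be positive")
  nf <- dim(frames)[3]
  baseline_frames <- as.integer(baseline_frames)
  if (baseline_frames < 2L || baseline_frames >= nf)
    stop(sprintf(
      "`baseline_frames` must be in [2, %d) for a %d-frame stack",
      nf, nf))
  structure(
    list(frames = frames, frame_interval_s = frame_interval_s,
         baseline_frames = baseline_frames),
    class = "timelapse_stack")
}

#' @export
print.timelapse_stack <- function(x, ...) {
  d <- dim(x$frames)
  cat(sprintf(
    "<timelapse_stack> %d x %d px, %d frames (%.3g s/frame, %d baseline)\n",
    d[1], d[2], d[3], x$frame_interval_s, x$baseline_frames))
  invisible(x)
}

#' Median-filter a time-lapse stack frame by frame
#'
#' Applies a 2D spatial median filter of the given (odd) kernel width to
#' every frame, suppressing photomultiplier shot noise before the
#' appearance-time thresholding. `kernel = 1` is the identity. Filtering is
#' spatial only; no temporal smoothing is applied.
#'
#' @param stack A [timelapse_stack()].
#' @param kernel Odd kernel width in pixels (default 3, i.e. 3 x 3).
#' @return A filtered `timelapse_stack` with identical metadata.
#' @export
denoise_stack <- function(stack, kernel = 3L) {
  stopifnot(inherits(stack, "timelapse_stack"))
  kernel <- as.integer(kernel)
  if (kernel < 1L || kernel %% 2L == 0L)
    stop(sprintf("`kernel` must be an odd positive width, got %d", kernel))
  if (kernel == 1L) return(stack)
  out <- stack$frames
  rng <- range(out)
  scale <- if (diff(rng) > 0) diff(rng) else 1
  for (f in seq_len(dim(out)[3])) {
    # EBImage's constant-time median works on [0, 1]; the rescale is
    # monotone, so it commutes with the median exactly
    fr <- (out[, , f] - rng[1]) / scale
    out[, , f] <- EBImage::medianFilter(fr, (kernel - 1L) %/% 2L) *
      scale + rng[1]
  }
  timelapse_stack(out, frame_interval_s = stack$frame_interval_s,
                  baseline_frames = stack$baseline_frames)
}

#' Per-pixel baseline mean and SD over the pre-injection frames
#'
#' @param stack A [timelapse_stack()].
#' @return List with matrices `mean` and `sd` (sample SD, `n - 1`
#'   denominator) over frames `1..baseline_frames`.
#' @export
baseline_stats <- function(stack) {
  stopifnot(inherits(stack, "timelapse_stack"))
  d <- dim(stack$frames)
  B <- stack$baseline_frames
  m <- matrix(stack$frames[, , seq_len(B)], nrow = d[1] * d[2], ncol = B)
  mu <- rowMeans(m)
  s2 <- rowSums((m - mu)^2) / (B - 1)
  list(mean = matrix(mu, d[1], d[2]), sd = matrix(sqrt(s2), d[1], d[2]))
}

#' Per-pixel dye appearance time
#'
#' A pixel's appearance frame is the earliest post-baseline frame at which
#' its intensity and the `persistence` subsequent frames all strictly
#' exceed the pixel threshold `baseline mean + k_sd * baseline SD` (a run
#' of `persistence + 1` consecutive frames). Runs that would extend past
#' the last frame do not qualify. Pixels with no qualifying frame are
#' excluded (marked invalid). Appearance time is reported in seconds
#' relative to the first post-baseline frame.
#'
#' @param stack A [timelapse_stack()] (typically after [denoise_stack()]).
#' @param baseline A [baseline_stats()] result; computed from `stack` when
#'   omitted.
#' @param k_sd Threshold multiplier (default 2: mean + 2 SD).
#' @param persistence Number of subsequent frames that must also exceed
#'   the threshold (default 5).
#' @return Object of class `appearance_map`: list with `t_appear` (matrix
#'   of seconds, `NA` where invalid), `valid` (logical matrix),
#'   `frame_interval_s` and `duration_s` (post-baseline duration).
#' @export
appearance_time <- function(stack, baseline = NULL, k_sd = 2,
                            persistence = 5L) {
  stopifnot(inherits(stack, "timelapse_stack"))
  if (is.null(baseline)) baseline <- baseline_stats(stack)
  persistence <- as.integer(persistence)
  if (persistence < 0L) stop("`persistence` must be >= 0")
  d <- dim(stack$frames)
  B <- stack$baseline_frames
  n_post <- d[3] - B
  if (persistence >= n_post)
    stop(sprintf(
      "`persistence` = %d needs more than the %d post-baseline frames",
      persistence, n_post))
  thr <- as.vector(baseline$mean + k_sd * baseline$sd)
  post <- matrix(stack$frames[, , (B + 1):d[3]], nrow = d[1] * d[2],
                 ncol = n_post)
  above <- post > thr                      # thr recycles down columns
  n_starts <- n_post - persistence
  run <- above[, seq_len(n_starts), drop = FALSE]
  if (persistence > 0L)
    for (k in seq_len(persistence))
      run <- run & above[, k + seq_len(n_starts), drop = FALSE]
  any_run <- rowSums(run) > 0
  first <- max.col(run, ties.method = "first")  # first TRUE where any
  t_ap <- ifelse(any_run, (first - 1) * stack$frame_interval_s, NA_real_)
  structure(
    list(t_appear = matrix(t_ap, d[1], d[2]),
         valid = matrix(any_run, d[1], d[2]),
         frame_interval_s = stack$frame_interval_s,
         duration_s = (n_post - 1) * stack$frame_interval_s),
    class = "appearance_map")
}

#' @export
print.appearance_map <- function(x, ...) {
  cat(sprintf(
    "<appearance_map> %d x %d px, %d valid (%.1f%%), t in [%.3g, %.3g] s\n",
    nrow(x$t_appear), ncol(x$t_appear), sum(x$valid),
    100 * mean(x$valid),
    if (any(x$valid)) min(x$t_appear, na.rm = TRUE) else NA,
    if (any(x$valid)) max(x$t_appear, na.rm = TRUE) else NA))
  invisible(x)
}

#' Appearance-time statistics of a vascular segment
#'
#' @param map An [appearance_time()] result.
#' @param mask Logical matrix (same shape) selecting the segment.
#' @param label Segment label, e.g. `"arterial"` or `"venous"`.
#' @return Object of class `segment_stats`: list with `label`,
#'   `pixel_count` (valid in-mask pixels), `area_fraction` (valid in-mask
#'   pixels over total image pixels), `mean_s`, `sd_s`, `median_s`.
#' @export
segment_stats <- function(map, mask, label = "segment") {
  stopifnot(inherits(map, "appearance_map"))
  mask <- as.logical(mask)
  if (length(mask) != length(map$t_appear))
    stop("`mask` shape does not match the appearance map")
  sel <- mask & as.vector(map$valid)
  if (!any(sel))
    stop(errorCondition(
      sprintf("empty segment: no valid pixels in mask '%s'", label),
      class = c("microvel_empty_segment", "error", "condition")))
  v <- map$t_appear[sel]
  structure(
    list(label = label, pixel_count = sum(sel),
         area_fraction = sum(sel) / length(mask),
         mean_s = mean(v), sd_s = stats::sd(v),
         median_s = stats::median(v)),
    class = "segment_stats")
}

#' @export
print.segment_stats <- function(x, ...) {
  cat(sprintf(
    "<segment_stats> %s: %d px (%.0f%% of image), %.3g +/- %.3g s (median %.3g)\n",
    x$label, x$pixel_count, 100 * x$area_fraction, x$mean_s, x$sd_s,
    x$median_s))
  invisible(x)
}

#' Arteriovenous transit time from segment statistics
#'
#' AVTT is the venous minus the arterial appearance time, computed on both
#' segment means and segment medians. Negative values are allowed but
#' flagged with a warning since they are physiologically unexpected.
#'
#' @param arterial,venous [segment_stats()] for the two segments.
#' @return Object of class `avtt_result`: list with `avtt_mean_s`,
#'   `avtt_median_s`, `arterial`, `venous`.
#' @examples
#' a <- structure(list(label = "arterial", pixel_count = 100L,
#'                     area_fraction = 0.1, mean_s = 0.29, sd_s = 0.28,
#'                     median_s = 0.21), class = "segment_stats")
#' v <- structure(list(label = "venous", pixel_count = 100L,
#'                     area_fraction = 0.2, mean_s = 1.43, sd_s = 0.48,
#'                     median_s = 1.33), class = "segment_stats")
#' compute_avtt(a, v)$avtt_mean_s   # 1.14
#' @export
compute_avtt <- function(arterial, venous) {
  stopifnot(inherits(arterial, "segment_stats"),
            inherits(venous, "segment_stats"))
  if (arterial$pixel_count < 1L || venous$pixel_count < 1L)
    stop("both segments must be non-empty")
  res <- structure(
    list(avtt_mean_s = venous$mean_s - arterial$mean_s,
         avtt_median_s = venous$median_s - arterial$median_s,
         arterial = arterial, venous = venous),
    class = "avtt_result")
  if (res$avtt_mean_s < 0)
    warning("negative AVTT (venous dye arrival before arterial) is physiologically unexpected")
  res
}

#' @export
print.avtt_result <- function(x, ...) {
  cat(sprintf("<avtt_result> AVTT = %.3g s (mean), %.3g s (median)\n",
              x$avtt_mean_s, x$avtt_median_s))
  print(x$arterial); print(x$venous)
  invisible(x)
}

#' Region-growing segmentation assistant over an appearance-time map
#'
#' Vessel segments are normally traced manually from the spatial
#' continuity of appearance times along vessels; this optional helper
#' automates that: starting from labelled seed pixels it grows 4-connected
#' regions over valid pixels, admitting a neighbour when its appearance
#' time differs from the region's running mean by at most `tolerance_s`.
#' Seeds are processed in order; a pixel claimed by an earlier-seeded
#' region is never re-claimed.
#'
#' @param map An [appearance_time()] result.
#' @param seeds Data frame with columns `row`, `col`, `label` (at least
#'   one seed per label).
#' @param tolerance_s Maximum allowed deviation from the region's running
#'   mean appearance time, seconds.
#' @return Named list of disjoint logical masks, one per label.
#' @export
segment_assist <- function(map, seeds, tolerance_s) {
  stopifnot(inherits(map, "appearance_map"),
            all(c("row", "col", "label") %in% names(seeds)))
  H <- nrow(map$t_appear); W <- ncol(map$t_appear)
  claimed <- matrix(FALSE, H, W)
  masks <- list()
  for (lab in unique(as.character(seeds$label))) masks[[lab]] <-
    matrix(FALSE, H, W)
  tmap <- map$t_appear
  for (s in seq_len(nrow(seeds))) {
    r0 <- as.integer(seeds$row[s]); c0 <- as.integer(seeds$col[s])
    lab <- as.character(seeds$label[s])
    if (!map$valid[r0, c0] || claimed[r0, c0]) next
    region_sum <- 0; region_n <- 0L
    stack_idx <- integer(H * W)
    stack_idx[1L] <- (c0 - 1L) * H + r0
    top <- 1L
    claimed[r0, c0] <- TRUE
    while (top > 0L) {
      idx <- stack_idx[top]; top <- top - 1L
      t_px <- tmap[idx]
      mu <- if (region_n > 0L) region_sum / region_n else t_px
      if (abs(t_px - mu) > tolerance_s) {
        claimed[idx] <- FALSE   # leave it for a later-seeded region
        next
      }
      masks[[lab]][idx] <- TRUE
      region_sum <- region_sum + t_px; region_n <- region_n + 1L
      r <- (idx - 1L) %% H + 1L; c <- (idx - 1L) %/% H + 1L
      for (k in 1:4) {
        rn <- r + c(-1L, 1L, 0L, 0L)[k]; cn <- c + c(0L, 0L, -1L, 1L)[k]
        if (rn >= 1L && rn <= H && cn >= 1L && cn <= W &&
            !claimed[rn, cn] && map$valid[rn, cn] &&
            !masks[[lab]][rn, cn]) {
          claimed[rn, cn] <- TRUE
          top <- top + 1L
          if (top > length(stack_idx))
            stack_idx <- c(stack_idx, integer(H * W))
          stack_idx[top] <- (cn - 1L) * H + rn
        }
      }
    }
    claimed <- claimed | Reduce(`|`, masks)  # admitted pixels stay claimed
  }
  masks
}
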