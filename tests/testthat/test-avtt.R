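make_trace_stack <- function(traces, baseline_frames = 4,
                             frame_interval_s = 0.5) {
  # traces: list of per-pixel intensity vectors laid out on a tiny grid
  n <- length(traces[[1]])
  h <- 3; w <- 3
  frames <- array(0, dim = c(h, w, n))
  for (i in seq_along(traces))
    frames[((i - 1) %% h) + 1, ((i - 1) %/% h) + 1, ] <- traces[[i]]
  timelapse_stack(frames, frame_interval_s = frame_interval_s,
                  baseline_frames = baseline_frames)
}

test_that("median filtering is the identity at kernel 1 and removes impulses", {
  set.seed(1)
  frames <- array(runif(16 * 16 * 6, 90, 110), dim = c(16, 16, 6))
  st <- timelapse_stack(frames, frame_interval_s = 0.1,
                        baseline_frames = 3)
  expect_identical(denoise_stack(st, 1)$frames, st$frames)
  flat <- array(10, dim = c(16, 16, 3))
  flat[8, 8, 2] <- 1000
  st2 <- timelapse_stack(flat, frame_interval_s = 0.1,
                         baseline_frames = 2)
  den <- denoise_stack(st2, 3)
  expect_equal(den$frames[8, 8, 2], 10, tolerance = 1e-6)
  expect_error(denoise_stack(st, 2), "odd")
})

test_that("median filtering reduces per-pixel noise on a seeded stack", {
  sim <- make_bolus_stack(bolus_scene(height = 32, width = 32,
                                      n_frames = 30, noise_sd = 4,
                                      seed = 8))
  den <- denoise_stack(sim$stack, 3)
  # SD over the baseline frames, away from the filter's border pixels
  sd_raw <- baseline_stats(sim$stack)$sd[3:30, 3:30]
  sd_den <- baseline_stats(den)$sd[3:30, 3:30]
  expect_lt(mean(sd_den), 0.7 * mean(sd_raw))
})

test_that("baseline statistics use the sample SD over pre-injection frames", {
  tr <- c(8, 12, 100, 100, 100, 100, 100, 100)
  st <- make_trace_stack(rep(list(tr), 9), baseline_frames = 2)
  bl <- baseline_stats(st)
  expect_equal(bl$mean[1, 1], 10)
  expect_equal(bl$sd[1, 1], sqrt(8))
  const <- make_trace_stack(rep(list(rep(5, 8)), 9), baseline_frames = 4)
  expect_true(all(baseline_stats(const)$sd == 0))
})

test_that("appearance requires the frame plus `persistence` successors above threshold", {
  base <- rep(10, 4)
  run5 <- c(base, 20, 20, 20, 20, 20, 0, 0, 0)   # 5-frame run: too short
  run6 <- c(base, 20, 20, 20, 20, 20, 20, 0, 0)  # 6-frame run: qualifies
  later <- c(base, 0, 20, 20, 20, 20, 20, 20, 0) # qualifies one frame later
  never <- c(base, rep(10, 8))
  st <- make_trace_stack(list(run5, run6, later, never, never, never,
                              never, never, never),
                         baseline_frames = 4, frame_interval_s = 0.5)
  map <- appearance_time(st, k_sd = 2, persistence = 5)
  expect_false(map$valid[1, 1])
  expect_true(map$valid[2, 1])
  expect_equal(map$t_appear[2, 1], 0)
  expect_equal(map$t_appear[3, 1], 0.5)
  expect_false(map$valid[1, 2])
  # persistence must leave room in the post-baseline window
  expect_error(appearance_time(st, persistence = 9), "persistence")
})

test_that("thresholds are strict and use mean + k_sd * SD", {
  base <- c(9, 11, 9, 11)                    # mean 10, sd ~1.155
  at_thr <- c(base, rep(10 + 2 * sd(c(9, 11, 9, 11)), 9))  # == threshold
  above <- c(base, rep(13, 9))
  st <- make_trace_stack(list(at_thr, above, above, above, above, above,
                              above, above, above), baseline_frames = 4)
  map <- appearance_time(st, k_sd = 2, persistence = 5)
  expect_false(map$valid[1, 1])              # equality does not surpass
  expect_true(map$valid[2, 1])
})

test_that("raising k_sd never validates a pixel or advances its appearance", {
  sim <- make_bolus_stack(bolus_scene(height = 24, width = 24,
                                      n_frames = 50, noise_sd = 3,
                                      seed = 4))
  m1 <- appearance_time(sim$stack, k_sd = 1)
  m2 <- appearance_time(sim$stack, k_sd = 2)
  m3 <- appearance_time(sim$stack, k_sd = 4)
  expect_true(all(m2$valid <= m1$valid))
  expect_true(all(m3$valid <= m2$valid))
  both <- m1$valid & m2$valid
  expect_true(all(m2$t_appear[both] >= m1$t_appear[both]))
})

test_that("noise-free step arrivals are recovered up to frame quantization", {
  sc <- bolus_scene(height = 24, width = 24, n_frames = 60,
                    rise_time_s = 0, noise_sd = 0, seed = 6)
  sim <- make_bolus_stack(sc)
  map <- appearance_time(sim$stack, k_sd = 2, persistence = 5)
  dt <- sim$stack$frame_interval_s
  reach <- sim$truth$reachable
  expect_true(all(map$valid[reach]))
  err <- map$t_appear[reach] - sim$truth$t_arrival[reach]
  # detection at the first frame at or after the true arrival
  expect_true(all(err >= 0 & err <= dt + 1e-12))
})

test_that("temporal 2x downsampling moves appearance by at most one coarse frame", {
  sc <- bolus_scene(height = 24, width = 24, n_frames = 60,
                    rise_time_s = 0, noise_sd = 0, seed = 7)
  sim <- make_bolus_stack(sc)
  fine <- appearance_time(sim$stack, k_sd = 2, persistence = 5)
  coarse_frames <- sim$stack$frames[, , seq(1, 60, by = 2)]
  coarse <- timelapse_stack(coarse_frames,
                            frame_interval_s = 2 * sim$stack$frame_interval_s,
                            baseline_frames = 5)
  cmap <- appearance_time(coarse, k_sd = 2, persistence = 5)
  both <- fine$valid & cmap$valid
  expect_gt(mean(both[sim$truth$reachable]), 0.95)
  d <- abs(cmap$t_appear[both] - fine$t_appear[both])
  expect_true(all(d <= 2 * sim$stack$frame_interval_s + 1e-12))
})

test_that("segment statistics match brute-force recomputation and report areas", {
  sim <- make_bolus_stack(bolus_scene(seed = 11))
  map <- appearance_time(denoise_stack(sim$stack, 3))
  mask <- sim$truth$arterial_mask
  st <- segment_stats(map, mask, "arterial")
  vals <- map$t_appear[mask & map$valid]
  expect_equal(st$pixel_count, length(vals))
  expect_equal(st$mean_s, mean(vals))
  expect_equal(st$sd_s, sd(vals))
  expect_equal(st$median_s, median(vals))
  expect_equal(st$area_fraction, length(vals) / (96 * 96))
  # whole-image mask on an all-valid map covers 100%
  full <- matrix(TRUE, 96, 96)
  allmap <- map
  allmap$valid[] <- TRUE
  allmap$t_appear[] <- 1
  expect_equal(segment_stats(allmap, full)$area_fraction, 1)
  empty <- matrix(FALSE, 96, 96)
  expect_error(segment_stats(map, empty, "x"),
               class = "microvel_empty_segment")
})

test_that("AVTT subtracts arterial from venous statistics", {
  seg <- function(mean_s, median_s, label)
    structure(list(label = label, pixel_count = 1000L,
                   area_fraction = 0.1, mean_s = mean_s, sd_s = 0.1,
                   median_s = median_s), class = "segment_stats")
  res <- compute_avtt(seg(0.29, 0.21, "arterial"),
                      seg(1.43, 1.33, "venous"))
  expect_equal(res$avtt_mean_s, 1.14)
  expect_equal(res$avtt_median_s, 1.12)
  same <- compute_avtt(seg(0.5, 0.5, "a"), seg(0.5, 0.5, "v"))
  expect_equal(same$avtt_mean_s, 0)
  expect_warning(compute_avtt(seg(1.0, 1.0, "a"), seg(0.4, 0.4, "v")),
                 "negative AVTT")
})

test_that("an all-background stack leaves every pixel excluded", {
  frames <- array(100, dim = c(12, 12, 30))
  set.seed(9)
  frames <- frames + rnorm(length(frames))
  st <- timelapse_stack(frames, frame_interval_s = 0.1,
                        baseline_frames = 8)
  map <- appearance_time(st, k_sd = 4, persistence = 5)
  expect_false(any(map$valid))
  expect_error(segment_stats(map, matrix(TRUE, 12, 12)),
               class = "microvel_empty_segment")
})

test_that("region growing recovers well-separated arrival plateaus", {
  t_map <- matrix(NA_real_, 20, 20)
  t_map[3:18, 2:9] <- 0.3
  t_map[3:18, 12:19] <- 1.5
  map <- structure(list(t_appear = t_map, valid = !is.na(t_map),
                        frame_interval_s = 0.1, duration_s = 3),
                   class = "appearance_map")
  seeds <- data.frame(row = c(5, 5), col = c(3, 15),
                      label = c("arterial", "venous"))
  masks <- segment_assist(map, seeds, tolerance_s = 0.2)
  expect_equal(masks$arterial, !is.na(t_map) & t_map == 0.3)
  expect_equal(masks$venous, !is.na(t_map) & t_map == 1.5)
  expect_false(any(masks$arterial & masks$venous))
  # zero tolerance only admits exact matches of the seed value
  t_map2 <- t_map
  t_map2[4, 3] <- 0.31
  map2 <- map; map2$t_appear <- t_map2
  m0 <- segment_assist(map2, seeds[1, ], tolerance_s = 0)
  expect_false(m0$arterial[4, 3])
  expect_true(m0$arterial[5, 3])
})

test_that("region growing recovers generator segments on a bolus fixture", {
  # tight arrival spread within each segment: appearance time is then
  # spatially continuous along the vessel, the regime the assistant
  # (like the manual tracing it automates) relies on
  sim <- make_bolus_stack(bolus_scene(arterial_arrival_sd_s = 0.05,
                                      venous_arrival_sd_s = 0.05,
                                      noise_sd = 1, seed = 12))
  map <- appearance_time(denoise_stack(sim$stack, 3))
  dt <- sim$stack$frame_interval_s
  seeds <- data.frame(row = c(48, 48), col = c(5, 90),
                      label = c("arterial", "venous"))
  masks <- segment_assist(map, seeds, tolerance_s = 2 * dt)
  jaccard <- function(a, b) sum(a & b) / sum(a | b)
  ref_a <- sim$truth$arterial_mask & map$valid
  ref_v <- sim$truth$venous_mask & map$valid
  expect_gt(jaccard(masks$arterial, ref_a), 0.95)
  expect_gt(jaccard(masks$venous, ref_v), 0.95)
})
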