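# build a ComponentSet list from a list of logical matrices (one per frame)
component_sets_from <- function(masks, ps = 1) {
  lapply(masks, function(px) label_components(binary_mask(px, ps)))
}

disc_at <- function(r, cc, size = 40) {
  px <- matrix(FALSE, size, size)
  px[(r - 1):(r + 1), (cc - 1):(cc + 1)] <- TRUE
  px
}

test_that("stationary cells yield one track per cell across all frames", {
  masks <- replicate(5, disc_at(10, 10) | disc_at(30, 25), simplify = FALSE)
  cs <- component_sets_from(masks)
  tr <- link_tracks(cs, timestamps = (0:4) * 10, max_step = 5)
  expect_equal(length(unique(tr$tracks$track_id)), 2)
  expect_true(all(table(tr$tracks$track_id) == 5))
})

test_that("displacement beyond max_step terminates the track and starts a new one", {
  masks <- list(disc_at(10, 10), disc_at(10, 12), disc_at(10, 30))
  cs <- component_sets_from(masks)
  tr <- link_tracks(cs, (0:2) * 10, max_step = 5)
  expect_equal(length(unique(tr$tracks$track_id)), 2)
  t1 <- tr$tracks[tr$tracks$track_id == 1, ]
  expect_equal(t1$frame, 1:2)
})

test_that("slow non-crossing walkers are recovered as single tracks", {
  # step sd far below max_step, sparse field: >= 95% of cells one track
  n_cells_total <- 0; n_single <- 0
  for (s in 1:5) {
    sim <- generate_timelapse(timelapse_params(
      field_size = c(300, 300), n_target_cells = 0, n_effector_cells = 6,
      effector_step_sd = 2, n_frames = 15L, seed = s))
    cs <- segment_frames(sim$timelapse, "effector", min_area = 25)
    tr <- link_tracks(cs, sim$timelapse$timestamps, max_step = 20)
    spans <- table(tr$tracks$track_id)
    n_cells_total <- n_cells_total + 6
    n_single <- n_single + sum(spans == 15)
  }
  expect_gte(n_single / n_cells_total, 0.95)
})

test_that("detect_contact finds the first frame of mask adjacency", {
  # effector approaches; at frame 3 its dilated mask overlaps the target
  eff <- list(disc_at(10, 10), disc_at(10, 14), disc_at(10, 17))
  tgt <- replicate(3, disc_at(10, 20), simplify = FALSE)
  ts <- c(0, 15, 30)
  etr <- link_tracks(component_sets_from(eff), ts, max_step = 10)
  ttr <- link_tracks(component_sets_from(tgt), ts, max_step = 10)
  expect_equal(detect_contact(etr, ttr, 1, 1, contact_dilation = 1), 30)
  # always >= 5 px apart with dilation 1: no contact
  far <- list(disc_at(10, 10), disc_at(10, 11), disc_at(10, 12))
  ftr <- link_tracks(component_sets_from(far), ts, max_step = 10)
  expect_true(is.na(detect_contact(ftr, ttr, 1, 1, contact_dilation = 1)))
})

test_that("detect_pi_uptake applies the onset and persistence rules", {
  tgt <- replicate(8, disc_at(10, 10), simplify = FALSE)
  ts <- (0:7) * 10
  ttr <- link_tracks(component_sets_from(tgt), ts, max_step = 5)
  none <- lapply(1:8, function(i) binary_mask(matrix(FALSE, 40, 40), 1))
  expect_true(is.na(detect_pi_uptake(ttr, 1, none)))
  # full overlap from frame 5 onward -> uptake at frame 5's timestamp (40)
  on5 <- lapply(1:8, function(i)
    binary_mask(if (i >= 5) disc_at(10, 10) else matrix(FALSE, 40, 40), 1))
  expect_equal(detect_pi_uptake(ttr, 1, on5, onset_fraction = 0.3,
                                persistence = 2), 40)
  # single-frame flicker rejected by persistence = 2
  flicker <- lapply(1:8, function(i)
    binary_mask(if (i == 5) disc_at(10, 10) else matrix(FALSE, 40, 40), 1))
  expect_true(is.na(detect_pi_uptake(ttr, 1, flicker, persistence = 2)))
  expect_equal(detect_pi_uptake(ttr, 1, flicker, persistence = 1), 40)
})

test_that("time_for_killing subtracts times and enforces ordering", {
  expect_equal(time_for_killing("01:00", "01:45"), 45)
  expect_equal(time_for_killing(10, 62.5), 52.5)
  expect_error(time_for_killing(30, 30), "event-ordering")
  expect_error(time_for_killing(45, 30), "event-ordering")
})

test_that("compare_groups reproduces the closed-form pooled-variance t-test", {
  gc <- compare_groups(c(1, 2, 3), c(4, 5, 6))
  expect_equal(gc$t_statistic, -3.6742, tolerance = 1e-4)
  expect_equal(gc$df, 4)
  expect_equal(gc$p_value, 2 * pt(-abs(gc$t_statistic), 4))
  expect_equal(gc$p_value, 0.0213, tolerance = 1e-3)
  # identical groups: t = 0, p = 1
  same <- compare_groups(c(2, 2, 2), c(2, 2, 2))
  expect_equal(same$t_statistic, 0)
  expect_equal(same$p_value, 1)
  # symmetry up to the sign of t
  ab <- compare_groups(c(1, 5, 7, 2), c(3, 9, 4))
  ba <- compare_groups(c(3, 9, 4), c(1, 5, 7, 2))
  expect_equal(ab$t_statistic, -ba$t_statistic)
  expect_equal(ab$p_value, ba$p_value)
  expect_error(compare_groups(1, c(2, 3)), "sample-size")
})

test_that("compare_groups detects a 3-sd gap with n = 30 nearly always", {
  set.seed(123)
  hits <- sum(replicate(100, {
    a <- rnorm(30, 0, 1); b <- rnorm(30, 3, 1)
    compare_groups(a, b)$p_value < 0.001
  }))
  expect_gte(hits, 95)
})

test_that("extracted kill events recover the generator's timing end-to-end", {
  sim <- generate_timelapse(timelapse_params(
    seed = 5, kill_probability_per_contact = 1, n_frames = 30L))
  ev <- extract_kill_events(sim$timelapse)
  expect_gt(nrow(ev), 0)
  expect_true(all(ev$pi_time > ev$contact_time))
  expect_true(all(ev$time_for_killing > 0))
  # recovered contacts sit within one frame interval of truth for >= 90%
  ok <- 0
  for (k in seq_len(nrow(ev))) {
    d <- min(abs(sim$events$contact_time - ev$contact_time[k]))
    if (d <= 10) ok <- ok + 1
  }
  expect_gte(ok / nrow(ev), 0.9)
})
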