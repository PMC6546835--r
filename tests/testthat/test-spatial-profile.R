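test_that("make_roi derives bins and rejects non-divisible geometry", {
  roi <- make_roi(side_length = 700, bin_width = 100)
  expect_equal(roi$n_bins, 7L)
  expect_equal(roi$bin_labels, paste0("R", 0:6))
  expect_equal(roi$analysis_bins, 1:5)
  expect_equal(make_roi(side_length = 100, bin_width = 100)$n_bins, 1L)
  expect_error(make_roi(side_length = 700, bin_width = 150), "geometry")
  expect_error(make_roi(side_length = 700, bin_width = 100,
                        analysis_bins = c(1, 9)), "0..6")
})

test_that("bin_areas assigns pixel centers to half-open bins and conserves area", {
  roi <- make_roi(side_length = 700, bin_width = 100)
  # mask entirely inside R1 (depth 100-200 um at 2 um/px: columns 51-100)
  px <- matrix(FALSE, 20, 350)
  px[5:10, 60:80] <- TRUE
  m <- binary_mask(px, pixel_size = 2)
  ba <- bin_areas(m, roi)
  expect_equal(unname(ba), c(0, 6 * 21 * 4, 0, 0, 0, 0, 0))
  # uniform foreground splits equally across the 7 bins
  full <- binary_mask(matrix(TRUE, 10, 350), pixel_size = 2)
  expect_true(all(bin_areas(full, roi) == 10 * 50 * 4))
  # random masks against the per-pixel recount oracle, exact conservation
  set.seed(21)
  for (i in 1:5) {
    rnd <- binary_mask(matrix(runif(40 * 350) < 0.3, 40, 350), pixel_size = 2)
    ba <- bin_areas(rnd, roi)
    expect_equal(ba, bin_areas_oracle(rnd, roi))
    expect_identical(sum(ba), mask_area(rnd))
  }
  expect_error(bin_areas(binary_mask(matrix(TRUE, 5, 10), 2), roi), "exceeds")
})

test_that("profile flags bins without target area as undefined, not zero", {
  roi <- make_roi(side_length = 700, bin_width = 100)
  cal <- calibrate(150, 400, 200)
  empty <- binary_mask(matrix(FALSE, 30, 350), 2)
  prof <- profile_subregions(empty, empty, empty, roi, cal)
  expect_true(all(prof$effector_count == 0))
  expect_true(all(is.na(prof$percent_killed)))
  # live area everywhere, dead nowhere: 0% where defined
  live <- binary_mask(matrix(TRUE, 30, 350), 2)
  prof2 <- profile_subregions(empty, live, empty, roi, cal)
  expect_true(all(prof2$percent_killed == 0))
  expect_error(profile_subregions(empty, live,
                                  binary_mask(matrix(FALSE, 10, 10), 2),
                                  roi, cal), "shape")
})

test_that("overall_percent_killed pools R1-R5 only and ignores R0/R6 content", {
  roi <- make_roi(side_length = 700, bin_width = 100)
  cal <- calibrate(150, 500, 250)  # ratio 2
  ps <- 2
  live <- matrix(FALSE, 20, 350); dead <- matrix(FALSE, 20, 350)
  # pooled live 500 um^2 (125 px) and dead 250 um^2 in R1-R5
  live[1:5, 60:84] <- TRUE                    # 125 px in R1
  dead[10, 110:171] <- TRUE; dead[11, 110:111] <- TRUE  # 64 px spread R2-R3
  lm <- binary_mask(live, ps); dm <- binary_mask(dead, ps)
  expect_equal(sum(bin_areas(lm, roi)[2:6]), 500)
  # converted dead = 2 * measured dead; evaluate against direct formula
  dead_area <- sum(bin_areas(dm, roi)[2:6])
  expect_equal(overall_percent_killed(lm, dm, roi, cal),
               100 * 2 * dead_area / (500 + 2 * dead_area))
  # dead area confined to R0 and R6 contributes nothing
  dead0 <- matrix(FALSE, 20, 350)
  dead0[, c(1:50, 301:350)] <- TRUE
  expect_equal(overall_percent_killed(lm, binary_mask(dead0, ps), roi, cal), 0)
  # any modification confined to R0/R6 leaves the statistic unchanged
  live_mod <- live; live_mod[, 1:50] <- TRUE
  dead_mod <- dead; dead_mod[, 301:350] <- TRUE
  expect_equal(
    overall_percent_killed(binary_mask(live_mod, ps),
                           binary_mask(dead_mod, ps), roi, cal),
    overall_percent_killed(lm, dm, roi, cal))
  expect_error(overall_percent_killed(binary_mask(matrix(FALSE, 20, 350), ps),
                                      binary_mask(dead0, ps), roi, cal),
               "undefined")
})

test_that("aggregate_profiles computes per-bin mean and SEM with pairwise NA handling", {
  roi <- make_roi(side_length = 300, bin_width = 100)
  cal <- calibrate(100, 400, 200)
  mk <- function(eff_cols, pk_cols, rep) {
    ps <- 2
    eff <- matrix(FALSE, 10, 150); eff[1:5, eff_cols] <- TRUE
    live <- matrix(FALSE, 10, 150); live[6:8, pk_cols] <- TRUE
    profile_subregions(binary_mask(eff, ps), binary_mask(live, ps),
                       binary_mask(matrix(FALSE, 10, 150), ps),
                       roi, cal, replicate = rep)
  }
  # effector counts {1, 2, 3} in bin R0 across replicates
  profs <- lapply(1:3, function(r) mk(1:(5 * r), 60:70, r))
  smry <- aggregate_profiles(profs)
  # counts are 1, 2, 3 cells (25, 50, 75 px at 4 um^2 over a 100-um^2 cell)
  expect_equal(smry$mean_count[1], 2)
  counts <- sapply(profs, function(p) p$effector_count[1])
  expect_equal(smry$sem_count[1], sd(counts) / sqrt(3))
  # single replicate: SEM undefined
  one <- aggregate_profiles(profs[1])
  expect_true(is.na(one$sem_count[1]))
  expect_equal(one$mean_count[1], profs[[1]]$effector_count[1])
  # identical replicates: SEM 0
  same <- aggregate_profiles(list(profs[[2]], profs[[2]]))
  expect_equal(same$sem_count[1], 0)
  # undefined percent_killed bins are excluded pairwise with n reported
  expect_equal(smry$n_killed[1], 0)   # no target area in R0
  expect_true(is.na(smry$mean_killed[1]))
  expect_equal(smry$n_killed[2], 3)   # targets in R1 in all replicates
  expect_error(aggregate_profiles(list()), "empty")
})

test_that("replicate counts {1,2,3} give mean 2 and SEM 1/sqrt(3)", {
  expect_equal(sd(c(1, 2, 3)) / sqrt(3), 1 / sqrt(3))
  roi <- make_roi(side_length = 100, bin_width = 100)
  cal <- calibrate(4, 400, 200)  # 1 px = 1 cell at ps 2
  mk <- function(n) {
    px <- matrix(FALSE, 10, 50); px[1, seq_len(n)] <- TRUE
    profile_subregions(binary_mask(px, 2),
                       binary_mask(matrix(TRUE, 10, 50), 2),
                       binary_mask(matrix(FALSE, 10, 50), 2), roi, cal)
  }
  smry <- aggregate_profiles(lapply(1:3, mk))
  expect_equal(smry$mean_count, 2)
  expect_equal(smry$sem_count, 1 / sqrt(3), tolerance = 1e-12)
})
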