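test_that("dead-cell count is exact when n x fraction is integral", {
  sc <- generate_scene(scene_params(field_size = c(500, 500),
                                    n_target_cells = 50, dead_fraction = 0.2,
                                    n_effector_cells = 10, seed = 4))
  tgt <- sc$truth$cells[sc$truth$cells$cell_type == "target", ]
  expect_equal(nrow(tgt), 50)
  expect_equal(sum(tgt$state == "dead"), 10)
})

test_that("zero effectors leave a background-only effector channel", {
  p <- small_scene_params(seed = 2, n_effector_cells = 0)
  sc <- generate_scene(p)
  eff <- sc$channels$effector$data
  expect_lt(max(eff), p$background_level + 6 * p$noise_sd)
  expect_true(all(sc$truth$per_bin_effector_count == 0))
})

test_that("identical parameters and seed give bit-identical scenes", {
  a <- generate_scene(small_scene_params(seed = 33))
  b <- generate_scene(small_scene_params(seed = 33))
  expect_identical(a$channels$target$data, b$channels$target$data)
  expect_identical(a$channels$effector$data, b$channels$effector$data)
  expect_identical(a$channels$dead_stain$data, b$channels$dead_stain$data)
  expect_identical(a$truth$cells, b$truth$cells)
  c <- generate_scene(small_scene_params(seed = 34))
  expect_false(identical(a$channels$target$data, c$channels$target$data))
})

test_that("dead-stain foreground lies only on dead-target footprints", {
  p <- small_scene_params(seed = 6, dead_fraction = 0.3, noise_sd = 0)
  sc <- generate_scene(p)
  dead_fg <- sc$channels$dead_stain$data[, , 1] == p$foreground_level
  tgt_fg <- sc$channels$target$data[, , 1] == p$foreground_level
  expect_true(all(tgt_fg[dead_fg]))  # confinement to target cells
  dead_cells <- sc$truth$cells[sc$truth$cells$cell_type == "target" &
                                 sc$truth$cells$state == "dead", ]
  expect_equal(sum(dead_fg) * p$pixel_size^2, sum(dead_cells$rendered_area))
})

test_that("truth per-bin counts match a direct recount of cell depths", {
  sc <- generate_scene(scene_params(seed = 12))
  roi <- sc$truth$roi
  eff <- sc$truth$cells[sc$truth$cells$cell_type == "effector", ]
  recount <- vapply(seq_len(roi$n_bins) - 1L, function(b)
    sum(eff$depth >= b * roi$bin_width & eff$depth < (b + 1) * roi$bin_width),
    1L)
  expect_equal(unname(sc$truth$per_bin_effector_count), as.numeric(recount))
  expect_true(all(sc$truth$true_percent_killed >= 0 &
                    sc$truth$true_percent_killed <= 100, na.rm = TRUE))
})

test_that("effector depths follow the stated exponential decay", {
  # ML fit (sample mean of depths) across 20 seeds within 20% of 100 um;
  # overlap allowed so packing pressure cannot distort the depth law
  fits <- sapply(1:20, function(s) {
    sc <- generate_scene(scene_params(seed = s, infiltration_decay_length = 100,
                                      n_effector_cells = 500,
                                      n_target_cells = 0,
                                      allow_overlap = TRUE))
    cells <- sc$truth$cells
    mean(cells$depth[cells$cell_type == "effector"])
  })
  expect_lt(abs(mean(fits) - 100) / 100, 0.2)
  # and per-bin counts decrease R1 to R5 on average
  sc <- generate_scene(scene_params(seed = 1, infiltration_decay_length = 100,
                                    n_effector_cells = 500,
                                    n_target_cells = 0,
                                    allow_overlap = TRUE))
  counts <- sc$truth$per_bin_effector_count[2:6]
  expect_true(all(diff(counts) <= 0))
})

test_that("infeasible density raises a placement error naming the culprit", {
  p <- scene_params(field_size = c(60, 60), n_target_cells = 40,
                    n_effector_cells = 0, seed = 1)
  expect_error(generate_scene(p), "placement error")
})

test_that("scene parameter invariants are enforced", {
  expect_error(scene_params(dead_fraction = 1.2), "dead_fraction")
  expect_error(scene_params(live_axis_ratio = 0.5), "live_axis_ratio")
  expect_error(scene_params(pixel_size = 0), "pixel_size")
  expect_error(scene_params(field_size = c(701, 700)), "multiples")
  expect_error(scene_params(live_area_mean = -5), "live_area_mean")
})

test_that("truth and event tables round-trip losslessly through CSV", {
  sc <- generate_scene(small_scene_params(seed = 9))
  path <- withr::local_tempfile(fileext = ".csv")
  write_truth(sc$truth, path)
  back <- read_truth(path)
  expect_equal(nrow(back), nrow(sc$truth$cells))
  expect_equal(back$x, sc$truth$cells$x, tolerance = 1e-12)
  expect_identical(back$state, sc$truth$cells$state)
  # three-row table -> three data rows
  small <- sc$truth$cells[1:3, ]
  write_truth(small, path)
  expect_equal(nrow(read_truth(path)), 3)
  # empty event log -> header-only file the reader accepts
  empty <- data.frame(effector_id = integer(), target_id = integer(),
                      contact_time = numeric(), pi_time = numeric(),
                      time_for_killing = numeric())
  write_truth(empty, path)
  back2 <- read_truth(path)
  expect_equal(nrow(back2), 0)
  expect_identical(names(back2), names(empty))
  expect_error(write_truth(empty, file.path(tempdir(), "no", "such", "dir", "x.csv")),
               "I/O error")
})
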