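#' Parameters for a synthetic assay scene
#'
#' The generator emulates an endpoint co-culture image of a gel block seen
#' from above: target cells (e.g. CFSE-labelled HeLa) scattered uniformly
#' through the gel, effector cells (e.g. NK-92) that entered from the
#' gel-media face with an exponentially decaying depth distribution, and a
#' dead-stain channel (e.g. propidium iodide) lit only over dead targets.
#' Live targets are rendered as ellipses (extended morphology), dead
#' targets and effectors as discs (rounded morphology). Intensities are a
#' flat foreground over a flat background with additive Gaussian noise,
#' clipped to the bit depth.
#'
#' Defaults describe one fixed "stated world": a 700 x 700 um field
#' (matching the reference ROI) at 2 um/pixel, 120 targets of which 30%
#' are dead, 150 effectors with a 150-um infiltration decay length, live
#' targets of 400 +/- 60 um^2 at axis ratio 2.5, dead targets 200 +/- 30
#' um^2 (live/dead area ratio 2), effectors 120 +/- 20 um^2, and a clean
#' intensity separation (background 20, foreground 200, noise sd 5,
#' 8-bit).
#'
#' @param field_size `c(width_x, height_y)` in um; each must be a positive
#'   multiple of `pixel_size`.
#' @param pixel_size um per pixel.
#' @param gel_interface_x x position (um) of the gel-media face effectors
#'   enter from; depth is measured from here.
#' @param n_target_cells,n_effector_cells cell counts.
#' @param dead_fraction proportion of targets rendered dead, in `[0, 1]`.
#'   The realised count is `round(n_target_cells * dead_fraction)` (exact,
#'   not binomial, so ground truth is sharp).
#' @param infiltration_decay_length length scale (um) of the exponential
#'   decay of effector density with depth.
#' @param live_axis_ratio major/minor axis ratio of live-target ellipses
#'   (>= 1).
#' @param live_area_mean,live_area_sd,dead_area_mean,dead_area_sd,effector_area_mean,effector_area_sd
#'   single-cell area distributions in um^2 (normal, truncated at 25% of
#'   the mean).
#' @param background_level,foreground_level,noise_sd intensities (a.u.).
#' @param bit_depth 8 or 16.
#' @param infiltration_mode `"count"` (default): exactly
#'   `n_effector_cells` are placed, with depths from the truncated
#'   exponential — the sharp-truth contract. `"flux"`: `n_effector_cells`
#'   cells are seeded at the gel face and each *enters* only with
#'   probability `exp(-d/L)` for its attempted depth `d` (drawn uniform
#'   over the field); blocked cells pile up against the face (half-normal
#'   depths, 15-um scale, overlap allowed), so a denser matrix (shorter
#'   decay length) shows fewer cells at every analysis depth and an
#'   accumulation in the boundary bin, as real dense gels do.
#' @param dead_placement `"uniform"` (default): dead targets are placed
#'   like live ones, so the true kill fraction is depth-independent.
#'   `"exposure"`: dead-target positions are accepted with probability
#'   `exp(-depth/infiltration_decay_length)`, concentrating kills where
#'   effectors actually reach — the spatial coupling between infiltration
#'   and killing.
#' @param allow_overlap if `FALSE` (default) cells are placed by rejection
#'   sampling with at least one background pixel between footprints, so
#'   rendered components map one-to-one to cells; `TRUE` permits overlap
#'   for stress tests.
#' @param seed integer seed; identical parameters and seed give
#'   bit-identical scenes.
#' @return an object of class `SceneParams`.
#' @export
scene_params <- function(field_size = c(700, 700), pixel_size = 2,
                         gel_interface_x = 0,
                         n_target_cells = 120, dead_fraction = 0.3,
                         n_effector_cells = 150,
                         infiltration_decay_length = 150,
                         live_axis_ratio = 2.5,
                         live_area_mean = 400, live_area_sd = 60,
                         dead_area_mean = 200, dead_area_sd = 30,
                         effector_area_mean = 120, effector_area_sd = 20,
                         background_level = 20, foreground_level = 200,
                         noise_sd = 5, bit_depth = 8L,
                         infiltration_mode = c("count", "flux"),
                         dead_placement = c("uniform", "exposure"),
                         allow_overlap = FALSE, seed = 1L) {
  p <- list(field_size = field_size, pixel_size = pixel_size,
            gel_interface_x = gel_interface_x,
            n_target_cells = as.integer(n_target_cells),
            dead_fraction = dead_fraction,
            n_effector_cells = as.integer(n_effector_cells),
            infiltration_decay_length = infiltration_decay_length,
            live_axis_ratio = live_axis_ratio,
            live_area_mean = live_area_mean, live_area_sd = live_area_sd,
            dead_area_mean = dead_area_mean, dead_area_sd = dead_area_sd,
            effector_area_mean = effector_area_mean,
            effector_area_sd = effector_area_sd,
            background_level = background_level,
            foreground_level = foreground_level,
            noise_sd = noise_sd, bit_depth = as.integer(bit_depth),
            infiltration_mode = match.arg(infiltration_mode),
            dead_placement = match.arg(dead_placement),
            allow_overlap = isTRUE(allow_overlap), seed = as.integer(seed))
  validate_scene_params(p)
  structure(p, class = "SceneParams")
}

validate_scene_params <- function(p) {
  check_number(p$pixel_size, "pixel_size", lower = 0, allow_equal_lower = FALSE)
  if (length(p$field_size) != 2L || any(p$field_size <= 0) ||
      !all(is_wholenumber(p$field_size / p$pixel_size)))
    stopf("'field_size' must be two positive multiples of pixel_size")
  check_number(p$gel_interface_x, "gel_interface_x", lower = 0)
  check_number(p$dead_fraction, "dead_fraction", lower = 0, upper = 1)
  check_number(p$live_axis_ratio, "live_axis_ratio", lower = 1)
  check_number(p$infiltration_decay_length, "infiltration_decay_length",
               lower = 0, allow_equal_lower = FALSE)
  for (nm in c("live_area_mean", "dead_area_mean", "effector_area_mean"))
    check_number(p[[nm]], nm, lower = 0, allow_equal_lower = FALSE)
  for (nm in c("live_area_sd", "dead_area_sd", "effector_area_sd", "noise_sd"))
    check_number(p[[nm]], nm, lower = 0)
  if (p$n_target_cells < 0 || p$n_effector_cells < 0)
    stopf("cell counts must be non-negative")
  if (!p$bit_depth %in% c(8L, 16L)) stopf("'bit_depth' must be 8 or 16")
  if (p$foreground_level <= p$background_level)
    stopf("'foreground_level' must exceed 'background_level'")
  invisible(p)
}

# Truncated-normal area draw; truncation at 25% of the mean keeps areas
# positive without meaningfully distorting the stated mean/sd.
draw_area <- function(n, mean, sd) {
  if (n == 0L) return(numeric())
  lo <- 0.25 * mean
  x <- rnorm(n, mean, sd)
  while (any(bad <- x < lo)) x[bad] <- rnorm(sum(bad), mean, sd)
  x
}

# Pixel footprint (row/col indices) of an ellipse or disc centred at
# (x, y) um. By default returns NULL when any part would leave the image,
# so placed cells always have their full analytic area rendered; with
# clip = TRUE the footprint is clipped at the borders instead (used when
# rendering moving cells that may brush the field edge).
cell_footprint <- function(x, y, area, axis_ratio, theta, ps, nr, nc,
                           clip = FALSE) {
  a <- sqrt(area * axis_ratio / pi)  # semi-major (um); disc when ratio = 1
  b <- sqrt(area / (axis_ratio * pi))
  r_max <- a
  if (!clip && (x - r_max < 0 || y - r_max < 0 ||
                x + r_max > nc * ps || y + r_max > nr * ps)) return(NULL)
  c0 <- max(1L, floor((x - r_max) / ps)); c1 <- min(nc, ceiling((x + r_max) / ps) + 1L)
  r0 <- max(1L, floor((y - r_max) / ps)); r1 <- min(nr, ceiling((y + r_max) / ps) + 1L)
  cols <- c0:c1; rows <- r0:r1
  cx <- (cols - 0.5) * ps - x
  cy <- (rows - 0.5) * ps - y
  dx <- matrix(cx, nrow = length(rows), ncol = length(cols), byrow = TRUE)
  dy <- matrix(cy, nrow = length(rows), ncol = length(cols))
  u <- (dx * cos(theta) + dy * sin(theta)) / a
  v <- (-dx * sin(theta) + dy * cos(theta)) / b
  inside <- u * u + v * v <= 1
  if (!any(inside)) return(NULL)
  idx <- which(inside, arr.ind = TRUE)
  cbind(row = rows[idx[, 1]], col = cols[idx[, 2]])
}

# Rejection-sampled placement. `draw_xy` proposes a centroid; a candidate
# is accepted when its footprint fits the image and (unless allow_overlap)
# its dilated footprint misses every previously placed footprint. The
# 2-pixel margin keeps components 8-disconnected even after the 3x3
# median despeckle, which can bridge single-pixel gaps.
place_cells <- function(n, draw_xy, areas, axis_ratio, ps, nr, nc,
                        occupied, allow_overlap, what, max_tries = 500L,
                        margin = 2L) {
  rows <- vector("list", n)
  thetas <- numeric(n)
  for (i in seq_len(n)) {
    theta <- if (axis_ratio > 1) runif(1, 0, pi) else 0
    placed <- FALSE
    for (try in seq_len(max_tries)) {
      xy <- draw_xy()
      fp <- cell_footprint(xy[1], xy[2], areas[i], axis_ratio, theta, ps, nr, nc)
      if (is.null(fp)) next
      if (!allow_overlap) {
        # dilated neighbourhood check against the occupancy grid
        clash <- FALSE
        for (dr in -margin:margin) {
          for (dcol in -margin:margin) {
            r2 <- fp[, 1] + dr; c2 <- fp[, 2] + dcol
            ok <- r2 >= 1L & r2 <= nr & c2 >= 1L & c2 <= nc
            if (any(occupied[cbind(r2[ok], c2[ok])])) { clash <- TRUE; break }
          }
          if (clash) break
        }
        if (clash) next
      }
      occupied[fp] <- TRUE
      rows[[i]] <- list(x = xy[1], y = xy[2], theta = theta, footprint = fp)
      placed <- TRUE
      break
    }
    if (!placed)
      stopf(paste0("placement error: could not place %s cell %d of %d after %d ",
                   "tries; cell density too high for non-overlapping placement"),
            what, i, n, max_tries)
  }
  list(cells = rows, occupied = occupied)
}

render_channel <- function(footprints, nr, nc, p) {
  img <- matrix(p$background_level, nr, nc)
  for (fp in footprints) if (!is.null(fp)) img[fp] <- p$foreground_level
  if (p$noise_sd > 0) img <- img + rnorm(nr * nc, 0, p$noise_sd)
  vmax <- 2^p$bit_depth - 1
  img[] <- pmin(pmax(round(img), 0), vmax)
  img
}

#' Generate a synthetic endpoint scene with ground truth
#'
#' See [scene_params()] for the model. Effector centroid depths are drawn
#' with density proportional to `exp(-depth / infiltration_decay_length)`,
#' truncated to the field; target centroids are uniform over the gel. The
#' dead-stain channel renders foreground only on dead-target footprints.
#'
#' @param params a [scene_params()].
#' @param roi optional [make_roi()] used for the ground-truth per-bin
#'   tallies; defaults to the reference geometry (as much of a 700-um,
#'   100-um-binned ROI as fits the field).
#' @return a list with `channels` (named list of single-plane
#'   [image_stack()]s: `target`, `effector`, `dead_stain`) and `truth`, a
#'   `GroundTruth` list containing `cells` (one row per rendered cell:
#'   `cell_id`, `cell_type`, `state`, `x`, `y`, `depth`, `drawn_area`,
#'   `rendered_area`), `per_bin_effector_count`, `true_percent_killed`
#'   (per bin, count-based), `true_percent_killed_overall` (analysis bins
#'   only), the `roi`, and the `params` echoed with the seed.
#' @export
generate_scene <- function(params, roi = NULL) {
  stopifnot(inherits(params, "SceneParams"))
  p <- params
  ps <- p$pixel_size
  nc <- as.integer(round(p$field_size[1] / ps))
  nr <- as.integer(round(p$field_size[2] / ps))
  if (is.null(roi)) {
    side <- min(700, floor(p$field_size[1] / 100) * 100)
    roi <- if (side >= 100)
      make_roi(interface_x = p$gel_interface_x, side_length = side,
               bin_width = 100)
    else  # field narrower than one standard bin: single-bin ROI
      make_roi(interface_x = p$gel_interface_x,
               side_length = p$field_size[1] - p$gel_interface_x,
               bin_width = p$field_size[1] - p$gel_interface_x)
  }

  with_seed_(p$seed, {
    n_dead <- as.integer(round(p$n_target_cells * p$dead_fraction))
    n_live <- p$n_target_cells - n_dead
    states <- c(rep("live", n_live), rep("dead", n_dead))

    live_areas <- draw_area(n_live, p$live_area_mean, p$live_area_sd)
    dead_areas <- draw_area(n_dead, p$dead_area_mean, p$dead_area_sd)
    eff_areas <- draw_area(p$n_effector_cells, p$effector_area_mean,
                           p$effector_area_sd)

    occupied <- matrix(FALSE, nr, nc)
    gel_x0 <- p$gel_interface_x
    L <- p$infiltration_decay_length
    draw_target_xy <- function() c(runif(1, gel_x0, p$field_size[1]),
                                   runif(1, 0, p$field_size[2]))
    # dead-target positions: uniform, or thinned toward the interface in
    # proportion to effector exposure exp(-depth/L)
    draw_dead_xy <- if (p$dead_placement == "uniform") draw_target_xy else
      function() {
        repeat {
          xy <- draw_target_xy()
          if (runif(1) < exp(-(xy[1] - gel_x0) / L)) return(xy)
        }
      }
    draw_effector_xy <- function() {
      repeat {
        d <- rexp(1, rate = 1 / L)
        if (gel_x0 + d <= p$field_size[1]) break
      }
      c(gel_x0 + d, runif(1, 0, p$field_size[2]))
    }
    # under "flux" seeding, each of the n_effector_cells at the face
    # attempts a uniform depth and enters only with probability
    # exp(-d/L); entrants get exponential depths, while blocked cells
    # pile up against the gel face (half-normal depth, 15-um scale, i.e.
    # inside R0) — a denser matrix then shows fewer cells at every
    # analysis depth and an accumulation at the boundary, as real dense
    # gels do
    n_eff <- p$n_effector_cells
    n_enter <- n_eff
    if (p$infiltration_mode == "flux" && n_eff > 0L) {
      d_try <- runif(n_eff, 0, p$field_size[1] - gel_x0)
      n_enter <- sum(runif(n_eff) < exp(-d_try / L))
    }
    draw_face_xy <- function() {
      repeat {
        d <- abs(rnorm(1, 0, 15))
        if (gel_x0 + d <= p$field_size[1]) break
      }
      c(gel_x0 + d, runif(1, 0, p$field_size[2]))
    }

    pl_live <- place_cells(n_live, draw_target_xy, live_areas,
                           p$live_axis_ratio, ps, nr, nc, occupied,
                           p$allow_overlap, "live target")
    pl_dead <- place_cells(n_dead, draw_dead_xy, dead_areas, 1, ps, nr, nc,
                           pl_live$occupied, p$allow_overlap, "dead target")
    pl_eff <- place_cells(n_enter, draw_effector_xy, eff_areas[seq_len(n_enter)],
                          1, ps, nr, nc, pl_dead$occupied, p$allow_overlap,
                          "effector")
    face_areas <- if (n_eff > n_enter) eff_areas[(n_enter + 1L):n_eff] else numeric()
    # blocked cells crowd and overlap in projection, as at a real gel face
    pl_face <- place_cells(n_eff - n_enter, draw_face_xy, face_areas, 1,
                           ps, nr, nc, pl_eff$occupied, TRUE, "face effector")

    all_cells <- c(pl_live$cells, pl_dead$cells, pl_eff$cells, pl_face$cells)
    types <- c(rep("target", p$n_target_cells), rep("effector", n_eff))
    states_all <- c(states, rep("live", n_eff))
    drawn <- c(live_areas, dead_areas, eff_areas)
    cells <- data.frame(
      cell_id = seq_along(all_cells),
      cell_type = types,
      state = states_all,
      x = vapply(all_cells, `[[`, 1.0, "x"),
      y = vapply(all_cells, `[[`, 1.0, "y"),
      drawn_area = drawn,
      rendered_area = vapply(all_cells, function(cl) nrow(cl$footprint) * ps^2, 1.0))
    cells$depth <- cells$x - p$gel_interface_x

    target_fp <- lapply(all_cells[types == "target"], `[[`, "footprint")
    dead_fp <- lapply(all_cells[types == "target" & states_all == "dead"],
                      `[[`, "footprint")
    eff_fp <- lapply(all_cells[types == "effector"], `[[`, "footprint")

    channels <- list(
      target = image_stack(render_channel(target_fp, nr, nc, p), ps,
                           channel = "target", bit_depth = p$bit_depth),
      effector = image_stack(render_channel(eff_fp, nr, nc, p), ps,
                             channel = "effector", bit_depth = p$bit_depth),
      dead_stain = image_stack(render_channel(dead_fp, nr, nc, p), ps,
                               channel = "dead_stain", bit_depth = p$bit_depth))

    truth <- build_ground_truth(cells, roi, p)
    list(channels = channels, truth = truth)
  })
}

# Count-based per-bin tallies from the cell table: effectors per bin and
# the true kill fraction (dead / all targets) per bin and pooled over the
# analysis bins.
build_ground_truth <- function(cells, roi, params) {
  bin_of <- function(depth) {
    b <- floor(depth / roi$bin_width)
    b[depth < 0 | depth >= roi$side_length] <- NA
    b
  }
  cells$bin <- bin_of(cells$depth)
  bins <- seq_len(roi$n_bins) - 1L
  eff <- cells[cells$cell_type == "effector" & !is.na(cells$bin), ]
  per_bin_eff <- vapply(bins, function(b) sum(eff$bin == b), 1.0)
  names(per_bin_eff) <- roi$bin_labels
  tgt <- cells[cells$cell_type == "target" & !is.na(cells$bin), ]
  pk_bin <- vapply(bins, function(b) {
    n <- sum(tgt$bin == b)
    if (n == 0) NA_real_ else 100 * sum(tgt$bin == b & tgt$state == "dead") / n
  }, 1.0)
  names(pk_bin) <- roi$bin_labels
  in_analysis <- tgt$bin %in% roi$analysis_bins
  pk_overall <- if (!any(in_analysis)) NA_real_ else
    100 * sum(tgt$state[in_analysis] == "dead") / sum(in_analysis)
  structure(list(cells = cells,
                 per_bin_effector_count = per_bin_eff,
                 true_percent_killed = pk_bin,
                 true_percent_killed_overall = pk_overall,
                 roi = roi, params = params),
            class = "GroundTruth")
}

#' Self-consistent calibration from scene ground truth
#'
#' Builds a [calibrate()] object from the rendered single-cell areas in a
#' scene's ground truth, mimicking a perfect manual calibration on the
#' same imaging system. Uses dead-area parameters from the generator when
#' the scene contains no dead cells.
#'
#' @param truth a `GroundTruth` from [generate_scene()].
#' @return a `CellCalibration`.
#' @export
calibrate_from_truth <- function(truth) {
  stopifnot(inherits(truth, "GroundTruth"))
  cells <- truth$cells
  eff <- cells$rendered_area[cells$cell_type == "effector"]
  liv <- cells$rendered_area[cells$cell_type == "target" & cells$state == "live"]
  ded <- cells$rendered_area[cells$cell_type == "target" & cells$state == "dead"]
  p <- truth$params
  if (!length(eff)) eff <- p$effector_area_mean
  if (!length(liv)) liv <- p$live_area_mean
  if (!length(ded)) ded <- p$dead_area_mean
  calibrate(eff, liv, ded)
}

#' Write / read ground-truth and event tables
#'
#' Cell tables (`GroundTruth$cells`) and kill-event logs round-trip
#' losslessly through plain CSV; an empty event list writes a header-only
#' file the reader accepts.
#'
#' @param truth a `GroundTruth`, or a data frame (cell or event table).
#' @param path CSV destination.
#' @return `write_truth` returns `path` invisibly; `read_truth` the data
#'   frame.
#' @export
write_truth <- function(truth, path) {
  tab <- if (inherits(truth, "GroundTruth")) truth$cells else truth
  if (!is.data.frame(tab)) stopf("'truth' must be a GroundTruth or data frame")
  ok <- tryCatch({ write.csv(tab, path, row.names = FALSE); TRUE },
                 error = function(e) e, warning = function(w) w)
  if (!isTRUE(ok))
    stopf("I/O error writing '%s': %s", path, conditionMessage(ok))
  invisible(path)
}

#' @rdname write_truth
#' @export
read_truth <- function(path) {
  if (!file.exists(path)) stopf("file not found: '%s'", path)
  read.csv(path, stringsAsFactors = FALSE)
}
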