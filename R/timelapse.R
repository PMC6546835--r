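#' Parameters for a synthetic kill-kinetics time-lapse
#'
#' Extends [scene_params()] with the temporal model: effectors perform a
#' reflected Gaussian random walk; when an effector first comes within
#' `contact_distance` of a live target (edge-to-edge, using equivalent
#' circular radii), a kill occurs with probability
#' `kill_probability_per_contact`. A killed target switches from the
#' extended (ellipse) to the rounded (disc) morphology `rounding_delay`
#' frames after contact, and its dead-stain signal turns on at
#' `contact_time` plus a truncated-normal delay — emulating the observed
#' contact, rounding, then dye-uptake sequence. Targets are stationary
#' (they are embedded in the gel); each target can be killed at most once,
#' and an effector that fails its kill draw never re-attempts that target
#' (another effector still can).
#'
#' Time-lapse defaults describe a smaller, denser field than the endpoint
#' scene so that contacts actually happen within a short recording:
#' 250 x 250 um, 20 live targets, 12 effectors placed uniformly
#' (`infiltration_decay_length = 1e6`), 10-min frames for 24 frames (4 h),
#' 6-um steps, 4-um contact distance, kill probability 0.6, and a PI
#' delay of 40 +/- 10 min.
#'
#' @param ... overrides for the [scene_params()] fields.
#' @param frame_interval minutes between frames (> 0).
#' @param n_frames number of frames (>= 2).
#' @param effector_step_sd random-walk step sd, um per frame per axis.
#' @param contact_distance edge-to-edge contact threshold in um; must be
#'   at least one pixel.
#' @param kill_probability_per_contact probability in `[0, 1]`.
#' @param rounding_delay frames from contact to rounded morphology.
#' @param pi_delay_mean,pi_delay_sd minutes from contact to dead-stain
#'   onset (normal, truncated > 0; `sd = 0` gives exactly the mean).
#' @return an object of class `TimeLapseParams` (also a `SceneParams`).
#' @export
timelapse_params <- function(..., frame_interval = 10, n_frames = 24L,
                             effector_step_sd = 6, contact_distance = 4,
                             kill_probability_per_contact = 0.6,
                             rounding_delay = 1L,
                             pi_delay_mean = 40, pi_delay_sd = 10) {
  scene_defaults <- list(field_size = c(250, 250), n_target_cells = 20L,
                         dead_fraction = 0, n_effector_cells = 12L,
                         infiltration_decay_length = 1e6)
  dots <- list(...)
  unknown <- setdiff(names(dots), names(formals(scene_params)))
  if (length(unknown))
    stopf("unknown scene parameter(s): %s", paste(unknown, collapse = ", "))
  sp <- do.call(scene_params, modifyList(scene_defaults, dots))
  check_number(frame_interval, "frame_interval", lower = 0, allow_equal_lower = FALSE)
  if (n_frames < 2L) stopf("'n_frames' must be >= 2")
  check_number(effector_step_sd, "effector_step_sd", lower = 0)
  if (contact_distance < sp$pixel_size)
    stopf("configuration error: contact_distance (%g um) is smaller than one pixel (%g um)",
          contact_distance, sp$pixel_size)
  check_number(kill_probability_per_contact, "kill_probability_per_contact",
               lower = 0, upper = 1)
  if (rounding_delay < 0L) stopf("'rounding_delay' must be >= 0")
  check_number(pi_delay_mean, "pi_delay_mean", lower = 0, allow_equal_lower = FALSE)
  check_number(pi_delay_sd, "pi_delay_sd", lower = 0)
  p <- c(unclass(sp),
         list(frame_interval = frame_interval, n_frames = as.integer(n_frames),
              effector_step_sd = effector_step_sd,
              contact_distance = contact_distance,
              kill_probability_per_contact = kill_probability_per_contact,
              rounding_delay = as.integer(rounding_delay),
              pi_delay_mean = pi_delay_mean, pi_delay_sd = pi_delay_sd))
  structure(p, class = c("TimeLapseParams", "SceneParams"))
}

draw_pi_delay <- function(mean, sd) {
  if (sd == 0) return(mean)
  repeat {
    d <- rnorm(1, mean, sd)
    if (d > 0) return(d)
  }
}

#' Generate a synthetic time-lapse with a kill-event log
#'
#' Runs the temporal model of [timelapse_params()] and renders each frame
#' as three single-plane channels. Every kill is logged as one event with
#' the exact (continuous) contact and dead-stain onset times; the stain is
#' rendered from the first frame at or after its onset time, and the
#' rounded morphology from `rounding_delay` frames after contact.
#'
#' @param params a [timelapse_params()].
#' @return a list with `timelapse` (a [time_lapse()]), `events` (data
#'   frame: `effector_id`, `target_id`, `contact_time`, `pi_time`,
#'   `time_for_killing`, minutes), and `cells` (the initial cell table).
#' @export
generate_timelapse <- function(params) {
  stopifnot(inherits(params, "TimeLapseParams"))
  p <- params
  ps <- p$pixel_size
  nc <- as.integer(round(p$field_size[1] / ps))
  nr <- as.integer(round(p$field_size[2] / ps))

  with_seed_(p$seed, {
    n_dead0 <- as.integer(round(p$n_target_cells * p$dead_fraction))
    n_live0 <- p$n_target_cells - n_dead0
    tgt_state <- c(rep("live", n_live0), rep("dead", n_dead0))
    tgt_area_live <- draw_area(p$n_target_cells, p$live_area_mean, p$live_area_sd)
    tgt_area_dead <- draw_area(p$n_target_cells, p$dead_area_mean, p$dead_area_sd)
    eff_area <- draw_area(p$n_effector_cells, p$effector_area_mean,
                          p$effector_area_sd)
    tgt_theta <- runif(p$n_target_cells, 0, pi)

    # initial non-overlapping placement (same scheme as the endpoint scene)
    occupied <- matrix(FALSE, nr, nc)
    gel_x0 <- p$gel_interface_x
    draw_xy <- function() c(runif(1, gel_x0, p$field_size[1]),
                            runif(1, 0, p$field_size[2]))
    draw_eff_xy <- function() {
      repeat {
        d <- rexp(1, rate = 1 / p$infiltration_decay_length)
        if (gel_x0 + d <= p$field_size[1]) break
      }
      c(gel_x0 + d, runif(1, 0, p$field_size[2]))
    }
    pl_t <- place_cells(p$n_target_cells, draw_xy, tgt_area_live,
                        p$live_axis_ratio, ps, nr, nc, occupied, FALSE, "target")
    pl_e <- place_cells(p$n_effector_cells, draw_eff_xy, eff_area, 1, ps, nr,
                        nc, pl_t$occupied, FALSE, "effector")
    tgt_x <- vapply(pl_t$cells, `[[`, 1.0, "x")
    tgt_y <- vapply(pl_t$cells, `[[`, 1.0, "y")
    eff_x <- vapply(pl_e$cells, `[[`, 1.0, "x")
    eff_y <- vapply(pl_e$cells, `[[`, 1.0, "y")

    r_eff <- sqrt(eff_area / pi)

    killed <- tgt_state == "dead"       # pre-existing dead cells
    contact_time <- rep(NA_real_, p$n_target_cells)
    pi_time <- ifelse(killed, 0, NA_real_)  # pre-dead: stain on from t=0
    round_frame <- ifelse(killed, 0L, NA_integer_)
    attempted <- matrix(FALSE, p$n_effector_cells, max(1L, p$n_target_cells))
    # a killing effector docks at its target (immunological synapse) and
    # holds position until dye uptake, then resumes its walk
    docked_to <- rep(NA_integer_, p$n_effector_cells)
    dock_dir <- matrix(0, p$n_effector_cells, 2)
    events <- list()

    frames <- vector("list", p$n_frames)
    timestamps <- (seq_len(p$n_frames) - 1L) * p$frame_interval

    for (f in seq_len(p$n_frames)) {
      t_now <- timestamps[f]
      if (f > 1L && p$n_effector_cells > 0L) {
        # undock effectors whose target has taken up the dye by now
        done <- !is.na(docked_to) & t_now >= pi_time[docked_to]
        docked_to[done] <- NA_integer_
        free <- is.na(docked_to)
        step_x <- rnorm(p$n_effector_cells, 0, p$effector_step_sd)
        step_y <- rnorm(p$n_effector_cells, 0, p$effector_step_sd)
        eff_x[free] <- reflect_into(eff_x[free] + step_x[free], gel_x0,
                                    p$field_size[1])
        eff_y[free] <- reflect_into(eff_y[free] + step_y[free], 0,
                                    p$field_size[2])
      }
      # contact + kill draws (deterministic order: target, then effector)
      for (j in seq_len(p$n_target_cells)) {
        if (killed[j]) next
        for (i in seq_len(p$n_effector_cells)) {
          if (attempted[i, j] || !is.na(docked_to[i])) next
          dx <- eff_x[i] - tgt_x[j]; dy <- eff_y[i] - tgt_y[j]
          # edge-to-edge distance against the actual ellipse outline, so
          # logged contact agrees with when the rendered masks meet
          r_t <- ellipse_radius_at(tgt_area_live[j], p$live_axis_ratio,
                                   tgt_theta[j], atan2(dy, dx))
          gap <- sqrt(dx^2 + dy^2) - r_eff[i] - r_t
          if (gap > p$contact_distance) next
          attempted[i, j] <- TRUE
          if (p$kill_probability_per_contact > 0 &&
              runif(1) <= p$kill_probability_per_contact) {
            killed[j] <- TRUE
            contact_time[j] <- t_now
            delay <- draw_pi_delay(p$pi_delay_mean, p$pi_delay_sd)
            pi_time[j] <- t_now + delay
            round_frame[j] <- f + p$rounding_delay
            docked_to[i] <- j
            nrm <- sqrt(dx^2 + dy^2)
            dock_dir[i, ] <- if (nrm > 0) c(dx, dy) / nrm else c(1, 0)
            events[[length(events) + 1L]] <- data.frame(
              effector_id = i, target_id = j,
              contact_time = t_now, pi_time = pi_time[j],
              time_for_killing = delay)
            break
          }
        }
      }
      # keep docked effectors flush against their target's current outline
      # (slight overlap so the rendered masks are guaranteed to touch)
      for (i in which(!is.na(docked_to))) {
        j <- docked_to[i]
        rounded <- !is.na(round_frame[j]) && f >= round_frame[j]
        r_t <- if (rounded) sqrt(tgt_area_dead[j] / pi) else
          ellipse_radius_at(tgt_area_live[j], p$live_axis_ratio, tgt_theta[j],
                            atan2(dock_dir[i, 2], dock_dir[i, 1]))
        d <- max(r_t + r_eff[i] - ps, 0)
        eff_x[i] <- min(max(tgt_x[j] + dock_dir[i, 1] * d, 0), p$field_size[1])
        eff_y[i] <- min(max(tgt_y[j] + dock_dir[i, 2] * d, 0), p$field_size[2])
      }
      frames[[f]] <- render_timelapse_frame(
        p, nr, nc, f, t_now, tgt_x, tgt_y, tgt_theta, tgt_area_live,
        tgt_area_dead, tgt_state, killed, round_frame, pi_time, eff_x, eff_y,
        eff_area)
    }

    ev <- if (length(events)) do.call(rbind, events) else
      data.frame(effector_id = integer(), target_id = integer(),
                 contact_time = numeric(), pi_time = numeric(),
                 time_for_killing = numeric())
    cells <- data.frame(
      cell_id = seq_len(p$n_target_cells + p$n_effector_cells),
      cell_type = c(rep("target", p$n_target_cells),
                    rep("effector", p$n_effector_cells)),
      state = c(tgt_state, rep("live", p$n_effector_cells)),
      x = c(tgt_x, eff_x), y = c(tgt_y, eff_y))
    list(timelapse = time_lapse(frames, timestamps), events = ev,
         cells = cells)
  })
}

# distance from an ellipse's centre to its outline along world angle phi
ellipse_radius_at <- function(area, axis_ratio, theta, phi) {
  a <- sqrt(area * axis_ratio / pi)
  b <- sqrt(area / (axis_ratio * pi))
  ang <- phi - theta
  a * b / sqrt((b * cos(ang))^2 + (a * sin(ang))^2)
}

reflect_into <- function(x, lo, hi) {
  w <- hi - lo
  x <- (x - lo) %% (2 * w)
  lo + ifelse(x > w, 2 * w - x, x)
}

render_timelapse_frame <- function(p, nr, nc, f, t_now, tgt_x, tgt_y,
                                   tgt_theta, area_live, area_dead, state0,
                                   killed, round_frame, pi_time, eff_x, eff_y,
                                   eff_area) {
  ps <- p$pixel_size
  n_t <- length(tgt_x)
  tgt_fp <- vector("list", n_t)
  dead_fp <- list()
  for (j in seq_len(n_t)) {
    rounded <- killed[j] && !is.na(round_frame[j]) && f >= round_frame[j]
    fp <- if (rounded)
      cell_footprint(tgt_x[j], tgt_y[j], area_dead[j], 1, 0, ps, nr, nc,
                     clip = TRUE)
    else
      cell_footprint(tgt_x[j], tgt_y[j], area_live[j], p$live_axis_ratio,
                     tgt_theta[j], ps, nr, nc, clip = TRUE)
    tgt_fp[[j]] <- fp
    if (killed[j] && !is.na(pi_time[j]) && t_now >= pi_time[j])
      dead_fp[[length(dead_fp) + 1L]] <- fp
  }
  eff_fp <- lapply(seq_along(eff_x), function(i)
    cell_footprint(eff_x[i], eff_y[i], eff_area[i], 1, 0, ps, nr, nc,
                   clip = TRUE))
  list(
    target = image_stack(render_channel(tgt_fp, nr, nc, p), ps,
                         channel = "target", bit_depth = p$bit_depth),
    effector = image_stack(render_channel(eff_fp, nr, nc, p), ps,
                           channel = "effector", bit_depth = p$bit_depth),
    dead_stain = image_stack(render_channel(dead_fp, nr, nc, p), ps,
                             channel = "dead_stain", bit_depth = p$bit_depth))
}
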