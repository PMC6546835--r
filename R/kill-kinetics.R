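#' Segment every frame of one time-lapse channel
#'
#' Applies the mean auto-threshold to each frame independently and labels
#' components, yielding the per-frame `ComponentSet`s that tracking
#' consumes.
#'
#' @param tl a [time_lapse()].
#' @param channel `"target"`, `"effector"`, or `"dead_stain"`.
#' @param min_area minimum component area in um^2 (see
#'   [label_components()]).
#' @return list of `ComponentSet`, one per frame.
#' @export
segment_frames <- function(tl, channel, min_area = 25) {
  stopifnot(inherits(tl, "TimeLapse"))
  lapply(tl$frames, function(f) {
    img <- despeckle(z_project(f[[channel]], "max"))
    label_components(to_mask(img), min_area = min_area)
  })
}

#' Link per-frame components into tracks
#'
#' Greedy nearest-centroid linking: at each frame, (active track,
#' component) pairs are matched in order of increasing centroid distance,
#' accepting a pair only when the distance is at most `max_step` and
#' neither side is taken; ties are broken by lowest track id then lowest
#' component label, so linking is deterministic. Unmatched components
#' start new tracks; unmatched tracks are closed (tracks are contiguous in
#' time, no gap closing).
#'
#' @param component_sets list of [label_components()] results, one per
#'   frame, time-ordered.
#' @param timestamps frame times in minutes.
#' @param max_step maximum centroid displacement (um) per frame.
#' @return an object of class `TrackSet`: list with `tracks` (data frame:
#'   `track_id`, `frame`, `label`, `x`, `y`), `timestamps`, and
#'   `component_sets` (kept for mask lookups).
#' @export
link_tracks <- function(component_sets, timestamps, max_step) {
  if (length(component_sets) != length(timestamps))
    stopf("'component_sets' and 'timestamps' lengths differ")
  check_number(max_step, "max_step", lower = 0, allow_equal_lower = FALSE)
  rows <- list()
  active <- data.frame(track_id = integer(), x = numeric(), y = numeric())
  next_id <- 1L
  for (f in seq_along(component_sets)) {
    tab <- component_sets[[f]]$table
    taken_comp <- logical(nrow(tab))
    matched_track <- logical(nrow(active))
    if (nrow(active) && nrow(tab)) {
      d <- outer(active$x, tab$x, "-")^2 + outer(active$y, tab$y, "-")^2
      cand <- which(d <= max_step^2, arr.ind = TRUE)
      if (nrow(cand)) {
        ord <- order(d[cand], active$track_id[cand[, 1]], tab$label[cand[, 2]])
        for (k in ord) {
          i <- cand[k, 1]; j <- cand[k, 2]
          if (matched_track[i] || taken_comp[j]) next
          matched_track[i] <- TRUE
          taken_comp[j] <- TRUE
          rows[[length(rows) + 1L]] <- data.frame(
            track_id = active$track_id[i], frame = f, label = tab$label[j],
            x = tab$x[j], y = tab$y[j])
        }
      }
    }
    new_idx <- which(!taken_comp)
    for (j in new_idx) {
      rows[[length(rows) + 1L]] <- data.frame(
        track_id = next_id, frame = f, label = tab$label[j],
        x = tab$x[j], y = tab$y[j])
      next_id <- next_id + 1L
    }
    # heads for the next frame: everything matched or newly started now
    this_frame <- do.call(rbind, rows[vapply(rows, function(r) r$frame == f, TRUE)])
    active <- data.frame(track_id = this_frame$track_id,
                         x = this_frame$x, y = this_frame$y)
  }
  tracks <- if (length(rows)) do.call(rbind, rows) else
    data.frame(track_id = integer(), frame = integer(), label = integer(),
               x = numeric(), y = numeric())
  tracks <- tracks[order(tracks$track_id, tracks$frame), ]
  rownames(tracks) <- NULL
  structure(list(tracks = tracks, timestamps = timestamps,
                 component_sets = component_sets),
            class = "TrackSet")
}

track_rows <- function(trackset, id) {
  trackset$tracks[trackset$tracks$track_id == id, , drop = FALSE]
}

component_pixels <- function(component_set, label) {
  component_set$labels == label
}

#' First effector-target contact time
#'
#' Contact is operationalized as mask adjacency: the first frame in which
#' the effector component, dilated by `contact_dilation` pixels, shares a
#' pixel with the target component. Returns that frame's timestamp, or
#' `NA` if the tracks never touch.
#'
#' @param effector_tracks,target_tracks [link_tracks()] results for the
#'   effector and target channels (sharing frames/timestamps).
#' @param effector_id,target_id track ids.
#' @param contact_dilation dilation radius in pixels (Chebyshev); default 1.
#' @return contact time in minutes, or `NA_real_`.
#' @export
detect_contact <- function(effector_tracks, target_tracks, effector_id,
                           target_id, contact_dilation = 1L) {
  prof <- contact_profile(effector_tracks, target_tracks, effector_id,
                          target_id, contact_dilation)
  hit <- which(prof$touching)
  if (!length(hit)) NA_real_ else prof$time[hit[1]]
}

# Per-frame mask-adjacency profile for one effector/target track pair:
# data frame of (frame, time, touching) over the frames both tracks exist.
contact_profile <- function(effector_tracks, target_tracks, effector_id,
                            target_id, contact_dilation = 1L) {
  stopifnot(inherits(effector_tracks, "TrackSet"),
            inherits(target_tracks, "TrackSet"))
  te <- track_rows(effector_tracks, effector_id)
  tt <- track_rows(target_tracks, target_id)
  common <- sort(intersect(te$frame, tt$frame))
  touching <- vapply(common, function(f) {
    ep <- component_pixels(effector_tracks$component_sets[[f]],
                           te$label[te$frame == f])
    tp <- component_pixels(target_tracks$component_sets[[f]],
                           tt$label[tt$frame == f])
    any(.dilate_square_cpp(ep, as.integer(contact_dilation)) & tp)
  }, TRUE)
  data.frame(frame = common,
             time = effector_tracks$timestamps[common],
             touching = touching)
}

#' First sustained dead-stain uptake on a target track
#'
#' Uptake is called at the first frame where the dead-stain foreground
#' covers at least `onset_fraction` of the target component and keeps
#' doing so for `persistence` consecutive frames — a short persistence
#' requirement rejects single-frame bleed-through flicker.
#'
#' @param target_tracks a [link_tracks()] result for the target channel.
#' @param target_id track id.
#' @param dead_masks list of [binary_mask()]s (dead-stain channel), one
#'   per frame.
#' @param onset_fraction overlap fraction in `[0, 1]`; default 0.3.
#' @param persistence required consecutive frames; default 2.
#' @return uptake time in minutes, or `NA_real_`.
#' @export
detect_pi_uptake <- function(target_tracks, target_id, dead_masks,
                             onset_fraction = 0.3, persistence = 2L) {
  stopifnot(inherits(target_tracks, "TrackSet"))
  check_number(onset_fraction, "onset_fraction", lower = 0, upper = 1)
  if (persistence < 1L) stopf("'persistence' must be >= 1")
  tt <- track_rows(target_tracks, target_id)
  frames <- tt$frame
  above <- vapply(seq_along(frames), function(k) {
    f <- frames[k]
    cs <- target_tracks$component_sets[[f]]
    px <- component_pixels(cs, tt$label[k])
    mean(dead_masks[[f]]$pixels[px]) >= onset_fraction
  }, TRUE)
  if (length(above) < persistence) return(NA_real_)
  runs <- rle(above)
  pos <- cumsum(c(1L, runs$lengths))
  hit <- which(runs$values & runs$lengths >= persistence)
  if (!length(hit)) return(NA_real_)
  target_tracks$timestamps[frames[pos[hit[1]]]]
}

#' Time for killing
#'
#' The per-event interval from first effector-target contact to target
#' dead-stain uptake, in minutes.
#'
#' @param contact_time,pi_time minutes (numbers, or `"HH:MM"` strings
#'   parsed via [parse_timestamp()]).
#' @return minutes (> 0).
#' @export
#' @examples
#' time_for_killing("01:00", "01:45")  # 45
time_for_killing <- function(contact_time, pi_time) {
  if (is.character(contact_time)) contact_time <- parse_timestamp(contact_time)
  if (is.character(pi_time)) pi_time <- parse_timestamp(pi_time)
  if (anyNA(contact_time) || anyNA(pi_time))
    stopf("both contact and uptake times must be defined")
  if (any(pi_time <= contact_time))
    stopf(paste0("event-ordering error: dead-stain uptake at or before contact ",
                 "(check track linking)"))
  pi_time - contact_time
}

#' Extract kill events from a synthetic or real time-lapse
#'
#' End-to-end kinetics: segments the target, effector, and dead-stain
#' channels frame by frame, links tracks per channel, detects sustained
#' dead-stain uptake on each target track, and attributes each uptake to
#' the effector track with the earliest mask contact before uptake. Only
#' events with both contact and uptake observed inside the recording
#' window are reported.
#'
#' @param tl a [time_lapse()].
#' @param max_step tracking search radius in um per frame.
#' @param min_area component area filter in um^2.
#' @param contact_dilation see [detect_contact()].
#' @param onset_fraction,persistence see [detect_pi_uptake()].
#' @return data frame with one row per event: `effector_track_id`,
#'   `target_track_id`, `contact_time`, `pi_time`, `time_for_killing`
#'   (minutes).
#' @export
extract_kill_events <- function(tl, max_step = 20, min_area = 25,
                                contact_dilation = 1L, onset_fraction = 0.3,
                                persistence = 2L) {
  stopifnot(inherits(tl, "TimeLapse"))
  tgt_cs <- segment_frames(tl, "target", min_area)
  eff_cs <- segment_frames(tl, "effector", min_area)
  # One dead-channel threshold for the whole recording, computed on the
  # temporal max-projection: per-frame mean thresholds collapse on frames
  # recorded before any dye uptake (a signal-free frame's mean sits at the
  # background level, calling half the noise foreground), whereas the
  # max-projection contains every pixel that is ever stained.
  dead_imgs <- lapply(tl$frames, function(f)
    despeckle(z_project(f$dead_stain, "max")))
  dead_tmax <- Reduce(pmax, dead_imgs)
  thr <- mean_threshold(dead_tmax)
  dead_masks <- lapply(dead_imgs, to_mask, threshold = thr)
  tgt_tr <- link_tracks(tgt_cs, tl$timestamps, max_step)
  eff_tr <- link_tracks(eff_cs, tl$timestamps, max_step)

  events <- list()
  for (tid in unique(tgt_tr$tracks$track_id)) {
    uptake <- detect_pi_uptake(tgt_tr, tid, dead_masks, onset_fraction,
                               persistence)
    if (is.na(uptake)) next
    # Attribute the kill to the effector still in contact when the dye
    # comes up (the killer stays conjugated to its victim through lysis),
    # not to whichever cell brushed the target first: bystander effectors
    # can touch and move on long before the lethal contact. The event's
    # contact time is the killer's own first contact.
    best <- NULL
    for (eid in unique(eff_tr$tracks$track_id)) {
      touch <- contact_profile(eff_tr, tgt_tr, eid, tid, contact_dilation)
      touch <- touch[touch$time < uptake, , drop = FALSE]
      hits <- which(touch$touching)
      if (!length(hits)) next
      # length of the contiguous touching run ending at the last touch:
      # the conjugated killer touches without interruption until lysis,
      # a passing bystander only transiently
      run_end <- hits[length(hits)]
      run_len <- 1L
      while (run_end - run_len >= 1L && touch$touching[run_end - run_len])
        run_len <- run_len + 1L
      # the event's contact time is the onset of this final run: the
      # killer conjugates at its lethal contact and stays put, whereas
      # counting from an earlier transient brush (own or after a track
      # merge) would overstate the killing time
      cand <- list(eid = eid, first = touch$time[run_end - run_len + 1L],
                   last = touch$time[run_end], run = run_len)
      if (is.null(best) || cand$last > best$last ||
          (cand$last == best$last && cand$run > best$run) ||
          (cand$last == best$last && cand$run == best$run &&
             cand$first < best$first)) best <- cand
    }
    if (is.null(best)) next
    events[[length(events) + 1L]] <- data.frame(
      effector_track_id = best$eid, target_track_id = tid,
      contact_time = best$first, pi_time = uptake,
      time_for_killing = uptake - best$first)
  }
  if (length(events)) do.call(rbind, events) else
    data.frame(effector_track_id = integer(), target_track_id = integer(),
               contact_time = numeric(), pi_time = numeric(),
               time_for_killing = numeric())
}

#' Compare time-for-killing between two conditions
#'
#' Classical unpaired two-tailed Student's t-test with pooled variance
#' (`df = n_a + n_b - 2`), the convention for comparing per-event killing
#' times between conditions. No direction is assumed; the signed t
#' statistic and both group means are reported.
#'
#' @param times_a,times_b numeric vectors (>= 2 values each), minutes.
#' @param labels optional length-2 character vector of group labels.
#' @return an object of class `GroupComparison`: list with `labels`, `n`,
#'   `means`, `t_statistic`, `df`, `p_value`.
#' @export
#' @examples
#' compare_groups(c(1, 2, 3), c(4, 5, 6))  # t = -3.674, df = 4, p = 0.021
compare_groups <- function(times_a, times_b, labels = c("a", "b")) {
  if (length(times_a) < 2L || length(times_b) < 2L)
    stopf("sample-size error: each group needs at least 2 values")
  na <- length(times_a); nb <- length(times_b)
  sp2 <- ((na - 1) * stats::var(times_a) + (nb - 1) * stats::var(times_b)) /
    (na + nb - 2)
  se <- sqrt(sp2 * (1 / na + 1 / nb))
  t_stat <- if (se == 0) 0 else (mean(times_a) - mean(times_b)) / se
  df <- na + nb - 2
  p <- 2 * pt(-abs(t_stat), df)
  structure(list(labels = labels, n = c(na, nb),
                 means = c(mean(times_a), mean(times_b)),
                 t_statistic = t_stat, df = df, p_value = p),
            class = "GroupComparison")
}

#' @export
print.GroupComparison <- function(x, ...) {
  stars <- if (x$p_value < 0.001) "***" else if (x$p_value < 0.01) "**"
    else if (x$p_value < 0.05) "*" else "ns"
  cat(sprintf("Student's t-test (pooled variance, two-tailed): %s (n=%d, mean %.2f) vs %s (n=%d, mean %.2f)\n  t = %.4f, df = %d, p = %.4g %s\n",
              x$labels[1], x$n[1], x$means[1], x$labels[2], x$n[2], x$means[2],
              x$t_statistic, x$df, x$p_value, stars))
  invisible(x)
}
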