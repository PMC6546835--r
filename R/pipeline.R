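#' Default pipeline configuration
#'
#' @return a plain list of defaults; see [validate_config()] for the
#'   documented keys and domains.
#' @export
default_config <- function() {
  list(
    mode = "simulate",
    seed = 1L,
    output_dir = "cytotox3d-out",
    replicates = 3L,
    scene = list(),                 # overrides for scene_params()
    conditions = NULL,              # named list of per-condition overrides
    roi = list(side_length = 700, bin_width = 100),
    timelapse = NULL,               # overrides for timelapse_params(), or NULL
    thresholds = list(overlap_fraction = 0.5, onset_fraction = 0.3,
                      persistence = 2L, contact_dilation = 1L,
                      min_area = 25, max_step = 20),
    write_masks = TRUE)
}

threshold_domains <- list(
  overlap_fraction = c(0, 1), onset_fraction = c(0, 1),
  persistence = c(1, Inf), contact_dilation = c(0, Inf),
  min_area = c(0, Inf), max_step = c(1e-12, Inf))

#' Validate and complete a pipeline configuration
#'
#' Accepts a YAML/JSON file path, a YAML string, or a list; fills
#' defaults, checks every threshold against its documented domain, and
#' rejects unknown keys by name. The echoed configuration includes the
#' derived bin count (`roi$n_bins`).
#'
#' @param config path, YAML text, or list.
#' @return an object of class `PipelineConfig` (a completed list).
#' @export
validate_config <- function(config) {
  if (is.character(config) && length(config) == 1L) {
    config <- if (file.exists(config)) yaml::read_yaml(config)
      else yaml::yaml.load(config)
  }
  if (is.null(config)) config <- list()
  if (!is.list(config)) stopf("config must be a file path, YAML text, or list")
  defaults <- default_config()
  unknown <- setdiff(names(config), names(defaults))
  if (length(unknown))
    stopf("unknown config key(s): %s", paste(unknown, collapse = ", "))
  cfg <- modifyList(defaults, config)

  unknown_thr <- setdiff(names(cfg$thresholds), names(threshold_domains))
  if (length(unknown_thr))
    stopf("unknown threshold key(s): %s", paste(unknown_thr, collapse = ", "))
  for (nm in names(threshold_domains)) {
    dom <- threshold_domains[[nm]]
    v <- cfg$thresholds[[nm]]
    if (!is.numeric(v) || length(v) != 1L || v < dom[1] || v > dom[2])
      stopf("config key 'thresholds.%s' = %s outside allowed range [%g, %g]",
            nm, format(v), dom[1], dom[2])
  }
  if (!is.numeric(cfg$seed) || abs(cfg$seed) >= 2^31)
    stopf("config key 'seed' must be a 32-bit integer")
  if (cfg$replicates < 1L) stopf("config key 'replicates' must be >= 1")
  # resolving the ROI here both validates it and echoes n_bins (dropped
  # first so an already-validated config revalidates cleanly)
  roi <- do.call(make_roi, cfg$roi[setdiff(names(cfg$roi), "n_bins")])
  cfg$roi$n_bins <- roi$n_bins
  if (!is.null(cfg$conditions) &&
      (!is.list(cfg$conditions) || is.null(names(cfg$conditions))))
    stopf("config key 'conditions' must be a named list of scene overrides")
  cfg$seed <- as.integer(cfg$seed)
  cfg$replicates <- as.integer(cfg$replicates)
  structure(cfg, class = "PipelineConfig")
}

scene_for <- function(cfg, overrides, seed) {
  args <- modifyList(cfg$scene, as.list(overrides))
  args$seed <- seed
  do.call(scene_params, args)
}

#' Quantify one endpoint scene
#'
#' Segment (mean threshold per channel), classify targets live/dead by
#' dead-stain overlap, calibrate from ground truth, and profile: the
#' single-scene core that [run_pipeline()] repeats over conditions and
#' replicates. Works equally as the degenerate single-region (2D well)
#' case when the ROI has one bin.
#'
#' @param scene a [generate_scene()] result.
#' @param roi a [make_roi()]; defaults to the scene truth's ROI.
#' @param thresholds list with `overlap_fraction` and `min_area`
#'   (see [default_config()]).
#' @param calibration a [calibrate()] result; defaults to
#'   [calibrate_from_truth()].
#' @param condition,replicate labels passed through to the profile.
#' @return list with `profile` ([profile_subregions()]), `overall`
#'   (pooled percent killed over the analysis bins, `NA` if no target area
#'   there), `calibration`, and the channel masks.
#' @export
quantify_scene <- function(scene, roi = NULL,
                           thresholds = default_config()$thresholds,
                           calibration = NULL, condition = "default",
                           replicate = 1L) {
  if (is.null(roi)) roi <- scene$truth$roi
  if (is.null(calibration)) calibration <- calibrate_from_truth(scene$truth)
  min_area <- thresholds$min_area
  if (is.null(min_area)) min_area <- 0.25 * calibration$mean_effector_area
  # Speckle suppression on every counted channel: despeckle (3x3 median)
  # before thresholding, open after (ragged correlated-noise blobs), then
  # drop sub-cellular components; isolated noise above the mean threshold
  # otherwise inflates the area-derived counts. A signal-free channel is
  # the mean threshold's degenerate case — the cutoff lands on the
  # background level and marks ~half the noise as foreground — so a mask
  # claiming over a quarter of the field is read as "no signal".
  channel_mask <- function(stack) {
    m <- binary_open(to_mask(despeckle(z_project(stack, "max"))))
    if (mean(m$pixels) > 0.25)
      m <- binary_mask(matrix(FALSE, nrow(m$pixels), ncol(m$pixels)),
                       m$pixel_size)
    m
  }
  eff_comp <- label_components(channel_mask(scene$channels$effector),
                               min_area = min_area)
  eff_mask <- binary_mask(eff_comp$labels > 0L, eff_comp$pixel_size)
  tgt_comp <- label_components(channel_mask(scene$channels$target),
                               min_area = min_area)
  dead_mask <- channel_mask(scene$channels$dead_stain)
  cls <- classify_dead(tgt_comp, dead_mask, thresholds$overlap_fraction)
  prof <- profile_subregions(eff_mask, cls$live_mask, cls$dead_mask, roi,
                             calibration, condition, replicate)
  overall <- tryCatch(
    overall_percent_killed(cls$live_mask, cls$dead_mask, roi, calibration),
    error = function(e) NA_real_)
  list(profile = prof, overall = overall, calibration = calibration,
       masks = list(effector = eff_mask, live = cls$live_mask,
                    dead = cls$dead_mask))
}

write_mask_tiff <- function(mask, path) {
  img <- matrix(ifelse(mask$pixels, 255L, 0L), nrow(mask$pixels))
  write_stack(image_stack(img, mask$pixel_size, bit_depth = 8L), path)
}

#' Run the full assay pipeline
#'
#' simulate -> segment -> quantify -> profile -> (optionally) kinetics ->
#' report, with every stage seeded from the configuration so re-running an
#' identical config reproduces identical tables. Per condition and
#' replicate, a scene is generated with seed
#' `seed + 1000 * condition_index + replicate`, quantified, and profiled;
#' if a `timelapse` block is configured, one time-lapse per condition is
#' generated and kill events extracted, and the first two conditions are
#' compared with [compare_groups()] when both have at least two events.
#'
#' @param config anything [validate_config()] accepts.
#' @return an `AssayReport`: list with `profiles`, `summaries`, `overall`,
#'   `events`, `comparison`, and a `provenance` block (seed, config echo,
#'   package version). Stage outputs are written under
#'   `config$output_dir`: `profiles.csv`, `summary.csv`, `overall.csv`,
#'   `events.csv`, `comparison.json`, `report.json`, truth CSVs, and
#'   binary channel masks as 8-bit TIFFs when `write_masks` is `TRUE`.
#' @export
run_pipeline <- function(config) {
  cfg <- validate_config(config)
  dir.create(cfg$output_dir, showWarnings = FALSE, recursive = TRUE)
  conditions <- cfg$conditions
  if (is.null(conditions)) conditions <- list(default = list())
  roi_args <- cfg$roi[setdiff(names(cfg$roi), "n_bins")]
  roi <- do.call(make_roi, roi_args)

  profiles <- list(); overall_rows <- list(); summaries <- list()
  for (ci in seq_along(conditions)) {
    cname <- names(conditions)[ci]
    cond_profiles <- list()
    for (r in seq_len(cfg$replicates)) {
      seed_r <- cfg$seed + 1000L * ci + r
      sp <- scene_for(cfg, conditions[[ci]], seed_r)
      scene <- generate_scene(sp, roi = roi)
      q <- quantify_scene(scene, roi, cfg$thresholds, condition = cname,
                          replicate = r)
      cond_profiles[[r]] <- q$profile
      overall_rows[[length(overall_rows) + 1L]] <- data.frame(
        condition = cname, replicate = r, seed = seed_r,
        percent_killed_overall = q$overall,
        true_percent_killed_overall = scene$truth$true_percent_killed_overall)
      write_truth(scene$truth,
                  file.path(cfg$output_dir,
                            sprintf("truth_%s_rep%d.csv", cname, r)))
      if (isTRUE(cfg$write_masks)) {
        for (mn in names(q$masks))
          write_mask_tiff(q$masks[[mn]],
                          file.path(cfg$output_dir,
                                    sprintf("mask_%s_rep%d_%s.tif", cname, r, mn)))
      }
    }
    profiles <- c(profiles, cond_profiles)
    summaries[[cname]] <- aggregate_profiles(cond_profiles)
  }
  profile_tab <- do.call(rbind, lapply(profiles, as.data.frame))
  summary_tab <- do.call(rbind, lapply(summaries, as.data.frame))
  overall_tab <- do.call(rbind, overall_rows)
  write.csv(profile_tab, file.path(cfg$output_dir, "profiles.csv"),
            row.names = FALSE)
  write.csv(summary_tab, file.path(cfg$output_dir, "summary.csv"),
            row.names = FALSE)
  write.csv(overall_tab, file.path(cfg$output_dir, "overall.csv"),
            row.names = FALSE)

  events_tab <- NULL; comparison <- NULL
  if (!is.null(cfg$timelapse)) {
    ev_by_cond <- list()
    for (ci in seq_along(conditions)) {
      cname <- names(conditions)[ci]
      tl_args <- modifyList(cfg$timelapse, as.list(conditions[[ci]]))
      tl_args <- tl_args[names(tl_args) %in%
                           c(names(formals(scene_params)),
                             names(formals(timelapse_params)))]
      tl_args$seed <- cfg$seed + 500000L + ci
      sim <- generate_timelapse(do.call(timelapse_params, tl_args))
      ev <- extract_kill_events(
        sim$timelapse, max_step = cfg$thresholds$max_step,
        min_area = cfg$thresholds$min_area,
        contact_dilation = cfg$thresholds$contact_dilation,
        onset_fraction = cfg$thresholds$onset_fraction,
        persistence = cfg$thresholds$persistence)
      if (nrow(ev)) ev$condition <- cname
      ev_by_cond[[cname]] <- ev
    }
    events_tab <- do.call(rbind, ev_by_cond[vapply(ev_by_cond, nrow, 1L) > 0])
    if (is.null(events_tab)) events_tab <- data.frame()
    write.csv(events_tab, file.path(cfg$output_dir, "events.csv"),
              row.names = FALSE)
    if (length(ev_by_cond) >= 2L &&
        nrow(ev_by_cond[[1]]) >= 2L && nrow(ev_by_cond[[2]]) >= 2L) {
      comparison <- compare_groups(ev_by_cond[[1]]$time_for_killing,
                                   ev_by_cond[[2]]$time_for_killing,
                                   labels = names(ev_by_cond)[1:2])
      jsonlite::write_json(unclass(comparison),
                           file.path(cfg$output_dir, "comparison.json"),
                           auto_unbox = TRUE, digits = NA)
    }
  }

  provenance <- list(seed = cfg$seed,
                     package_version = as.character(utils::packageVersion("cytotox3d")),
                     config = unclass(cfg))
  report <- structure(list(profiles = profile_tab, summaries = summaries,
                           overall = overall_tab, events = events_tab,
                           comparison = comparison, provenance = provenance),
                      class = "AssayReport")
  jsonlite::write_json(
    list(overall = overall_tab,
         comparison = if (is.null(comparison)) NULL else unclass(comparison),
         provenance = provenance),
    file.path(cfg$output_dir, "report.json"), auto_unbox = TRUE, digits = NA,
    null = "null", force = TRUE)
  report
}

#' @export
print.AssayReport <- function(x, ...) {
  cat("AssayReport\n")
  cat(sprintf("  conditions: %s\n", paste(names(x$summaries), collapse = ", ")))
  cat(sprintf("  replicates: %d rows in overall table\n", nrow(x$overall)))
  if (!is.null(x$events)) cat(sprintf("  kill events: %d\n", nrow(x$events)))
  if (!is.null(x$comparison)) print(x$comparison)
  invisible(x)
}
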