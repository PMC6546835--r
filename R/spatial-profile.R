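#' Define the depth-binned region of interest
#'
#' The analysis window is a square region of interest (ROI) abutting the
#' gel-media interface, divided into equal-width depth sub-regions
#' R0, R1, ... counted from the interface. The reference geometry is a
#' 700-um ROI in seven 100-um bins R0-R6, with the pooled statistic taken
#' over R1-R5 only: R0 and R6 sit at the gel boundaries where the
#' capillary meniscus makes edges ambiguous, so by default the first and
#' last bin are excluded from pooled analysis (all bins are still
#' reported per-bin).
#'
#' Bins are half-open in depth: `R_i` covers
#' `[i * bin_width, (i + 1) * bin_width)` micrometres from the interface.
#'
#' @param interface_x position of the gel-media interface in um
#'   (depth 0); default 0.
#' @param side_length ROI side in um; must be an integral multiple of
#'   `bin_width`. Default 700.
#' @param bin_width sub-region width in um. Default 100.
#' @param analysis_bins integer vector of bin indices (0-based, i.e. the
#'   `i` of `R_i`) used for pooled statistics. Default: all but the first
#'   and last bin when there are at least 3 bins, otherwise all bins.
#' @return an object of class `ROISpec`.
#' @export
#' @examples
#' roi <- make_roi()        # 7 bins R0..R6, analysis over R1..R5
#' roi$n_bins
make_roi <- function(interface_x = 0, side_length = 700, bin_width = 100,
                     analysis_bins = NULL) {
  check_number(interface_x, "interface_x", lower = 0)
  check_number(side_length, "side_length", lower = 0, allow_equal_lower = FALSE)
  check_number(bin_width, "bin_width", lower = 0, allow_equal_lower = FALSE)
  if (!is_wholenumber(side_length / bin_width))
    stopf("geometry error: side_length (%g) is not a multiple of bin_width (%g)",
          side_length, bin_width)
  n_bins <- as.integer(round(side_length / bin_width))
  if (is.null(analysis_bins)) {
    analysis_bins <- if (n_bins >= 3L) seq_len(n_bins - 2L) else seq_len(n_bins) - 1L
  }
  analysis_bins <- as.integer(analysis_bins)
  if (any(analysis_bins < 0L | analysis_bins >= n_bins))
    stopf("analysis_bins must be bin indices in 0..%d", n_bins - 1L)
  structure(list(interface_x = interface_x, side_length = side_length,
                 bin_width = bin_width, n_bins = n_bins,
                 bin_labels = paste0("R", seq_len(n_bins) - 1L),
                 analysis_bins = analysis_bins),
            class = "ROISpec")
}

#' @export
print.ROISpec <- function(x, ...) {
  cat(sprintf("ROISpec: %g um ROI from x=%g, %d x %g-um bins (%s-%s), pooled over %s\n",
              x$side_length, x$interface_x, x$n_bins, x$bin_width,
              x$bin_labels[1], x$bin_labels[x$n_bins],
              paste0("R", range(x$analysis_bins), collapse = "-")))
  invisible(x)
}

#' Sum mask area per depth sub-region
#'
#' Each foreground pixel is assigned to the bin containing its center's
#' depth coordinate (half-open bins, so no pixel is double-counted); the
#' per-bin areas sum exactly to the mask area inside the ROI.
#'
#' @param mask a [binary_mask()] in the same coordinate frame as the ROI.
#' @param roi a [make_roi()].
#' @return named numeric vector of areas (um^2), one per bin R0..R(n-1).
#' @export
bin_areas <- function(mask, roi) {
  stopifnot(inherits(mask, "BinaryMask"), inherits(roi, "ROISpec"))
  ps <- mask$pixel_size
  nc <- ncol(mask$pixels)
  image_extent <- nc * ps
  if (roi$interface_x + roi$side_length > image_extent + 1e-9)
    stopf("geometry error: ROI [%g, %g] um exceeds image x-extent %g um",
          roi$interface_x, roi$interface_x + roi$side_length, image_extent)
  x_centers <- (seq_len(nc) - 0.5) * ps
  depth <- x_centers - roi$interface_x
  bin_of_col <- ifelse(depth >= 0 & depth < roi$side_length,
                       floor(depth / roi$bin_width), NA)
  col_area <- colSums(mask$pixels) * ps^2
  out <- vapply(seq_len(roi$n_bins) - 1L,
                function(b) sum(col_area[!is.na(bin_of_col) & bin_of_col == b]),
                1.0)
  names(out) <- roi$bin_labels
  out
}

#' Build a per-sub-region infiltration and killing profile
#'
#' For each depth bin, the effector count is estimated from the binned
#' effector-mask area ([estimate_count()]) and the percent-killed
#' statistic from the binned live/dead target areas ([percent_killed()]).
#' Bins containing no target area get `NA` percent-killed ("undefined")
#' rather than 0: averaging zeros from empty bins would bias killing
#' downward.
#'
#' @param effector_mask,live_target_mask,dead_target_mask
#'   [binary_mask()]s sharing one shape and pixel size.
#' @param roi a [make_roi()].
#' @param calibration a [calibrate()] result.
#' @param condition free-text condition label (e.g. "E:T 5:1, 3 mg/ml").
#' @param replicate replicate identifier.
#' @return a data frame of class `SubRegionProfile` with columns `bin`,
#'   `depth_min`, `depth_max`, `effector_count`, `percent_killed`,
#'   `condition`, `replicate`; the ROI is attached as attribute `roi`.
#' @export
profile_subregions <- function(effector_mask, live_target_mask,
                               dead_target_mask, roi, calibration,
                               condition = "default", replicate = 1L) {
  stopifnot(inherits(calibration, "CellCalibration"))
  shapes <- lapply(list(effector_mask, live_target_mask, dead_target_mask),
                   function(m) dim(m$pixels))
  if (!all(vapply(shapes, identical, TRUE, shapes[[1]])))
    stopf("geometry error: channel masks have different shapes")
  eff <- bin_areas(effector_mask, roi)
  liv <- bin_areas(live_target_mask, roi)
  ded <- bin_areas(dead_target_mask, roi)
  pk <- mapply(function(l, d) {
    if (l + d == 0) NA_real_ else percent_killed(l, d, calibration)
  }, liv, ded)
  out <- data.frame(
    bin = roi$bin_labels,
    depth_min = (seq_len(roi$n_bins) - 1L) * roi$bin_width,
    depth_max = seq_len(roi$n_bins) * roi$bin_width,
    effector_count = estimate_count(eff, calibration$mean_effector_area),
    percent_killed = as.numeric(pk),
    condition = condition,
    replicate = replicate,
    row.names = NULL)
  attr(out, "roi") <- roi
  class(out) <- c("SubRegionProfile", "data.frame")
  out
}

#' Percent killed pooled over the analysis sub-regions
#'
#' Live and dead target areas are pooled over `roi$analysis_bins` (by
#' default all interior bins, R1-R5 for the reference geometry; the two
#' boundary bins are excluded) before applying the percent-killed formula.
#' Content confined to excluded bins therefore never affects the result.
#'
#' @inheritParams profile_subregions
#' @return percentage in `[0, 100]`.
#' @export
overall_percent_killed <- function(live_target_mask, dead_target_mask, roi,
                                   calibration) {
  liv <- bin_areas(live_target_mask, roi)
  ded <- bin_areas(dead_target_mask, roi)
  sel <- roi$analysis_bins + 1L
  l <- sum(liv[sel]); d <- sum(ded[sel])
  if (l + d == 0)
    stopf("undefined statistic: no target-cell area in analysis bins %s",
          paste0("R", roi$analysis_bins, collapse = ","))
  percent_killed(l, d, calibration)
}

#' Aggregate replicate profiles into a condition summary
#'
#' Per-bin arithmetic mean and standard error of the mean (SEM = sample
#' standard deviation / sqrt(n)) across replicates, for both the effector
#' count and percent killed. Bins where a replicate's percent killed is
#' undefined (no target area) are excluded pairwise, and the per-bin `n`
#' actually used is reported. SEM is `NA` at n = 1.
#'
#' @param profiles list of [profile_subregions()] results sharing an ROI
#'   and condition.
#' @return a data frame of class `ConditionSummary` with per-bin columns
#'   `n_count`, `mean_count`, `sem_count`, `n_killed`, `mean_killed`,
#'   `sem_killed`.
#' @export
aggregate_profiles <- function(profiles) {
  if (!is.list(profiles) || length(profiles) == 0L)
    stopf("empty input: 'profiles' must be a non-empty list of profiles")
  if (inherits(profiles, "SubRegionProfile")) profiles <- list(profiles)
  n_bins <- vapply(profiles, nrow, 1L)
  if (length(unique(n_bins)) != 1L)
    stopf("profiles have differing bin counts; they must share an ROI")
  sem <- function(x) if (length(x) < 2L) NA_real_ else sd(x) / sqrt(length(x))
  summarise_metric <- function(col) {
    vals <- do.call(cbind, lapply(profiles, `[[`, col))
    list(n = apply(vals, 1, function(v) sum(!is.na(v))),
         mean = apply(vals, 1, function(v) if (all(is.na(v))) NA_real_ else mean(v, na.rm = TRUE)),
         sem = apply(vals, 1, function(v) sem(v[!is.na(v)])))
  }
  cnt <- summarise_metric("effector_count")
  kil <- summarise_metric("percent_killed")
  out <- data.frame(
    bin = profiles[[1]]$bin,
    condition = profiles[[1]]$condition[1],
    n_count = cnt$n, mean_count = cnt$mean, sem_count = cnt$sem,
    n_killed = kil$n, mean_killed = kil$mean, sem_killed = kil$sem,
    row.names = NULL)
  attr(out, "roi") <- attr(profiles[[1]], "roi")
  class(out) <- c("ConditionSummary", "data.frame")
  out
}
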