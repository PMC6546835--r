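#' Calibrate single-cell areas
#'
#' Area-based counting needs a mean single-cell area per cell class. The
#' reference protocol pools manual selections from several raters (e.g.
#' five raters x 20 cells = 100 cells per type) and uses the arithmetic
#' mean of the pooled areas. The live/dead conversion ratio is the ratio
#' of pooled means (live mean / dead mean), not the mean of per-cell
#' ratios: live target cells are extended while dead ones are rounded, so
#' this ratio converts dead-cell area into the area an equivalent number
#' of live cells would occupy.
#'
#' @param effector_areas,live_target_areas,dead_target_areas numeric
#'   vectors of single-cell areas in um^2; each non-empty, all positive.
#' @return an object of class `CellCalibration` with fields
#'   `mean_effector_area`, `mean_live_target_area`, `mean_dead_target_area`,
#'   `n_cells_per_type`, and `conversion_ratio`.
#' @export
#' @examples
#' cal <- calibrate(150, 400, 200)
#' cal$conversion_ratio  # 2
calibrate <- function(effector_areas, live_target_areas, dead_target_areas) {
  check_areas <- function(x, name) {
    if (!is.numeric(x) || length(x) == 0L)
      stopf("calibration error: '%s' must be a non-empty numeric vector", name)
    if (anyNA(x) || any(x <= 0))
      stopf("calibration error: '%s' contains non-positive or missing areas", name)
    x
  }
  eff <- check_areas(effector_areas, "effector_areas")
  liv <- check_areas(live_target_areas, "live_target_areas")
  ded <- check_areas(dead_target_areas, "dead_target_areas")
  structure(list(
    mean_effector_area = mean(eff),
    mean_live_target_area = mean(liv),
    mean_dead_target_area = mean(ded),
    n_cells_per_type = c(effector = length(eff), live_target = length(liv),
                         dead_target = length(ded)),
    conversion_ratio = mean(liv) / mean(ded)),
    class = "CellCalibration")
}

#' @export
print.CellCalibration <- function(x, ...) {
  cat(sprintf(paste0("CellCalibration: effector %.1f um^2 (n=%d), ",
                     "live target %.1f (n=%d), dead target %.1f (n=%d), ",
                     "live/dead ratio %.3f\n"),
              x$mean_effector_area, x$n_cells_per_type[["effector"]],
              x$mean_live_target_area, x$n_cells_per_type[["live_target"]],
              x$mean_dead_target_area, x$n_cells_per_type[["dead_target"]],
              x$conversion_ratio))
  invisible(x)
}

#' Write / read a calibration table
#'
#' Calibration areas round-trip through a plain CSV with columns
#' `cell_type` (`effector`, `live_target`, `dead_target`), `area_um2`, and
#' `rater`, mirroring a multi-rater manual selection protocol.
#'
#' @param areas data frame with columns `cell_type`, `area_um2`, and
#'   optionally `rater`.
#' @param path CSV file path.
#' @return `write_calibration_table` returns `path` invisibly;
#'   `read_calibration` returns a [calibrate()] result.
#' @export
write_calibration_table <- function(areas, path) {
  stopifnot(is.data.frame(areas),
            all(c("cell_type", "area_um2") %in% names(areas)))
  if (!"rater" %in% names(areas)) areas$rater <- NA
  write.csv(areas[c("cell_type", "area_um2", "rater")], path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_calibration_table
#' @export
read_calibration <- function(path) {
  tab <- read.csv(path)
  if (!all(c("cell_type", "area_um2") %in% names(tab)))
    stopf("calibration table '%s' must have cell_type and area_um2 columns", path)
  calibrate(tab$area_um2[tab$cell_type == "effector"],
            tab$area_um2[tab$cell_type == "live_target"],
            tab$area_um2[tab$cell_type == "dead_target"])
}

#' Estimate a cell count from a total mask area
#'
#' The count is the total foreground area divided by the mean single-cell
#' area. No rounding is applied: areas divide inexactly and downstream
#' statistics average over replicates, so fractional counts are kept.
#'
#' @param total_area total mask area in um^2 (>= 0).
#' @param mean_single_cell_area calibrated mean single-cell area in um^2.
#' @return the (fractional) estimated number of cells.
#' @export
estimate_count <- function(total_area, mean_single_cell_area) {
  if (!is.numeric(mean_single_cell_area) || any(mean_single_cell_area <= 0))
    stopf("calibration error: 'mean_single_cell_area' must be positive")
  if (any(total_area < 0)) stopf("'total_area' must be non-negative")
  total_area / mean_single_cell_area
}

#' Percent of target cells killed, from live/dead areas
#'
#' Dead target cells are rounded and hence smaller than extended live
#' ones, so the dead area is first converted to an equivalent live-cell
#' area by multiplying with the calibrated live/dead area ratio. The
#' statistic is then
#' `100 * converted_dead / (live_area + converted_dead)`.
#'
#' @param live_area,dead_area areas in um^2 (>= 0, not both zero).
#' @param calibration a [calibrate()] result, or directly the numeric
#'   live/dead conversion ratio.
#' @return percentage in `[0, 100]`.
#' @export
#' @examples
#' percent_killed(500, 250, 2)  # 50
percent_killed <- function(live_area, dead_area, calibration) {
  ratio <- if (inherits(calibration, "CellCalibration"))
    calibration$conversion_ratio else calibration
  if (!is.numeric(ratio) || length(ratio) != 1L || ratio <= 0)
    stopf("'calibration' must be a CellCalibration or a positive ratio")
  if (any(live_area < 0) || any(dead_area < 0))
    stopf("areas must be non-negative")
  if (live_area + dead_area == 0)
    stopf("undefined statistic: no target-cell area in region")
  converted <- dead_area * ratio
  100 * converted / (live_area + converted)
}
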