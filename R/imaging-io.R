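#' Create an image stack
#'
#' An `ImageStack` holds one fluorescence channel as a 3D array of
#' non-negative integer intensities with physical metadata. Single-plane
#' images are stacks with z-extent 1. Array layout is `[y, x, z]` (row =
#' y, column = x), with the pixel `(1, 1)` at the top-left corner and x
#' increasing toward gel depth. Pixel `(r, c)` has its center at
#' `((c - 0.5) * pixel_size, (r - 0.5) * pixel_size)` in micrometres.
#'
#' @param data numeric matrix (single plane) or 3D array `[y, x, z]` of
#'   intensities in `[0, 2^bit_depth - 1]`.
#' @param pixel_size pixel edge length in micrometres; must be positive.
#' @param z_interval spacing between optical sections in micrometres
#'   (e.g. 4 for a 100-um stack imaged every 4 um); `NA` for single planes.
#' @param channel channel name, one of `"target"`, `"effector"`,
#'   `"dead_stain"`, or `NA`.
#' @param bit_depth bits per pixel, 8 or 16.
#' @return an object of class `ImageStack`.
#' @export
image_stack <- function(data, pixel_size, z_interval = NA_real_,
                        channel = NA_character_, bit_depth = 16L) {
  if (is.matrix(data)) data <- array(data, dim = c(dim(data), 1L))
  if (!is.array(data) || length(dim(data)) != 3L)
    stopf("'data' must be a matrix or 3D array [y, x, z]")
  check_number(pixel_size, "pixel_size", lower = 0, allow_equal_lower = FALSE)
  if (!bit_depth %in% c(8L, 16L)) stopf("'bit_depth' must be 8 or 16")
  if (!is.na(channel) && !channel %in% c("target", "effector", "dead_stain"))
    stopf("'channel' must be one of target, effector, dead_stain")
  vmax <- 2^bit_depth - 1
  if (anyNA(data) || min(data) < 0 || max(data) > vmax)
    stopf("intensities must lie in [0, %d]", vmax)
  storage.mode(data) <- "integer"
  structure(list(data = data, pixel_size = pixel_size,
                 z_interval = z_interval, channel = channel,
                 bit_depth = as.integer(bit_depth)),
            class = "ImageStack")
}

#' @export
print.ImageStack <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("ImageStack [%s]: %d x %d px, %d plane(s), %g um/px, %d-bit\n",
              ifelse(is.na(x$channel), "?", x$channel),
              d[1], d[2], d[3], x$pixel_size, x$bit_depth))
  invisible(x)
}

#' @export
dim.ImageStack <- function(x) dim(x$data)

#' Collapse a z-stack to a single working image
#'
#' Confocal stacks (e.g. 100 um deep at 4-um intervals) are collapsed to a
#' 2D image before thresholding. The default maximum-intensity projection
#' is the standard choice for sparse fluorescent cells; a mean projection
#' is available. `z_project` is idempotent under `"max"`: projecting a
#' projection returns itself.
#'
#' @param stack an [image_stack()], or a 2D matrix (treated as one plane).
#' @param method `"max"` (per-pixel maximum over z) or `"mean"`.
#' @return a numeric matrix with attributes `pixel_size` and `channel`.
#' @export
z_project <- function(stack, method = c("max", "mean")) {
  method <- match.arg(method)
  if (is.matrix(stack)) {
    ps <- attr(stack, "pixel_size")
    stack <- image_stack(stack, pixel_size = if (is.null(ps)) 1 else ps,
                         bit_depth = if (max(stack) > 255) 16L else 8L)
  }
  if (!inherits(stack, "ImageStack")) stopf("'stack' must be an ImageStack")
  d <- dim(stack$data)
  if (any(d == 0L)) stopf("cannot project an empty stack")
  out <- apply(stack$data, c(1, 2), if (method == "max") max else mean)
  attr(out, "pixel_size") <- stack$pixel_size
  attr(out, "channel") <- stack$channel
  out
}

#' Parse an HH:MM timestamp into minutes
#'
#' Time-lapse frames are conventionally annotated in `HH:MM`; this converts
#' such a label to minutes from the start (`60 * HH + MM`).
#'
#' @param text character vector of `"HH:MM"` strings with `0 <= MM < 60`.
#' @return numeric vector of minutes.
#' @export
#' @examples
#' parse_timestamp(c("00:00", "01:45", "10:07"))  # 0 105 607
parse_timestamp <- function(text) {
  if (!is.character(text) || length(text) == 0L)
    stopf("'text' must be a character vector of HH:MM timestamps")
  m <- regmatches(text, regexec("^([0-9]{1,3}):([0-5][0-9])$", text))
  bad <- vapply(m, length, 1L) != 3L
  if (any(bad))
    stopf("malformed timestamp '%s': expected HH:MM with 00 <= MM < 60",
          text[bad][1])
  vapply(m, function(p) 60 * as.numeric(p[2]) + as.numeric(p[3]), 1.0)
}

#' Bundle per-channel frames into a time-lapse
#'
#' @param frames list (one element per time point) of named lists of
#'   [image_stack()] objects, e.g. `list(target = ..., effector = ...,
#'   dead_stain = ...)`. All frames must share shape and pixel size.
#' @param timestamps minutes from start, strictly increasing, one per frame.
#' @return an object of class `TimeLapse`.
#' @export
time_lapse <- function(frames, timestamps) {
  if (length(frames) != length(timestamps))
    stopf("'frames' and 'timestamps' lengths differ")
  if (length(timestamps) && any(diff(timestamps) <= 0))
    stopf("'timestamps' must be strictly increasing")
  ref <- NULL
  for (f in frames) for (ch in f) {
    if (!inherits(ch, "ImageStack")) stopf("every channel must be an ImageStack")
    key <- c(dim(ch$data)[1:2], ch$pixel_size)
    if (is.null(ref)) ref <- key
    else if (!isTRUE(all.equal(ref, key)))
      stopf("all frames must share shape and pixel_size")
  }
  structure(list(frames = frames, timestamps = as.numeric(timestamps)),
            class = "TimeLapse")
}

#' @export
print.TimeLapse <- function(x, ...) {
  cat(sprintf("TimeLapse: %d frame(s), %s min, channels: %s\n",
              length(x$frames),
              if (length(x$timestamps)) paste0(min(x$timestamps), "-", max(x$timestamps)) else "-",
              paste(names(x$frames[[1]]), collapse = ", ")))
  invisible(x)
}
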