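# Minimal baseline TIFF reader/writer for grayscale 8/16-bit multi-page
# stacks. No TIFF package ships with the target environment, and the assay
# only ever needs single-sample uncompressed data, so a small dialect is
# implemented here: writing is always little-endian with one strip per
# page; reading accepts both byte orders, multiple strips, and 8/16-bit
# unsigned samples, and rejects anything compressed or multi-sample.

TAG_WIDTH <- 256L; TAG_LENGTH <- 257L; TAG_BPS <- 258L; TAG_COMPRESSION <- 259L
TAG_PHOTOMETRIC <- 262L; TAG_STRIP_OFFSETS <- 273L; TAG_SPP <- 277L
TAG_ROWS_PER_STRIP <- 278L; TAG_STRIP_BYTES <- 279L; TAG_PLANAR <- 284L

uint_le <- function(value, nbytes) {
  out <- raw(nbytes)
  for (i in seq_len(nbytes)) {
    out[i] <- as.raw(value %% 256)
    value <- value %/% 256
  }
  out
}

ifd_entry <- function(tag, type, count, value) {
  # type 3 = SHORT, 4 = LONG; value fits inline (left-justified, LE)
  v <- raw(4)
  vb <- uint_le(value, if (type == 3L) 2L else 4L)
  v[seq_along(vb)] <- vb
  c(uint_le(tag, 2L), uint_le(type, 2L), uint_le(count, 4L), v)
}

pixels_to_raw <- function(plane, bytes) {
  v <- as.integer(t(plane))  # TIFF is row-major
  if (bytes == 1L) return(as.raw(v))
  lo <- as.raw(v %% 256L)
  hi <- as.raw(v %/% 256L)
  out <- raw(2L * length(v))
  out[seq(1L, length(out), by = 2L)] <- lo
  out[seq(2L, length(out), by = 2L)] <- hi
  out
}

#' Write an image stack as a multi-page TIFF
#'
#' Writes uncompressed grayscale baseline TIFF (little-endian), one page
#' per z-plane. Round-trips losslessly through [read_stack()] for 8- and
#' 16-bit data.
#'
#' @param stack an [image_stack()].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_stack <- function(stack, path) {
  if (!inherits(stack, "ImageStack")) stopf("'stack' must be an ImageStack")
  d <- dim(stack$data)
  nr <- d[1]; nc <- d[2]; nz <- d[3]
  bytes <- stack$bit_depth %/% 8L
  page_bytes <- nr * nc * bytes
  data_start <- 8L
  ifd_size <- 2L + 9L * 12L + 4L
  first_ifd <- data_start + nz * page_bytes

  con <- tryCatch(file(path, "wb"), error = function(e)
    stopf("cannot write TIFF '%s': %s", path, conditionMessage(e)))
  on.exit(close(con), add = TRUE)
  writeBin(c(as.raw(c(0x49, 0x49)), uint_le(42, 2L), uint_le(first_ifd, 4L)), con)
  for (z in seq_len(nz)) writeBin(pixels_to_raw(stack$data[, , z], bytes), con)
  for (z in seq_len(nz)) {
    strip_off <- data_start + (z - 1L) * page_bytes
    next_ifd <- if (z < nz) first_ifd + z * ifd_size else 0L
    ifd <- c(
      uint_le(9L, 2L),
      ifd_entry(TAG_WIDTH, 4L, 1L, nc),
      ifd_entry(TAG_LENGTH, 4L, 1L, nr),
      ifd_entry(TAG_BPS, 3L, 1L, stack$bit_depth),
      ifd_entry(TAG_COMPRESSION, 3L, 1L, 1L),
      ifd_entry(TAG_PHOTOMETRIC, 3L, 1L, 1L),
      ifd_entry(TAG_STRIP_OFFSETS, 4L, 1L, strip_off),
      ifd_entry(TAG_SPP, 3L, 1L, 1L),
      ifd_entry(TAG_ROWS_PER_STRIP, 4L, 1L, nr),
      ifd_entry(TAG_STRIP_BYTES, 4L, 1L, page_bytes),
      uint_le(next_ifd, 4L))
    writeBin(ifd, con)
  }
  invisible(path)
}

read_uint <- function(bytes, pos, n, size, endian) {
  # 4-byte values are read as signed 32-bit; TIFF offsets here stay < 2^31
  v <- readBin(bytes[pos:(pos + n * size - 1L)], "integer", n = n,
               size = size, signed = size == 4L, endian = endian)
  if (size < 4L) v <- v %% (2^(8 * size))
  v
}

read_ifd_values <- function(bytes, entry_pos, endian) {
  type <- read_uint(bytes, entry_pos + 2L, 1L, 2L, endian)
  count <- read_uint(bytes, entry_pos + 4L, 1L, 4L, endian)
  size <- switch(as.character(type), "1" = 1L, "3" = 2L, "4" = 4L, NULL)
  if (is.null(size)) return(NULL)  # unsupported value type: ignore tag
  total <- size * count
  if (total <= 4L) pos <- entry_pos + 8L
  else pos <- read_uint(bytes, entry_pos + 8L, 1L, 4L, endian) + 1L
  read_uint(bytes, pos, count, size, endian)
}

#' Read a TIFF stack
#'
#' Reads a grayscale, uncompressed, 8- or 16-bit TIFF (either byte order,
#' any strip layout) as an [image_stack()]. Physical metadata is supplied
#' by the caller because plain TIFF carries none.
#'
#' @param path path to a TIFF file.
#' @param pixel_size pixel edge length in micrometres.
#' @param z_interval z spacing in micrometres (`NA` for single planes).
#' @param channel optional channel name (see [image_stack()]).
#' @return an [image_stack()] whose z-extent equals the page count.
#' @export
read_stack <- function(path, pixel_size, z_interval = NA_real_,
                       channel = NA_character_) {
  if (!file.exists(path)) stopf("file not found: '%s'", path)
  bytes <- readBin(path, "raw", n = file.size(path))
  if (length(bytes) < 8L) stopf("'%s' is not a TIFF file (too short)", path)
  order_tag <- rawToChar(bytes[1:2])
  endian <- switch(order_tag, II = "little", MM = "big",
                   stopf("'%s' is not a TIFF file (bad byte-order mark)", path))
  if (read_uint(bytes, 3L, 1L, 2L, endian) != 42L)
    stopf("'%s' is not a TIFF file (bad magic number)", path)

  planes <- list()
  ifd_off <- read_uint(bytes, 5L, 1L, 4L, endian)
  while (ifd_off != 0L) {
    p <- ifd_off + 1L
    n_entries <- read_uint(bytes, p, 1L, 2L, endian)
    tags <- list()
    for (i in seq_len(n_entries)) {
      epos <- p + 2L + (i - 1L) * 12L
      tag <- read_uint(bytes, epos, 1L, 2L, endian)
      val <- read_ifd_values(bytes, epos, endian)
      if (!is.null(val)) tags[[as.character(tag)]] <- val
    }
    get_tag <- function(tag, default = NULL) {
      v <- tags[[as.character(tag)]]
      if (is.null(v)) default else v
    }
    nc <- get_tag(TAG_WIDTH); nr <- get_tag(TAG_LENGTH)
    if (is.null(nc) || is.null(nr)) stopf("'%s': page missing image dimensions", path)
    spp <- get_tag(TAG_SPP, 1L)
    planar <- get_tag(TAG_PLANAR, 1L)
    photometric <- get_tag(TAG_PHOTOMETRIC, 1L)
    if (spp != 1L || photometric > 1L || planar != 1L)
      stopf(paste0("'%s' contains interleaved multi-sample (e.g. RGB) data; ",
                   "split channels into separate grayscale files first"), path)
    if (get_tag(TAG_COMPRESSION, 1L) != 1L)
      stopf("'%s' uses compression; only uncompressed TIFF is supported", path)
    bps <- get_tag(TAG_BPS, 1L)
    if (!bps %in% c(8L, 16L)) stopf("'%s': unsupported bit depth %d", path, bps)
    size <- bps %/% 8L
    offs <- get_tag(TAG_STRIP_OFFSETS); cnts <- get_tag(TAG_STRIP_BYTES)
    if (is.null(offs) || is.null(cnts)) stopf("'%s': page missing strip layout", path)
    v <- unlist(lapply(seq_along(offs), function(i)
      read_uint(bytes, offs[i] + 1L, cnts[i] %/% size, size, endian)))
    if (length(v) != nr * nc) stopf("'%s': strip data does not match dimensions", path)
    planes[[length(planes) + 1L]] <- matrix(v, nrow = nr, ncol = nc, byrow = TRUE)
    ifd_off <- read_uint(bytes, p + 2L + n_entries * 12L, 1L, 4L, endian)
  }
  if (!length(planes)) stopf("'%s' contains no image pages", path)
  bps_out <- bps  # bit depth of the last parsed page (all pages checked equal-dim)
  arr <- array(0L, dim = c(dim(planes[[1]]), length(planes)))
  for (z in seq_along(planes)) {
    if (!identical(dim(planes[[z]]), dim(planes[[1]])))
      stopf("'%s': pages have differing dimensions", path)
    arr[, , z] <- planes[[z]]
  }
  image_stack(arr, pixel_size = pixel_size, z_interval = z_interval,
              channel = channel, bit_depth = bps_out)
}
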