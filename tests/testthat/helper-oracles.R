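# Independent oracles, deliberately written with naive algorithms so they
# share no code path with the implementation they check.

# 8-connected component labelling by explicit breadth-first flood fill.
flood_fill_label <- function(pixels) {
  nr <- nrow(pixels); nc <- ncol(pixels)
  lab <- matrix(0L, nr, nc)
  nxt <- 0L
  for (c0 in seq_len(nc)) for (r0 in seq_len(nr)) {
    if (!pixels[r0, c0] || lab[r0, c0] != 0L) next
    nxt <- nxt + 1L
    queue <- matrix(c(r0, c0), ncol = 2)
    lab[r0, c0] <- nxt
    while (nrow(queue) > 0) {
      r <- queue[1, 1]; cc <- queue[1, 2]
      queue <- queue[-1, , drop = FALSE]
      for (dr in -1:1) for (dc in -1:1) {
        rr <- r + dr; c2 <- cc + dc
        if (rr < 1 || rr > nr || c2 < 1 || c2 > nc) next
        if (pixels[rr, c2] && lab[rr, c2] == 0L) {
          lab[rr, c2] <- nxt
          queue <- rbind(queue, c(rr, c2))
        }
      }
    }
  }
  lab
}

# per-pixel z maximum by explicit triple loop
max_project_oracle <- function(arr) {
  d <- dim(arr)
  out <- matrix(-Inf, d[1], d[2])
  for (z in seq_len(d[3])) for (x in seq_len(d[2])) for (y in seq_len(d[1]))
    out[y, x] <- max(out[y, x], arr[y, x, z])
  out
}

# per-pixel depth binning recount
bin_areas_oracle <- function(mask, roi) {
  out <- numeric(roi$n_bins)
  ps <- mask$pixel_size
  for (cc in seq_len(ncol(mask$pixels))) for (r in seq_len(nrow(mask$pixels))) {
    if (!mask$pixels[r, cc]) next
    depth <- (cc - 0.5) * ps - roi$interface_x
    if (depth < 0 || depth >= roi$side_length) next
    b <- floor(depth / roi$bin_width) + 1
    out[b] <- out[b] + ps^2
  }
  names(out) <- roi$bin_labels
  out
}

# small scene parameters used by several tests (fast to generate)
small_scene_params <- function(seed, ...) {
  args <- utils::modifyList(
    list(field_size = c(300, 300), n_target_cells = 30,
         n_effector_cells = 30, infiltration_decay_length = 80, seed = seed),
    list(...))
  do.call(scene_params, args)
}
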