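#' Image stacks
#'
#' A `myotrace` image stack is an ordered, isotropic, single-channel grayscale
#' volume. Stacks loaded from a folder of PNG slices are *lazy*: slice pixels
#' are read on demand and held in a small least-recently-used cache, so that
#' tracking a fiber never keeps more than `radius + 1` decoded slices in
#' memory at once. Stacks can also be held fully in memory (as produced by
#' [equalize_stack()] or the phantom generator before saving).
#'
#' Coordinates follow one convention everywhere in the package: 0-based
#' voxel indices `(x, y, z)` with `x` the column, `y` the row and `z` the
#' slice index (position in the sorted file sequence). Grayscale values are
#' normalized to `[0, 1]` (8-bit values divided by 255, 16-bit by 65535).
#' The `offsets` field records where a cropped stack sits inside the original
#' scan: `original = cropped + offsets` for every voxel coordinate.
#'
#' @param dir Directory containing at least two PNG slices of identical
#'   dimensions. Files are ordered by natural sort of their names
#'   (`slice2.png` before `slice10.png`); non-PNG files are skipped with a
#'   warning.
#' @return An object of class `image_stack` with fields `n_slices`, `height`,
#'   `width`, `bit_depth`, `offsets` and a lazy slice accessor (see
#'   [stack_slice()]).
#' @seealso [crop_stack()], [equalize_stack()], [threshold_preview()],
#'   [generate_phantom()]
#' @export
load_stack <- function(dir) {
  if (!dir.exists(dir)) stopf("directory '%s' does not exist", dir)
  all_files <- list.files(dir, full.names = FALSE)
  is_png <- grepl("\\.png$", all_files, ignore.case = TRUE)
  if (any(!is_png) && length(all_files) > 0) {
    skipped <- all_files[!is_png]
    skipped <- skipped[!dir.exists(file.path(dir, skipped))]
    if (length(skipped) > 0)
      warnf("skipping %d non-PNG file(s) in '%s': %s", length(skipped), dir,
            paste(utils::head(skipped, 5), collapse = ", "))
  }
  files <- natural_sort(all_files[is_png])
  if (length(files) < 2)
    stopf("'%s' must contain at least 2 PNG slices (found %d)", dir,
          length(files))
  paths <- file.path(dir, files)
  hdr <- lapply(paths, png_header)
  w <- vapply(hdr, `[[`, 0L, "width")
  h <- vapply(hdr, `[[`, 0L, "height")
  bd <- vapply(hdr, `[[`, 0L, "bit_depth")
  if (length(unique(w)) != 1L || length(unique(h)) != 1L)
    stopf("slices have mixed dimensions (e.g. %dx%d vs %dx%d)",
          w[1], h[1], w[which(w != w[1] | h != h[1])[1]],
          h[which(w != w[1] | h != h[1])[1]])
  new_image_stack(source_dir = dir, files = paths, n_slices = length(paths),
                  height = h[1], width = w[1], bit_depth = bd[1])
}

# Parse a PNG IHDR without decoding pixel data.
png_header <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  sig <- readBin(con, "raw", 8)
  if (!identical(sig, as.raw(c(0x89, 0x50, 0x4e, 0x47, 0x0d, 0x0a, 0x1a, 0x0a))))
    stopf("'%s' is not a PNG file", path)
  readBin(con, "raw", 8)  # IHDR chunk length + type
  wh <- readBin(con, "integer", 2, size = 4, endian = "big")
  bd <- as.integer(readBin(con, "raw", 1))
  list(width = wh[1], height = wh[2], bit_depth = bd)
}

new_image_stack <- function(source_dir = NULL, files = NULL, data = NULL,
                            n_slices, height, width, bit_depth = 8L,
                            offsets = c(0L, 0L, 0L)) {
  cache <- new.env(parent = emptyenv())
  cache$slices <- list()
  cache$limit <- Inf
  cache$peak <- 0L
  cache$loads <- 0L
  cache$warned_rgb <- FALSE
  structure(list(source_dir = source_dir, files = files, data = data,
                 n_slices = as.integer(n_slices), height = as.integer(height),
                 width = as.integer(width), bit_depth = as.integer(bit_depth),
                 offsets = as.numeric(offsets), cache = cache),
            class = "image_stack")
}

#' Construct an in-memory image stack from a 3D array
#'
#' @param data numeric array `[height, width, n_slices]` with values in
#'   `[0, 1]`.
#' @param offsets integer `(x0, y0, z0)` voxel offsets within the original
#'   scan frame (0 for an uncropped volume).
#' @export
as_image_stack <- function(data, offsets = c(0, 0, 0)) {
  stopifnot(is.array(data), length(dim(data)) == 3)
  if (min(data) < 0 || max(data) > 1)
    stopf("stack values must lie in [0, 1]")
  d <- dim(data)
  new_image_stack(data = data, n_slices = d[3], height = d[1], width = d[2],
                  offsets = offsets)
}

#' @export
print.image_stack <- function(x, ...) {
  src <- if (!is.null(x$source_dir)) sprintf("'%s'", x$source_dir)
         else "in memory"
  cat(sprintf("image_stack: %d slices of %d x %d (w x h), %d-bit, %s\n",
              x$n_slices, x$width, x$height, x$bit_depth, src))
  cat(sprintf("  offsets (x0, y0, z0): %s\n",
              paste(x$offsets, collapse = ", ")))
  invisible(x)
}

#' @export
dim.image_stack <- function(x) c(x$height, x$width, x$n_slices)

#' Access one slice of a stack
#'
#' Returns the grayscale pixel matrix (`height` rows by `width` columns,
#' values in `[0, 1]`) of slice `z`. File-backed stacks decode the PNG on
#' first access and keep it in the stack's slice cache, evicting the least
#' recently used slice once the cache limit (see [stack_cache_limit()]) is
#' reached.
#'
#' @param stack an `image_stack`.
#' @param z 0-based slice index.
#' @export
stack_slice <- function(stack, z) {
  z <- as.integer(z)
  if (z < 0 || z >= stack$n_slices)
    stopf("slice index %d out of range [0, %d]", z, stack$n_slices - 1L)
  if (!is.null(stack$data)) {
    m <- stack$data[, , z + 1L, drop = FALSE]
    dim(m) <- dim(m)[1:2]
    return(m)
  }
  key <- as.character(z)
  cache <- stack$cache
  hit <- cache$slices[[key]]
  if (!is.null(hit)) {
    # refresh LRU position
    cache$slices <- c(cache$slices[names(cache$slices) != key],
                      stats::setNames(list(hit), key))
    return(hit)
  }
  img <- png::readPNG(stack$files[[z + 1L]])
  if (length(dim(img)) == 3) {
    if (!cache$warned_rgb) {
      warnf("multi-channel PNG slices converted to grayscale by channel mean")
      cache$warned_rgb <- TRUE
    }
    nchan <- min(dim(img)[3], 3L)  # ignore alpha
    img <- apply(img[, , seq_len(nchan), drop = FALSE], c(1, 2), mean)
  }
  cache$loads <- cache$loads + 1L
  while (length(cache$slices) >= cache$limit)
    cache$slices[[1]] <- NULL
  cache$slices[[key]] <- img
  n <- length(cache$slices)
  if (n > cache$peak) cache$peak <- n
  img
}

#' Control and inspect the slice cache
#'
#' `stack_cache_limit()` sets the maximum number of decoded slices a
#' file-backed stack may hold at once (the tracker sets this to
#' `radius + backstep + 1` for the duration of a walk). `stack_cache_reset()`
#' empties the cache and clears the instrumentation counters;
#' `stack_cache_stats()` reports the current occupancy, the peak number of
#' simultaneously resident slices since the last reset, and the number of
#' slice decodes.
#'
#' @param stack an `image_stack`.
#' @param limit maximum resident slices (may be `Inf`).
#' @export
stack_cache_limit <- function(stack, limit) {
  stack$cache$limit <- limit
  while (length(stack$cache$slices) > limit)
    stack$cache$slices[[1]] <- NULL
  invisible(stack)
}

#' @rdname stack_cache_limit
#' @export
stack_cache_reset <- function(stack) {
  stack$cache$slices <- list()
  stack$cache$peak <- 0L
  stack$cache$loads <- 0L
  invisible(stack)
}

#' @rdname stack_cache_limit
#' @export
stack_cache_stats <- function(stack) {
  list(resident = length(stack$cache$slices), peak = stack$cache$peak,
       loads = stack$cache$loads, limit = stack$cache$limit)
}

# Gray values at 0-based voxel coordinates (n x 3 matrix), grouped by slice
# so each needed slice is decoded once.
stack_gray <- function(stack, coords) {
  coords <- matrix(coords, ncol = 3)
  out <- numeric(nrow(coords))
  for (z in unique(coords[, 3])) {
    sl <- stack_slice(stack, z)
    idx <- which(coords[, 3] == z)
    out[idx] <- sl[cbind(coords[idx, 2] + 1L, coords[idx, 1] + 1L)]
  }
  out
}

#' Save a stack as numbered PNG slices
#'
#' @param stack an `image_stack`.
#' @param dir output directory (created if missing).
#' @param bit_depth 8 or 16.
#' @return `dir`, invisibly.
#' @export
save_stack <- function(stack, dir, bit_depth = 8L) {
  stopifnot(bit_depth %in% c(8L, 16L))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  ndig <- max(4L, nchar(as.character(stack$n_slices)))
  for (z in seq_len(stack$n_slices) - 1L) {
    sl <- stack_slice(stack, z)
    # quantize explicitly so a write/read round trip is a pure grid snap
    q <- if (bit_depth == 8L) 255 else 65535
    sl <- rnd_half_up(pmin(pmax(sl, 0), 1) * q) / q
    png::writePNG(sl, file.path(dir, sprintf("slice%0*d.png", ndig, z)))
  }
  invisible(dir)
}

#' Crop a stack to its content plus a black buffer
#'
#' Finds the smallest sub-volume containing every nonzero voxel and pads it
#' by `buffer` black voxels on all six sides (synthesizing black padding
#' where the content touches the original extents, so the buffer is always
#' present). The returned stack's `offsets` satisfy
#' `original = cropped + offsets` (offsets may be negative when padding was
#' synthesized). A buffer of black voxels around the muscle is required by
#' the tracker, whose candidate paths must be evaluable right up to the
#' muscle boundary.
#'
#' @param stack an `image_stack`.
#' @param buffer black margin in voxels (>= 1).
#' @param out_dir optional: write the cropped slices there as PNGs (plus an
#'   `offsets.json` sidecar) and return a file-backed stack.
#' @return a cropped `image_stack` with `offsets` recorded.
#' @export
crop_stack <- function(stack, buffer = 2L, out_dir = NULL) {
  if (buffer < 1) stopf("buffer must be >= 1")
  buffer <- as.integer(buffer)
  xr <- yr <- zr <- c(Inf, -Inf)
  for (z in seq_len(stack$n_slices) - 1L) {
    sl <- stack_slice(stack, z)
    nz <- which(sl > 0, arr.ind = TRUE)
    if (nrow(nz) == 0) next
    yr <- c(min(yr[1], min(nz[, 1]) - 1L), max(yr[2], max(nz[, 1]) - 1L))
    xr <- c(min(xr[1], min(nz[, 2]) - 1L), max(xr[2], max(nz[, 2]) - 1L))
    zr <- c(min(zr[1], z), max(zr[2], z))
  }
  if (!is.finite(zr[1])) stopf("cannot crop an all-black stack")
  offs <- c(xr[1], yr[1], zr[1]) - buffer
  newdim <- c(yr[2] - yr[1] + 1L, xr[2] - xr[1] + 1L, zr[2] - zr[1] + 1L) +
    2L * buffer
  out <- array(0, dim = newdim)
  for (z in zr[1]:zr[2]) {
    sl <- stack_slice(stack, z)
    out[buffer + seq_len(yr[2] - yr[1] + 1L),
        buffer + seq_len(xr[2] - xr[1] + 1L),
        z - zr[1] + buffer + 1L] <-
      sl[(yr[1] + 1L):(yr[2] + 1L), (xr[1] + 1L):(xr[2] + 1L)]
  }
  cropped <- as_image_stack(out, offsets = offs)
  cropped$bit_depth <- stack$bit_depth
  if (!is.null(out_dir)) {
    save_stack(cropped, out_dir, bit_depth = stack$bit_depth)
    jsonlite::write_json(list(offsets = offs), file.path(out_dir, "offsets.json"),
                         auto_unbox = FALSE, digits = NA)
    cropped <- load_stack(out_dir)
    cropped$offsets <- offs
  }
  cropped
}

#' Linear contrast stretch of a whole stack
#'
#' Rescales grayscale values so the global minimum maps to 0 and the global
#' maximum to 1. The transform is monotone (rank order preserved), so
#' threshold semantics survive equalization; it is a min-max stretch, not
#' histogram equalization.
#'
#' @param stack an `image_stack` with at least two distinct gray values.
#' @return an in-memory equalized `image_stack` (offsets preserved).
#' @export
equalize_stack <- function(stack) {
  lo <- Inf; hi <- -Inf
  for (z in seq_len(stack$n_slices) - 1L) {
    sl <- stack_slice(stack, z)
    lo <- min(lo, min(sl)); hi <- max(hi, max(sl))
  }
  if (hi <= lo) stopf("cannot equalize a constant-valued stack")
  out <- array(0, dim = c(stack$height, stack$width, stack$n_slices))
  for (z in seq_len(stack$n_slices) - 1L)
    out[, , z + 1L] <- (stack_slice(stack, z) - lo) / (hi - lo)
  eq <- as_image_stack(out, offsets = stack$offsets)
  eq$bit_depth <- stack$bit_depth
  eq
}

#' Preview binarizations of one slice at several thresholds
#'
#' For each threshold `t`, the mask keeps pixels with gray value `>= t`.
#' Used to pick the `threshold` (seed selection) and `cutoff` (tracking)
#' parameters by eye before a run.
#'
#' @param stack an `image_stack`.
#' @param z 0-based slice index.
#' @param thresholds numeric vector in `[0, 1]`.
#' @param path optional PNG file; the masks are written side by side as one
#'   panel image with 2-pixel gray separators.
#' @return invisibly, a named list of logical masks (one per threshold).
#' @export
threshold_preview <- function(stack, z, thresholds, path = NULL) {
  if (any(thresholds < 0 | thresholds > 1))
    stopf("thresholds must lie in [0, 1]")
  sl <- stack_slice(stack, z)
  masks <- lapply(thresholds, function(t) sl >= t)
  names(masks) <- sprintf("t=%g", thresholds)
  if (!is.null(path)) {
    sep <- matrix(0.5, nrow = nrow(sl), ncol = 2L)
    panels <- lapply(masks, function(m) m * 1)
    panel <- do.call(cbind, Reduce(function(a, b) c(a, list(sep), list(b)),
                                   panels[-1], list(panels[[1]])))
    png::writePNG(panel, path)
  }
  invisible(masks)
}
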