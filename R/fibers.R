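#' Fiber sets
#'
#' A `fiber_set` collects the raw stepwise tracks from one tracking run
#' together with their spline-smoothed curves, the configuration that
#' produced them, the crop offsets needed to realign them to the original
#' scan, and a processing log. It is the unit on which quality control,
#' fusion, de-duplication, metrics and export operate.
#'
#' @param tracks list of `fiber_track` objects.
#' @param config the [tracking_config()] that produced them.
#' @param offsets `(x0, y0, z0)` crop offsets of the source stack.
#' @param group single group label for all fibers (e.g. the muscle name).
#' @param log character vector of processing messages.
#' @return an object of class `fiber_set`.
#' @export
fiber_set <- function(tracks, config = NULL, offsets = c(0, 0, 0),
                      group = "muscle", log = character()) {
  structure(list(tracks = tracks, fibers = list(), config = config,
                 offsets = as.numeric(offsets),
                 groups = rep(group, length(tracks)), log = log),
            class = "fiber_set")
}

#' @export
print.fiber_set <- function(x, ...) {
  cat(sprintf("fiber_set: %d raw tracks, %d smoothed fibers, offsets (%s)\n",
              length(x$tracks), length(x$fibers),
              paste(x$offsets, collapse = ", ")))
  for (l in x$log) cat(" ", l, "\n")
  invisible(x)
}

#' @export
length.fiber_set <- function(x)
  if (length(x$fibers) > 0) length(x$fibers) else length(x$tracks)

#' Smooth a raw track with a natural cubic spline
#'
#' Each coordinate is fitted by least squares against the normalized
#' cumulative chord length of the raw points, on a natural-cubic-spline
#' basis with `df` degrees of freedom (`df - 1` interior knots). `df = 1`
#' is an exact straight-line least-squares fit; `df = 2` admits a single
#' arch, `df = 3` an S-shape, and so on. The curve is evaluated densely at
#' `max(50, 10 * n)` uniform parameter values.
#'
#' @param track a `fiber_track` (or any object with `points` and `gray`),
#'   with at least `df + 2` points.
#' @param df degrees of freedom (>= 1).
#' @param id fiber identifier carried into error messages and the result.
#' @return an object of class `smoothed_fiber`: `dense_points`,
#'   `mean_residual` (mean distance from raw points to their fitted
#'   positions), `quality_ratio` (SD of raw gray values / raw track
#'   length), the raw `points` and `gray`, `df` and `source_ids`.
#' @export
smooth_fiber <- function(track, df, id = 1L) {
  pts <- track$points
  n <- nrow(pts)
  if (df < 1) stopf("df must be >= 1")
  if (n < df + 2)
    stopf("fiber %s: %d points are too few to smooth with df = %d",
          paste(id, collapse = "+"), n, df)
  seg <- sqrt(rowSums(diff(pts)^2))
  raw_len <- sum(seg)
  t_raw <- c(0, cumsum(seg)) / raw_len
  n_eval <- max(50L, 10L * n)
  t_dense <- seq(0, 1, length.out = n_eval)
  if (df == 1) {
    X <- cbind(1, t_raw)
    Xd <- cbind(1, t_dense)
  } else {
    basis <- splines::ns(t_raw, df = df)
    X <- cbind(1, basis)
    Xd <- cbind(1, stats::predict(basis, t_dense))
  }
  fit <- stats::lm.fit(X, pts)
  fitted <- X %*% fit$coefficients
  dense <- Xd %*% fit$coefficients
  colnames(dense) <- c("x", "y", "z")
  structure(list(id = id, source_ids = id, df = df,
                 points = pts, gray = track$gray,
                 dense_points = dense,
                 mean_residual = mean(sqrt(rowSums((pts - fitted)^2))),
                 quality_ratio = stats::sd(track$gray) / raw_len,
                 raw_length = raw_len),
            class = "smoothed_fiber")
}

#' @export
print.smoothed_fiber <- function(x, ...) {
  cat(sprintf("smoothed_fiber %s: df=%d, %d raw points, length %.2f vox, mean residual %.3f\n",
              paste(x$source_ids, collapse = "+"), x$df, nrow(x$points),
              fiber_length(x), x$mean_residual))
  invisible(x)
}

#' Smooth every track in a fiber set
#'
#' Tracks too short for the requested `df` are dropped with a log entry.
#'
#' @param set a [fiber_set()].
#' @param df spline degrees of freedom (see [smooth_fiber()]).
#' @return the set with `fibers` populated.
#' @export
smooth_fibers <- function(set, df = 1L) {
  fibers <- list()
  short <- 0L
  for (i in seq_along(set$tracks)) {
    if (nrow(set$tracks[[i]]$points) < df + 2) { short <- short + 1L; next }
    fibers[[length(fibers) + 1L]] <- smooth_fiber(set$tracks[[i]], df, id = i)
  }
  set$fibers <- fibers
  set$groups <- rep(set$groups[1] %||% "muscle", length(fibers))
  set$log <- c(set$log, sprintf("smoothed %d fibers with df=%d (%d too short)",
                                length(fibers), df, short))
  set
}

set_lengths <- function(set)
  vapply(set$fibers, fiber_length, 0)

#' Remove poor-quality and short fibers
#'
#' A fiber's quality ratio is the standard deviation of the gray values
#' along its raw track divided by the raw track length; a track that
#' wandered across fascicle boundaries shows high gray variation per unit
#' length. Fibers whose ratio is a Tukey-fence outlier
#' (`> Q3 + 1.5 * IQR` across the set) are removed, then fibers whose
#' smoothed length falls below `min_length`, if given.
#'
#' @param set a smoothed [fiber_set()].
#' @param min_length optional minimum smoothed length in voxels.
#' @return the filtered set (with a log entry).
#' @export
quality_check <- function(set, min_length = NULL) {
  if (length(set$fibers) == 0) return(set)
  ratios <- vapply(set$fibers, `[[`, 0, "quality_ratio")
  q <- stats::quantile(ratios, c(0.25, 0.75), names = FALSE, type = 7)
  fence <- q[2] + 1.5 * (q[2] - q[1])
  keep <- ratios <= fence
  n_out <- sum(!keep)
  set$fibers <- set$fibers[keep]
  set$groups <- set$groups[keep]
  n_short <- 0L
  if (!is.null(min_length) && length(set$fibers) > 0) {
    keep <- set_lengths(set) >= min_length
    n_short <- sum(!keep)
    set$fibers <- set$fibers[keep]
    set$groups <- set$groups[keep]
  }
  set$log <- c(set$log, sprintf("quality_check removed %d outlier and %d short fibers (%d remain)",
                                n_out, n_short, length(set$fibers)))
  set
}

endpoint_gap <- function(a, b) {
  ea <- a$points[c(1, nrow(a$points)), , drop = FALSE]
  eb <- b$points[c(1, nrow(b$points)), , drop = FALSE]
  d <- outer(seq_len(2), seq_len(2),
             Vectorize(function(i, j) sqrt(sum((ea[i, ] - eb[j, ])^2))))
  w <- which(d == min(d), arr.ind = TRUE)[1, ]
  list(dist = min(d), a_end = w[1], b_end = w[2])
}

# Concatenate two raw tracks so the joining endpoints are adjacent.
merge_tracks <- function(a, b, gap) {
  pa <- a$points; ga <- a$gray
  pb <- b$points; gb <- b$gray
  if (gap$a_end == 1) { pa <- pa[rev(seq_len(nrow(pa))), ]; ga <- rev(ga) }
  if (gap$b_end == 2) { pb <- pb[rev(seq_len(nrow(pb))), ]; gb <- rev(gb) }
  list(points = rbind(pa, pb), gray = c(ga, gb))
}

#' Fuse partial fibers that likely belong to one fiber
#'
#' Walks that stopped early at noise can leave one true fiber as two partial
#' tracks. For every fiber pair whose closest raw endpoints lie within
#' `min_vox` (closest pairs first), the two raw tracks are concatenated
#' end-to-start and re-smoothed; the merge is accepted only when the merged
#' fiber improves on both parts — strictly longer than either, with a mean
#' residual no worse than the worse of the two. Merging repeats until no
#' acceptable merge remains. Choose `min_vox` around half an average
#' fascicle width so fibers from different bundles are never joined.
#'
#' @param set a smoothed [fiber_set()].
#' @param min_vox endpoint distance gate in voxels.
#' @param df spline degrees of freedom for re-smoothing (defaults to the
#'   fibers' own df).
#' @return the fused set.
#' @export
fuse_fibers <- function(set, min_vox, df = NULL) {
  if (min_vox <= 0) stopf("min_vox must be > 0")
  n_merged <- 0L
  repeat {
    nf <- length(set$fibers)
    if (nf < 2) break
    pairs <- NULL
    for (i in seq_len(nf - 1)) for (j in (i + 1):nf) {
      g <- endpoint_gap(set$fibers[[i]], set$fibers[[j]])
      if (g$dist <= min_vox) pairs <- rbind(pairs, c(i, j, g$dist))
    }
    if (is.null(pairs)) break
    pairs <- pairs[order(pairs[, 3]), , drop = FALSE]
    accepted <- FALSE
    for (p in seq_len(nrow(pairs))) {
      i <- pairs[p, 1]; j <- pairs[p, 2]
      a <- set$fibers[[i]]; b <- set$fibers[[j]]
      use_df <- df %||% a$df
      g <- endpoint_gap(a, b)
      cand <- merge_tracks(a, b, g)
      merged <- smooth_fiber(cand, use_df, id = c(a$source_ids, b$source_ids))
      if (fiber_length(merged) > max(fiber_length(a), fiber_length(b)) &&
          merged$mean_residual <= max(a$mean_residual, b$mean_residual)) {
        merged$id <- a$id
        set$fibers[[i]] <- merged
        set$fibers[[j]] <- NULL
        set$groups <- set$groups[-j]
        n_merged <- n_merged + 1L
        accepted <- TRUE
        break
      }
    }
    if (!accepted) break
  }
  set$log <- c(set$log, sprintf("fuse_fibers accepted %d merges (%d fibers remain)",
                                n_merged, length(set$fibers)))
  set
}

# Redundancy distance between two dense polylines: the smaller of the two
# directed mean nearest-neighbour distances. Taking the minimum (not the
# average) flags a short fiber lying along part of a longer one -- the
# typical redundant pair, where the average of the directed means is
# inflated by the long fiber's unshared stretch.
polyline_mean_nn <- function(a, b) {
  d2 <- outer(rowSums(a^2), rowSums(b^2), "+") - 2 * tcrossprod(a, b)
  d2[d2 < 0] <- 0
  min(mean(sqrt(apply(d2, 1, min))), mean(sqrt(apply(d2, 2, min))))
}

#' Remove redundant fibers tracked from different seeds
#'
#' Separate seed points inside one fascicle yield near-coincident tracks.
#' Fibers are swept longest first; a fiber is discarded when its redundancy
#' distance to an already-kept fiber -- the smaller of the two directed mean
#' nearest-neighbour distances between their dense curves -- is within
#' `min_vox`, so the longest member of every redundant group survives (a
#' short partial track lying along part of a kept fiber is redundant too).
#'
#' @param set a smoothed [fiber_set()].
#' @param min_vox redundancy distance gate in voxels.
#' @return the de-duplicated set.
#' @export
check_overlap <- function(set, min_vox) {
  if (min_vox <= 0) stopf("min_vox must be > 0")
  nf <- length(set$fibers)
  if (nf < 2) return(set)
  ord <- order(-set_lengths(set))
  kept <- integer()
  for (i in ord) {
    dup <- any(vapply(kept, function(k)
      polyline_mean_nn(set$fibers[[i]]$dense_points,
                       set$fibers[[k]]$dense_points) <= min_vox, TRUE))
    if (!dup) kept <- c(kept, i)
  }
  kept <- sort(kept)
  removed <- nf - length(kept)
  set$fibers <- set$fibers[kept]
  set$groups <- set$groups[kept]
  set$log <- c(set$log, sprintf("check_overlap removed %d redundant fibers (%d remain)",
                                removed, length(set$fibers)))
  set
}

#' Shift a fiber set back into the original scan frame
#'
#' Adds the crop offsets recorded by [crop_stack()] to every raw and dense
#' coordinate, so fiber sets tracked in different cropped substacks of one
#' scan share a coordinate frame (and can be combined with
#' [combine_sets()]). All metrics are translation-invariant, so realignment
#' never changes lengths, angles or tortuosity.
#'
#' @param set a [fiber_set()].
#' @param offsets `(x0, y0, z0)`; defaults to the set's recorded offsets.
#' @return the realigned set (recorded offsets reduced by the shift applied).
#' @export
realign <- function(set, offsets = set$offsets) {
  offsets <- as.numeric(offsets)
  shift <- function(m) sweep(m, 2, -offsets)
  set$tracks <- lapply(set$tracks, function(tr) {
    tr$points <- shift(tr$points); tr$seed <- tr$seed + offsets; tr
  })
  set$fibers <- lapply(set$fibers, function(f) {
    f$points <- shift(f$points); f$dense_points <- shift(f$dense_points); f
  })
  set$offsets <- set$offsets - offsets
  set
}
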