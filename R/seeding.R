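#' Seed-point selection
#'
#' The tracker is started from a set of well-spaced seed points inside chosen
#' image planes. Within a plane, all pixels whose gray value is at least
#' `threshold` are clustered by UPGMA (average-linkage hierarchical
#' clustering, `stats::hclust(method = "average")`) on their pairwise
#' Euclidean distances; the dendrogram is cut into as many clusters as seeds
#' requested and one member is drawn uniformly at random from each cluster.
#' This spreads seeds across the whole muscle cross-section while keeping
#' the exact positions random; `start_seed` makes the draw reproducible.
#'
#' @name seeding
NULL

#' Supra-threshold pixels of one slice
#'
#' @param stack an `image_stack`.
#' @param z 0-based slice index.
#' @param threshold gray value in `[0, 1]`.
#' @return integer matrix with columns `x`, `y` (0-based), in row-major
#'   order (by `y`, then `x`); zero rows when no pixel qualifies.
#' @export
candidate_pixels <- function(stack, z, threshold) {
  sl <- stack_slice(stack, z)
  idx <- which(sl >= threshold, arr.ind = TRUE)
  out <- cbind(x = idx[, 2] - 1L, y = idx[, 1] - 1L)
  out[order(out[, "y"], out[, "x"]), , drop = FALSE]
}

#' Pick well-spaced seeds from a pixel set by UPGMA clustering
#'
#' Pixel sets larger than `cap` are first reduced to a uniform random
#' subsample of `cap` pixels (the full pairwise distance matrix is quadratic
#' in the pixel count; raising `threshold` is the recommended way to shrink
#' the set, the cap is a guard and is announced with a warning).
#'
#' @param pixels integer matrix with columns `x`, `y`.
#' @param n_seeds number of seeds wanted.
#' @param rng_seed integer seed for the random within-cluster draw.
#' @param cap maximum pixel count clustered exactly.
#' @return matrix with columns `x`, `y`: one seed per cluster,
#'   `min(n_seeds, nrow(pixels))` rows. Empty input yields zero rows with a
#'   warning (such a plane simply contributes no fibers).
#' @export
select_seeds <- function(pixels, n_seeds, rng_seed = NULL, cap = 20000L) {
  pixels <- matrix(as.numeric(pixels), ncol = 2,
                   dimnames = list(NULL, c("x", "y")))
  if (nrow(pixels) == 0) {
    warnf("no supra-threshold pixels: no seeds selected")
    return(pixels)
  }
  with_seed(rng_seed, {
    if (nrow(pixels) > cap) {
      warnf("clustering %d pixels exceeds cap %d; clustering a uniform subsample (consider raising the threshold)",
            nrow(pixels), cap)
      pixels <- pixels[sort(sample.int(nrow(pixels), cap)), , drop = FALSE]
    }
    k <- min(n_seeds, nrow(pixels))
    if (nrow(pixels) == 1L) return(pixels)
    cl <- stats::cutree(stats::hclust(stats::dist(pixels), method = "average"),
                        k = k)
    picks <- vapply(seq_len(k), function(g) {
      members <- which(cl == g)
      members[sample.int(length(members), 1L)]
    }, integer(1))
    pixels[picks, , drop = FALSE]
  })
}

#' Plan seeds across several image planes
#'
#' Each plane draws its own seeds with an RNG substream seeded
#' `start_seed + z`, so adding a plane never reshuffles seeds in the others.
#'
#' @param stack an `image_stack`.
#' @param planes 0-based slice indices.
#' @param seeds_per_plane seeds requested in each plane.
#' @param threshold gray value in `[0, 1]` selecting candidate pixels.
#' @param start_seed integer RNG seed, or `NULL` for a non-reproducible draw.
#' @return matrix with columns `x`, `y`, `z` (0-based voxel coordinates).
#' @export
plan_seeds <- function(stack, planes, seeds_per_plane, threshold,
                       start_seed = NULL) {
  stopifnot(seeds_per_plane >= 1, threshold >= 0, threshold <= 1)
  if (any(planes < 0 | planes >= stack$n_slices))
    stopf("seed plane out of stack range")
  out <- lapply(planes, function(z) {
    px <- candidate_pixels(stack, z, threshold)
    if (nrow(px) == 0) {
      warnf("seed plane z=%d has no pixels >= %g", z, threshold)
      return(cbind(x = numeric(0), y = numeric(0), z = numeric(0)))
    }
    s <- suppressWarnings(select_seeds(px, seeds_per_plane,
      rng_seed = if (!is.null(start_seed)) start_seed + z else NULL))
    cbind(s, z = rep(as.numeric(z), nrow(s)))
  })
  do.call(rbind, out)
}
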