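#' Fiber architecture metrics
#'
#' Length, orientation and tortuosity of smoothed fibers, in voxel units or
#' physical units via the isotropic scan resolution `res` (physical size of
#' one voxel edge).
#'
#' @name metrics
NULL

#' Fiber length
#'
#' Polyline length of the densely evaluated smoothed curve, multiplied by
#' `res` when given.
#'
#' @param fiber a `smoothed_fiber`.
#' @param res physical size per voxel, or `NULL` for voxel units.
#' @export
fiber_length <- function(fiber, res = NULL) {
  d <- fiber$dense_points
  len <- sum(sqrt(rowSums(diff(d)^2)))
  if (!is.null(res)) len * res else len
}

#' Fiber orientation relative to a reference axis
#'
#' The angle in degrees between the fiber's endpoint chord (last minus first
#' dense point) and `axis`, folded to `[0, 90]` because fibers carry no
#' preferred direction. The default axis is `z`, the direction through the
#' image sequence.
#'
#' @param fiber a `smoothed_fiber`.
#' @param axis reference direction (length-3, need not be unit).
#' @export
fiber_angle <- function(fiber, axis = c(0, 0, 1)) {
  d <- fiber$dense_points
  chord <- d[nrow(d), ] - d[1, ]
  cl <- sqrt(sum(chord^2))
  if (cl < .Machine$double.eps^0.5)
    stopf("fiber chord is degenerate (closed curve); angle undefined")
  axis <- axis / sqrt(sum(axis^2))
  ang <- acos(pmin(1, pmax(-1, sum(chord / cl * axis)))) * 180 / pi
  if (ang > 90) 180 - ang else ang
}

#' Fiber tortuosity
#'
#' Arc length divided by endpoint chord length; exactly 1 for a straight
#' fiber, pi/2 for a semicircle.
#'
#' @param fiber a `smoothed_fiber`.
#' @export
fiber_tortuosity <- function(fiber) {
  d <- fiber$dense_points
  chord <- sqrt(sum((d[nrow(d), ] - d[1, ])^2))
  if (chord < .Machine$double.eps^0.5)
    stopf("fiber chord is degenerate (closed curve); tortuosity undefined")
  fiber_length(fiber) / chord
}

#' Metrics table and summary for a fiber set
#'
#' @param object a smoothed [fiber_set()].
#' @param res physical size per voxel, or `NULL` for voxel units.
#' @param axis reference axis for orientation.
#' @param ... unused.
#' @return a data frame (class `summary.fiber_set`), one row per fiber:
#'   `fiber_id`, `group`, `length`, `angle_deg`, `tortuosity`, `n_points`,
#'   `quality_ratio`; the per-metric summary block (mean, sd, min, max) is
#'   attached as attribute `stats` and printed below the table.
#' @export
summary.fiber_set <- function(object, res = NULL, axis = c(0, 0, 1), ...) {
  fibers <- object$fibers
  tab <- data.frame(
    fiber_id = vapply(fibers, function(f) paste(f$source_ids, collapse = "+"), ""),
    group = if (length(fibers)) object$groups else character(0),
    length = vapply(fibers, fiber_length, 0, res = res),
    angle_deg = vapply(fibers, fiber_angle, 0, axis = axis),
    tortuosity = vapply(fibers, fiber_tortuosity, 0),
    n_points = vapply(fibers, function(f) nrow(f$points), 0L),
    quality_ratio = vapply(fibers, `[[`, 0, "quality_ratio"),
    stringsAsFactors = FALSE)
  stats_block <- if (nrow(tab)) {
    vals <- tab[c("length", "angle_deg", "tortuosity")]
    data.frame(metric = names(vals),
               mean = vapply(vals, mean, 0), sd = vapply(vals, stats::sd, 0),
               min = vapply(vals, min, 0), max = vapply(vals, max, 0),
               row.names = NULL)
  } else data.frame(metric = character(), mean = numeric(), sd = numeric(),
                    min = numeric(), max = numeric())
  attr(tab, "stats") <- stats_block
  attr(tab, "res") <- res
  class(tab) <- c("summary.fiber_set", "data.frame")
  tab
}

#' @export
print.summary.fiber_set <- function(x, ...) {
  cat(sprintf("fiber metrics (%d fibers, units: %s)\n", nrow(x),
              if (is.null(attr(x, "res"))) "voxels" else
                sprintf("physical, res = %g", attr(x, "res"))))
  print.data.frame(x, row.names = FALSE, digits = 4)
  cat("\nsummary:\n")
  print.data.frame(attr(x, "stats"), row.names = FALSE, digits = 4)
  invisible(x)
}
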