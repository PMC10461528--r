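#' Full-run configuration
#'
#' One validated record holding every parameter of an end-to-end
#' reconstruction: tracking (see [tracking_config()]), smoothing and
#' processing, metrics and export. Unknown fields are rejected, so a stale
#' config file fails loudly rather than silently using defaults.
#'
#' @param planes,seeds_per_plane,threshold,cutoff,radius,backstep,scalar,allowed_black,black_frac,bound_buffer,start_seed,min_track_points,max_steps,self_avoid,max_turn_deg
#'   tracking parameters, as in [tracking_config()].
#' @param df spline degrees of freedom for smoothing (1 = straight fibers;
#'   2--4 covers most curved vertebrate fibers).
#' @param min_vox distance gate in voxels for [fuse_fibers()] and
#'   [check_overlap()]; about half an average fascicle width.
#' @param min_length optional minimum fiber length (voxels) in
#'   [quality_check()].
#' @param crop_buffer black buffer for [crop_stack()]; `NULL` skips
#'   cropping.
#' @param equalize run [equalize_stack()] before tracking.
#' @param fuse,overlap run the respective processing stage.
#' @param res isotropic physical voxel size for metrics/export, or `NULL`
#'   for voxel units.
#' @param axis reference axis for fiber orientation.
#' @param tube_radius,n_sides STL tube geometry.
#' @return an object of class `run_config`.
#' @export
run_config <- function(planes, seeds_per_plane = 50L, threshold = 0.7,
                       cutoff = 0.65, radius = 7L, backstep = 0L, scalar = 1,
                       allowed_black = 0L, black_frac = 0.95,
                       bound_buffer = 5L, start_seed = NULL,
                       min_track_points = 3L, max_steps = 10000L,
                       self_avoid = 5, max_turn_deg = 90,
                       df = 1L, min_vox = 8, min_length = NULL,
                       crop_buffer = NULL, equalize = FALSE,
                       fuse = TRUE, overlap = TRUE,
                       res = NULL, axis = c(0, 0, 1),
                       tube_radius = 1, n_sides = 8L) {
  tc <- tracking_config(threshold = threshold, cutoff = cutoff,
                        radius = radius, backstep = backstep, scalar = scalar,
                        allowed_black = allowed_black, black_frac = black_frac,
                        bound_buffer = bound_buffer, planes = planes,
                        seeds_per_plane = seeds_per_plane,
                        start_seed = start_seed,
                        min_track_points = min_track_points,
                        max_steps = max_steps, self_avoid = self_avoid,
                        max_turn_deg = max_turn_deg)
  if (df < 1) stopf("df must be >= 1")
  if (min_vox <= 0) stopf("min_vox must be > 0")
  if (!is.null(crop_buffer) && crop_buffer < 1) stopf("crop_buffer must be >= 1")
  if (!is.null(res) && res <= 0) stopf("res must be > 0")
  structure(list(tracking = tc, df = as.integer(df), min_vox = min_vox,
                 min_length = min_length, crop_buffer = crop_buffer,
                 equalize = isTRUE(equalize), fuse = isTRUE(fuse),
                 overlap = isTRUE(overlap), res = res, axis = axis,
                 tube_radius = tube_radius, n_sides = as.integer(n_sides)),
            class = "run_config")
}

run_config_list <- function(cfg) {
  flat <- c(unclass(cfg$tracking), unclass(cfg)[setdiff(names(cfg), "tracking")])
  flat[!vapply(flat, is.null, TRUE)]
}

#' Read a run configuration from a JSON file
#'
#' @param path JSON file whose keys are [run_config()] arguments; unknown
#'   keys are an error.
#' @export
read_run_config <- function(path) {
  vals <- jsonlite::fromJSON(path, simplifyVector = TRUE)
  known <- names(formals(run_config))
  bad <- setdiff(names(vals), known)
  if (length(bad) > 0)
    stopf("unknown config field(s): %s", paste(bad, collapse = ", "))
  do.call(run_config, vals)
}

#' Serialize a fiber set to a directory
#'
#' Writes `tracks.csv` (raw stepwise coordinates:
#' `fiber_id, point_index, x, y, z, gray`), `fibers.csv` (dense smoothed
#' coordinates: `fiber_id, t, x, y, z`) and `manifest.json` (offsets, group
#' labels, processing log, per-fiber df and residuals).
#'
#' @param set a [fiber_set()].
#' @param dir output directory (created).
#' @return `dir`, invisibly.
#' @export
write_fiber_set <- function(set, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  tracks <- do.call(rbind, lapply(seq_along(set$tracks), function(i) {
    p <- set$tracks[[i]]$points
    data.frame(fiber_id = i, point_index = seq_len(nrow(p)) - 1L,
               x = p[, 1], y = p[, 2], z = p[, 3], gray = set$tracks[[i]]$gray)
  }))
  utils::write.csv(tracks %||% data.frame(), file.path(dir, "tracks.csv"),
                   row.names = FALSE)
  dense <- do.call(rbind, lapply(set$fibers, function(f) {
    d <- f$dense_points
    data.frame(fiber_id = paste(f$source_ids, collapse = "+"),
               t = seq(0, 1, length.out = nrow(d)),
               x = d[, 1], y = d[, 2], z = d[, 3])
  }))
  utils::write.csv(dense %||% data.frame(), file.path(dir, "fibers.csv"),
                   row.names = FALSE)
  manifest <- list(
    offsets = set$offsets, groups = set$groups, log = set$log,
    fibers = lapply(set$fibers, function(f)
      list(id = paste(f$source_ids, collapse = "+"), df = f$df,
           mean_residual = f$mean_residual, quality_ratio = f$quality_ratio)))
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  invisible(dir)
}

pipe_stage <- function(name, expr) {
  tryCatch(expr, error = function(e)
    stopf("pipeline stage '%s' failed: %s", name, conditionMessage(e)))
}

#' Run the whole reconstruction pipeline
#'
#' Executes, in order: load (if `input` is a directory), optional crop and
#' equalization, seed planning and tracking, spline smoothing, quality
#' check, fiber fusion, overlap removal, realignment into the original
#' frame, metrics, and STL/figure export. Every stage logs its input and
#' output counts; the echoed `config.json` plus `start_seed` make the run
#' exactly reproducible.
#'
#' @param input an `image_stack` or a directory of PNG slices.
#' @param config a [run_config()].
#' @param out_dir output directory; receives `tracks.csv`, `fibers.csv`,
#'   `manifest.json`, `metrics.csv`, `summary.json`, `fibers.stl`,
#'   `figure.png`, `config.json` and `log.txt`.
#' @return the final [fiber_set()], invisibly, with the metrics table in
#'   attribute `metrics`.
#' @export
run_pipeline <- function(input, config, out_dir) {
  stopifnot(inherits(config, "run_config"))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  stack <- pipe_stage("load", if (inherits(input, "image_stack")) input
                      else load_stack(input))
  if (!is.null(config$crop_buffer)) {
    stack <- pipe_stage("crop", crop_stack(stack, config$crop_buffer))
    # seed planes are given in the input frame; shift them into the crop
    config$tracking$planes <-
      as.integer(pmin(pmax(config$tracking$planes - stack$offsets[3], 0),
                      stack$n_slices - 1L))
  }
  if (config$equalize)
    stack <- pipe_stage("equalize", equalize_stack(stack))
  set <- pipe_stage("track", track_fibers(stack, config$tracking))
  set <- pipe_stage("smooth", smooth_fibers(set, config$df))
  set <- pipe_stage("quality_check", quality_check(set, config$min_length))
  # de-duplicate before fusing: fusing two redundant copies of one fiber
  # would concatenate them back-to-back into a doubled track
  if (config$overlap)
    set <- pipe_stage("overlap", check_overlap(set, config$min_vox))
  if (config$fuse)
    set <- pipe_stage("fuse", fuse_fibers(set, config$min_vox, config$df))
  set <- pipe_stage("realign", realign(set))
  metrics <- pipe_stage("metrics",
                        summary(set, res = config$res, axis = config$axis))
  utils::write.csv(as.data.frame(metrics), file.path(out_dir, "metrics.csv"),
                   row.names = FALSE)
  jsonlite::write_json(attr(metrics, "stats"),
                       file.path(out_dir, "summary.json"),
                       auto_unbox = TRUE, digits = NA)
  write_fiber_set(set, out_dir)
  if (length(set$fibers) > 0) {
    pipe_stage("export_stl",
               export_stl(set, file.path(out_dir, "fibers.stl"),
                          tube_radius = config$tube_radius,
                          n_sides = config$n_sides, res = config$res))
    pipe_stage("figure",
               render_figure(set, "length", file.path(out_dir, "figure.png")))
  }
  jsonlite::write_json(run_config_list(config), file.path(out_dir, "config.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  writeLines(set$log, file.path(out_dir, "log.txt"))
  attr(set, "metrics") <- metrics
  invisible(set)
}
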