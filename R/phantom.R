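#' Specify a synthetic muscle phantom
#'
#' Phantoms emulate the input the tracker expects from a segmented diceCT
#' substack: bright tubular fibers (well above threshold) embedded in darker
#' interstitial tissue, inside a muscle envelope surrounded by pure black
#' background, with known centerline geometry. Fibers run mainly through
#' the image sequence (the orientation the tracker is designed for); the
#' `in_plane` orientation lays them parallel to the image plane instead, to
#' reproduce qualitatively the regime where grayscale trackers are known to
#' struggle.
#'
#' Tube centerlines are laid out on a grid with center spacing
#' `2 * tube_radius + spacing`, so tube surfaces stay `spacing` voxels
#' apart and never intersect; volume dimensions are derived from the layout
#' plus an all-black margin. Default gray levels (foreground 0.8 +/- 0.05,
#' interstitium 0.25 +/- 0.05, voxel noise sd 0.02) leave a conservative
#' threshold of 0.7 and cutoff of 0.65 cleanly between the two tissue
#' classes.
#'
#' @param n_fibers number of fibers.
#' @param geometry `"straight"` (length `length` along z), `"arc"` (circle
#'   radius `arc_radius`, angular extent `arc_extent`, bending in x), or
#'   `"helix"` (radius `helix_radius`, pitch `helix_pitch`, `turns` turns).
#' @param length straight-fiber length in voxels.
#' @param arc_radius,arc_extent,helix_radius,helix_pitch,turns curve
#'   parameters (voxels / radians).
#' @param tube_radius fiber tube radius in voxels.
#' @param spacing clearance between tube surfaces (also the thickness of
#'   interstitial envelope around each tube).
#' @param fg_mean,fg_sd,int_mean,int_sd gray level mean/sd of fiber tissue
#'   and interstitium; separability `fg_mean - 2 fg_sd > int_mean + 2 int_sd`
#'   is enforced.
#' @param noise_sd additional independent voxel noise.
#' @param margin black border around the muscle envelope, in voxels.
#' @param in_plane lay fibers along x (parallel to the image plane).
#' @param seed RNG seed; generation is fully deterministic given the spec.
#' @return an object of class `phantom_spec`.
#' @export
phantom_spec <- function(n_fibers = 10L, geometry = c("straight", "arc", "helix"),
                         length = 60, arc_radius = 20, arc_extent = pi / 2,
                         helix_radius = 8, helix_pitch = 40, turns = 1,
                         tube_radius = 3, spacing = 4,
                         fg_mean = 0.8, fg_sd = 0.05,
                         int_mean = 0.25, int_sd = 0.05, noise_sd = 0.02,
                         margin = 4L, in_plane = FALSE, seed = 1L) {
  geometry <- match.arg(geometry)
  if (spacing <= 0) stopf("spacing must be > 0 (tubes may not touch)")
  if (!(fg_mean - 2 * fg_sd > int_mean + 2 * int_sd))
    stopf("gray levels not separable: need fg_mean - 2*fg_sd > int_mean + 2*int_sd")
  structure(as.list(environment()), class = "phantom_spec")
}

# Dense analytic centerline of fiber i (rows are (x, y, z)), plus analytic
# length and tortuosity.
phantom_centerline <- function(spec, cx, cy, z0, step = 0.25) {
  switch(spec$geometry,
    straight = {
      s <- seq(0, spec$length, by = step)
      list(xyz = cbind(cx, cy, z0 + s), length = spec$length, tortuosity = 1)
    },
    arc = {
      R <- spec$arc_radius; e <- spec$arc_extent
      th <- seq(-e / 2, e / 2, length.out = max(2, ceiling(R * e / step)))
      list(xyz = cbind(cx + R * (1 - cos(th)), cy, z0 + R * (sin(th) + sin(e / 2))),
           length = R * e, tortuosity = (e / 2) / sin(e / 2))
    },
    helix = {
      R <- spec$helix_radius; p <- spec$helix_pitch
      tt <- seq(0, 2 * pi * spec$turns,
                length.out = max(2, ceiling(spec$turns * sqrt((2 * pi * R)^2 + p^2) / step)))
      xyz <- cbind(cx + R * cos(tt) - R, cy + R * sin(tt), z0 + p * tt / (2 * pi))
      arc <- spec$turns * sqrt((2 * pi * R)^2 + p^2)
      list(xyz = xyz, length = arc,
           tortuosity = arc / sqrt(sum((xyz[nrow(xyz), ] - xyz[1, ])^2)))
    })
}

#' Generate a phantom stack and its ground truth
#'
#' Voxels within `tube_radius` of a centerline render as fiber tissue,
#' voxels within `tube_radius + spacing` as interstitium, all others as
#' black background. Gray levels are drawn once per voxel under the spec
#' seed, so the same spec always renders byte-identical stacks.
#'
#' @param spec a [phantom_spec()].
#' @param dir optional directory: the stack is written there as 8-bit PNG
#'   slices (plus `truth.csv` and `spec.json`) and returned file-backed;
#'   otherwise the stack stays in memory.
#' @return list with `stack` (an `image_stack`), `truth` (list of
#'   `centerlines`: data frame `fiber, x, y, z`; and `metrics`: data frame
#'   `fiber, length, angle_deg, tortuosity` of analytic values), and
#'   `spec`.
#' @export
generate_phantom <- function(spec, dir = NULL) {
  stopifnot(inherits(spec, "phantom_spec"))
  rt <- spec$tube_radius; sp <- spec$spacing; mg <- spec$margin
  pitch_xy <- 2 * rt + sp
  ncol_g <- ceiling(sqrt(spec$n_fibers))
  nrow_g <- ceiling(spec$n_fibers / ncol_g)
  # lateral extent a centerline adds beyond its anchor point
  sweep_x <- switch(spec$geometry,
                    straight = 0,
                    arc = spec$arc_radius * (1 - cos(spec$arc_extent / 2)),
                    helix = 2 * spec$helix_radius)
  sweep_y <- if (spec$geometry == "helix") 2 * spec$helix_radius else 0
  zlen <- switch(spec$geometry,
                 straight = spec$length,
                 arc = 2 * spec$arc_radius * sin(spec$arc_extent / 2),
                 helix = spec$helix_pitch * spec$turns)
  pad <- rt + sp + mg
  x0 <- pad; y0 <- pad; z0 <- pad
  anchors <- cbind(
    cx = x0 + (rep(seq_len(ncol_g), length.out = spec$n_fibers,
                   each = nrow_g)[seq_len(spec$n_fibers)] - 1) * pitch_xy,
    cy = y0 + (rep(seq_len(nrow_g), times = ncol_g)[seq_len(spec$n_fibers)] - 1) *
      (pitch_xy + sweep_y))
  nx <- as.integer(max(anchors[, 1]) + sweep_x + pad + 1)
  ny <- as.integer(max(anchors[, 2]) + sweep_y + pad + 1)
  nzl <- as.integer(z0 + zlen + pad + 1)
  if (spec$in_plane) { tmp <- nx; nx <- nzl; nzl <- tmp }
  # dist2_tube: squared distance to the centerline, Inf beyond the flat end
  # caps (so a fiber's bright extent equals its analytic length);
  # dist2_env: plain squared distance, defining the interstitial envelope.
  dist2_tube <- array(Inf, dim = c(ny, nx, nzl))
  dist2_env <- array(Inf, dim = c(ny, nx, nzl))
  lines <- vector("list", spec$n_fibers)
  truth_m <- NULL
  for (i in seq_len(spec$n_fibers)) {
    cl <- phantom_centerline(spec, anchors[i, 1], anchors[i, 2], z0)
    xyz <- cl$xyz
    if (spec$in_plane) xyz <- xyz[, c(3, 2, 1)]
    lines[[i]] <- xyz
    chord <- xyz[nrow(xyz), ] - xyz[1, ]
    ang <- acos(min(1, abs(chord[3]) / sqrt(sum(chord^2)))) * 180 / pi
    truth_m <- rbind(truth_m, data.frame(fiber = i, length = cl$length,
                                         angle_deg = ang,
                                         tortuosity = cl$tortuosity))
    # update squared distance field inside the fiber's dilated bounding box
    rx <- max(0, floor(min(xyz[, 1]) - rt - sp)):min(nx - 1, ceiling(max(xyz[, 1]) + rt + sp)) + 1
    ry <- max(0, floor(min(xyz[, 2]) - rt - sp)):min(ny - 1, ceiling(max(xyz[, 2]) + rt + sp)) + 1
    rz <- max(0, floor(min(xyz[, 3]) - rt - sp)):min(nzl - 1, ceiling(max(xyz[, 3]) + rt + sp)) + 1
    vox <- as.matrix(expand.grid(y = ry - 1, x = rx - 1, z = rz - 1))
    d2 <- outer(rowSums(vox[, c("x", "y", "z")]^2), rowSums(xyz^2), "+") -
      2 * vox[, c("x", "y", "z")] %*% t(xyz)
    d2[d2 < 0] <- 0
    near <- max.col(-d2, ties.method = "first")
    dmin <- d2[cbind(seq_len(nrow(d2)), near)]
    idx <- cbind(vox[, "y"] + 1, vox[, "x"] + 1, vox[, "z"] + 1)
    interior <- near > 1 & near < nrow(xyz)
    dist2_tube[idx[interior, , drop = FALSE]] <-
      pmin(dist2_tube[idx[interior, , drop = FALSE]], dmin[interior])
    dist2_env[idx] <- pmin(dist2_env[idx], dmin)
  }
  vol <- with_seed(spec$seed, {
    v <- array(0, dim = dim(dist2_env))
    tube <- dist2_tube <= rt^2
    env <- dist2_env <= (rt + sp)^2
    inter <- env & !tube
    v[tube] <- stats::rnorm(sum(tube), spec$fg_mean, spec$fg_sd)
    v[inter] <- stats::rnorm(sum(inter), spec$int_mean, spec$int_sd)
    v[env] <- v[env] + stats::rnorm(sum(env), 0, spec$noise_sd)
    v[env] <- pmin(pmax(v[env], 1 / 255), 1)  # support stays nonzero
    v
  })
  centerlines <- do.call(rbind, lapply(seq_along(lines), function(i)
    data.frame(fiber = i, x = lines[[i]][, 1], y = lines[[i]][, 2],
               z = lines[[i]][, 3])))
  truth <- list(centerlines = centerlines, metrics = truth_m)
  stack <- as_image_stack(vol)
  if (!is.null(dir)) {
    save_stack(stack, dir, bit_depth = 8L)
    stack <- load_stack(dir)
    utils::write.csv(centerlines, file.path(dir, "truth.csv"), row.names = FALSE)
    jsonlite::write_json(unclass(spec)[!vapply(unclass(spec), is.function, TRUE)],
                         file.path(dir, "spec.json"), auto_unbox = TRUE, digits = NA)
  }
  list(stack = stack, truth = truth, spec = spec)
}

#' Score a reconstructed fiber set against phantom ground truth
#'
#' Each detected fiber is assigned to the true centerline with the smallest
#' mean nearest-neighbour distance (from the fiber's dense points to the
#' centerline samples); assignments beyond `match_dist` are *spurious*. A
#' true fiber counts as detected when at least one fiber is assigned to it;
#' its length error compares its longest assigned fiber to the analytic
#' length. A detected fiber is *contained* when every dense point lies
#' within `contain_dist` of its matched centerline (i.e. inside the dilated
#' tube mask).
#'
#' @param set a smoothed [fiber_set()], in the phantom's coordinate frame.
#' @param truth the `truth` element of [generate_phantom()]'s result.
#' @param match_dist assignment gate in voxels.
#' @param contain_dist containment radius in voxels (default: `match_dist`).
#' @return list with `per_true` and `per_detected` data frames plus the
#'   scalars `detection_rate` (fraction of true fibers detected),
#'   `mean_abs_length_error_pct`, `mean_abs_angle_error_deg`,
#'   `n_spurious` and `n_outside` (fibers not contained).
#' @export
score_against_truth <- function(set, truth, match_dist = 5,
                                contain_dist = match_dist) {
  cl_mat <- as.matrix(truth$centerlines[c("x", "y", "z")])
  cls <- lapply(split(seq_len(nrow(cl_mat)), truth$centerlines$fiber),
                function(ii) cl_mat[ii, , drop = FALSE])
  nt <- length(cls)
  nd <- length(set$fibers)
  per_det <- data.frame(fiber = seq_len(nd),
                        matched = rep(NA_integer_, nd),
                        mean_dist = rep(NA_real_, nd),
                        max_dist = rep(NA_real_, nd),
                        length = rep(NA_real_, nd))
  for (i in seq_len(nd)) {
    dp <- set$fibers[[i]]$dense_points
    dists <- vapply(cls, function(cl) {
      d2 <- outer(rowSums(dp^2), rowSums(cl^2), "+") - 2 * tcrossprod(dp, cl)
      nn <- sqrt(pmax(0, apply(d2, 1, min)))
      c(mean(nn), max(nn))
    }, numeric(2))
    j <- which.min(dists[1, ])
    per_det$length[i] <- fiber_length(set$fibers[[i]])
    if (dists[1, j] <= match_dist) {
      per_det$matched[i] <- j
      per_det$mean_dist[i] <- dists[1, j]
      per_det$max_dist[i] <- dists[2, j]
    }
  }
  per_true <- truth$metrics
  per_true$detected <- FALSE
  per_true$length_error_pct <- NA_real_
  per_true$angle_error_deg <- NA_real_
  for (j in seq_len(nt)) {
    hits <- which(!is.na(per_det$matched) & per_det$matched == j)
    if (length(hits) == 0) next
    rep_i <- hits[which.max(per_det$length[hits])]
    per_true$detected[j] <- TRUE
    per_true$length_error_pct[j] <-
      100 * (per_det$length[rep_i] - per_true$length[j]) / per_true$length[j]
    per_true$angle_error_deg[j] <-
      abs(fiber_angle(set$fibers[[rep_i]]) - per_true$angle_deg[j])
  }
  list(per_true = per_true, per_detected = per_det,
       detection_rate = mean(per_true$detected),
       mean_abs_length_error_pct =
         if (any(per_true$detected)) mean(abs(per_true$length_error_pct),
                                          na.rm = TRUE) else NA_real_,
       mean_abs_angle_error_deg =
         if (any(per_true$detected)) mean(per_true$angle_error_deg,
                                          na.rm = TRUE) else NA_real_,
       n_spurious = sum(is.na(per_det$matched)),
       n_outside = sum(!is.na(per_det$matched) &
                         per_det$max_dist > contain_dist))
}
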