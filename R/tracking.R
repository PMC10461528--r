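#' Tracker configuration
#'
#' Collects every parameter of the fiber-tracking walk in one validated
#' record.
#'
#' @param threshold gray value in `[0, 1]` above which pixels are bright
#'   enough to seed a fiber. Set conservatively (high) so seeds land in the
#'   bright cores of fascicles.
#' @param cutoff gray value in `[0, 1]`; during tracking every voxel below
#'   `cutoff` is treated as black (set to zero). Usually equal to or lower
#'   than `threshold`.
#' @param radius spherical-cap radius in voxels (1--11). Candidate steps are
#'   all integer offsets within this Euclidean radius ahead of the current
#'   point; 5--9 suits most data, smaller values follow tighter curves.
#' @param backstep 0 for a strictly forward walk (`dz >= 1` per step);
#'   `b >= 1` also admits same-plane and up to `b`-slices-backward offsets,
#'   letting strongly curved fibers double back through the stack.
#' @param scalar exponent on the trajectory penalty in the diagnostic value
#'   `scaled_SD * penalty^scalar`; 0 disables trajectory penalization.
#' @param allowed_black number of black (post-cutoff) voxels a candidate
#'   path may cross before it is discarded.
#' @param black_frac stop the walk when this fraction (default 0.95) of all
#'   candidate-path voxels is black -- the signature of the noisy end of a
#'   fascicle.
#' @param bound_buffer minimum distance in voxels between a step endpoint
#'   and the muscle's external boundary (suggested 2--5); stops fibers from
#'   running along connective tissue at the muscle surface.
#' @param planes 0-based slice indices of the seed planes.
#' @param seeds_per_plane seed points requested per plane.
#' @param start_seed integer RNG seed for reproducible seed draws.
#' @param min_track_points tracks shorter than this are dropped (a 1--2
#'   point track cannot be splined).
#' @param max_steps hard cap on steps per walk direction (guards against
#'   pathological oscillation when `backstep > 0`).
#' @param self_avoid self-avoidance capture radius in voxels: every accepted
#'   step claims the voxels within this radius of its path, and later steps
#'   of the same walk may not end in territory claimed more than
#'   `self_avoid + 1` steps earlier. This stops a walk that has reached a
#'   fiber's end from re-tracking the same fascicle in reverse when
#'   `backstep > 0` admits in-plane and backward moves. Choose a little more
#'   than the fascicle radius: the claimed ball must also cover the
#'   boundary-adjacent corridor beside the walked path, or a finished walk
#'   can wrap around the fiber tip and re-track the fascicle along its far
#'   side. 0 disables the rule.
#' @param max_turn_deg maximum turn, in degrees, a single step may make
#'   relative to the previous step direction. Curvature accumulates across
#'   steps, so a fiber can still bend arbitrarily far over several steps;
#'   per-step turns sharper than this are treated as tracking noise. 60
#'   degrees corresponds to a bend radius of about one step length, far
#'   below any anatomically plausible fascicle curvature at voxel scale.
#' @return an object of class `tracking_config`.
#' @export
tracking_config <- function(threshold = 0.7, cutoff = 0.65, radius = 7L,
                            backstep = 0L, scalar = 1, allowed_black = 0L,
                            black_frac = 0.95, bound_buffer = 5L,
                            planes = NULL, seeds_per_plane = 50L,
                            start_seed = NULL, min_track_points = 3L,
                            max_steps = 10000L, self_avoid = 5,
                            max_turn_deg = 90) {
  chk <- function(cond, msg) if (!cond) stopf("invalid tracking_config: %s", msg)
  chk(threshold >= 0 && threshold <= 1, "threshold must lie in [0, 1]")
  chk(cutoff >= 0 && cutoff <= 1, "cutoff must lie in [0, 1]")
  chk(radius >= 1 && radius <= 11, "radius must lie in 1..11")
  chk(backstep >= 0, "backstep must be >= 0")
  chk(scalar >= 0, "scalar must be >= 0")
  chk(allowed_black >= 0, "allowed_black must be >= 0")
  chk(black_frac > 0 && black_frac <= 1, "black_frac must lie in (0, 1]")
  chk(bound_buffer >= 0, "bound_buffer must be >= 0")
  chk(seeds_per_plane >= 1, "seeds_per_plane must be >= 1")
  chk(min_track_points >= 2, "min_track_points must be >= 2")
  chk(self_avoid >= 0, "self_avoid must be >= 0")
  chk(max_turn_deg > 0 && max_turn_deg <= 180, "max_turn_deg must lie in (0, 180]")
  if (cutoff > threshold)
    warnf("cutoff (%g) exceeds threshold (%g); seeds may sit on voxels the tracker treats as black",
          cutoff, threshold)
  structure(list(threshold = threshold, cutoff = cutoff,
                 radius = as.integer(radius), backstep = as.integer(backstep),
                 scalar = scalar, allowed_black = as.integer(allowed_black),
                 black_frac = black_frac, bound_buffer = as.integer(bound_buffer),
                 planes = planes, seeds_per_plane = as.integer(seeds_per_plane),
                 start_seed = start_seed,
                 min_track_points = as.integer(min_track_points),
                 max_steps = as.integer(max_steps), self_avoid = self_avoid,
                 max_turn_deg = max_turn_deg),
            class = "tracking_config")
}

#' @export
print.tracking_config <- function(x, ...) {
  cat("tracking_config:\n")
  for (f in setdiff(names(x), "planes"))
    cat(sprintf("  %-16s %s\n", f, paste(x[[f]], collapse = ", ")))
  cat(sprintf("  %-16s %s\n", "planes", paste(x$planes, collapse = ", ")))
  invisible(x)
}

#' Integer offsets of the spherical cap of candidate steps
#'
#' All nonzero integer offsets `(dx, dy, dz)` with Euclidean norm at most
#' `radius`, restricted in `z`: strictly ahead (`direction * dz >= 1`) when
#' `backstep = 0`, or ahead, in-plane, or up to `backstep` slices behind
#' (`direction * dz >= -backstep`) otherwise. Deterministically ordered by
#' advancing `dz`, then `dy`, then `dx`.
#'
#' @param radius cap radius in voxels (1--11).
#' @param backstep see [tracking_config()].
#' @param direction `+1` (forward through the stack) or `-1` (backward).
#' @return integer matrix with columns `dx`, `dy`, `dz`.
#' @export
enumerate_endpoints <- function(radius, backstep = 0L, direction = 1L) {
  if (radius < 1 || radius > 11) stopf("radius must lie in 1..11")
  stopifnot(direction %in% c(-1L, 1L))
  r <- as.integer(radius)
  g <- as.matrix(expand.grid(dx = -r:r, dy = -r:r, dz = -r:r))
  keep <- rowSums(g^2) <= r^2 & rowSums(abs(g)) > 0
  dzmin <- if (backstep == 0) 1L else -as.integer(backstep)
  keep <- keep & (direction * g[, "dz"] >= dzmin)
  g <- g[keep, , drop = FALSE]
  g[order(direction * g[, "dz"], g[, "dy"], g[, "dx"]), , drop = FALSE]
}

#' Rasterize a 3D straight segment onto the voxel grid
#'
#' Digital differential analyzer: the continuous segment is sampled at
#' `max(|dx|, |dy|, |dz|)` equal steps and each sample rounded half-up to
#' the nearest voxel. The result starts at `a`, ends at `b`, has
#' `Chebyshev(a, b) + 1` voxels, consecutive voxels differ by at most 1 in
#' each coordinate, and `rasterize_segment(a, b)` is exactly the reverse of
#' `rasterize_segment(b, a)` (the segment is always sampled from its
#' lexicographically smaller endpoint). Half-up rounding (not banker's)
#' keeps the rasterization invariant under integer translation.
#'
#' @param a,b integer voxel coordinates (length-3).
#' @return integer matrix, one voxel per row.
#' @export
rasterize_segment <- function(a, b) {
  a <- as.numeric(a); b <- as.numeric(b)
  if (all(a == b)) stopf("degenerate segment: a == b")
  # canonical direction (lexicographically smaller endpoint first) makes the
  # reversal symmetry exact rather than subject to floating-point rounding
  # at half-integer samples
  swap <- FALSE
  d <- b - a
  first_diff <- d[which(d != 0)[1]]
  if (first_diff < 0) { tmp <- a; a <- b; b <- tmp; swap <- TRUE }
  n <- max(abs(b - a))
  out <- rnd_half_up(outer((0:n) / n, b - a) + rep(a, each = n + 1))
  if (swap) out <- out[(n + 1):1, , drop = FALSE]
  out
}

#' Grayscale variation along a candidate path
#'
#' Voxels below `cutoff` are zeroed first; the score is the sample standard
#' deviation (denominator n-1) of the masked values, and `n_black` counts
#' the zeros after masking.
#'
#' @param stack an `image_stack`.
#' @param voxels voxel matrix as from [rasterize_segment()] (>= 2 rows).
#' @param cutoff gray value in `[0, 1]`.
#' @return list with `gray_sd` and `n_black`.
#' @export
path_gray_sd <- function(stack, voxels, cutoff) {
  g <- stack_gray(stack, voxels)
  g[g < cutoff] <- 0
  list(gray_sd = stats::sd(g), n_black = sum(g == 0))
}

#' Trajectory-deviation penalties for a candidate set
#'
#' For each candidate endpoint, the deviation is the Euclidean distance from
#' the endpoint to the point the previous trajectory would reach at the same
#' step length. Deviations are min-max scaled to `[0, 1]` across the
#' candidate set and shifted by 1, so penalties lie in `[1, 2]`. On the
#' first step from a seed (no previous trajectory), or when all candidates
#' deviate equally, every penalty is 1.
#'
#' @param ends candidate endpoints (n x 3).
#' @param step_origin current point (length-3).
#' @param prev_direction unit vector of the previous step, or `NULL`.
#' @return list with `penalty` and raw `deviation` vectors.
#' @export
trajectory_penalties <- function(ends, step_origin, prev_direction = NULL) {
  ends <- matrix(ends, ncol = 3)
  if (is.null(prev_direction))
    return(list(penalty = rep(1, nrow(ends)), deviation = rep(0, nrow(ends))))
  d <- sweep(ends, 2, as.numeric(step_origin))
  len <- sqrt(rowSums(d^2))
  proj <- outer(len, as.numeric(prev_direction))
  dev <- sqrt(rowSums((d - proj)^2))
  rng <- range(dev)
  pen <- if (diff(rng) == 0) rep(1, nrow(ends)) else
    1 + (dev - rng[1]) / diff(rng)
  list(penalty = pen, deviation = dev)
}

#' Diagnostic values of a candidate set
#'
#' Gray-value SDs are scaled to `[0, 1]` across the candidate set by
#' dividing by the largest SD (an all-zero set stays zero) and multiplied
#' by `penalty^scalar`; the walk takes the candidate minimizing this value.
#' Scaling by the maximum (rather than min-max normalization) keeps the
#' scaled SD proportional to the raw SD, so the trajectory penalty can
#' genuinely trade off against grayscale variation -- under min-max scaling
#' the lowest-SD candidate would always score exactly zero and the penalty
#' could never influence the choice.
#'
#' @param gray_sds,penalties equal-length numeric vectors.
#' @param scalar penalty exponent (0 disables penalization).
#' @return numeric vector of diagnostic values.
#' @export
diagnostic_values <- function(gray_sds, penalties, scalar = 1) {
  stopifnot(length(gray_sds) == length(penalties))
  mx <- max(gray_sds)
  s <- if (mx == 0) rep(0, length(gray_sds)) else gray_sds / mx
  s * penalties^scalar
}

# Precompute cap geometry for one walk direction: every offset's rasterized
# path relative to the origin, flattened for vectorized scoring.
cap_geometry <- function(radius, backstep, direction) {
  offs <- enumerate_endpoints(radius, backstep, direction)
  paths <- lapply(seq_len(nrow(offs)), function(i) {
    p <- rasterize_segment(c(0, 0, 0), offs[i, ])
    if (any(p[1, ] != 0)) p <- p[nrow(p):1, , drop = FALSE]  # start first
    p
  })
  plen <- vapply(paths, nrow, 0L)
  list(offsets = offs,
       rel = do.call(rbind, paths),
       pid = rep(seq_len(nrow(offs)), plen),
       plen = plen,
       # the start voxel of each path is excluded from the black-voxel
       # statistics (it is the previous endpoint, bright by construction);
       # the SD is computed over the full path
       is_start = sequence(plen) == 1L)
}

#' Map of voxels a safe distance from the muscle boundary
#'
#' The muscle boundary is the set of support voxels (gray > 0) adjacent to a
#' zero voxel or a stack face. A voxel is *safe* when every voxel within
#' Euclidean distance `bound_buffer` of it lies inside the support -- an
#' erosion of the support mask by a discrete ball, equivalent to requiring
#' the distance to the nearest zero/outside voxel to exceed `bound_buffer`.
#' Step endpoints outside the safe region trigger the boundary stop
#' condition.
#'
#' @param stack an `image_stack`.
#' @param bound_buffer buffer distance in voxels (0 disables the condition:
#'   every support voxel is safe).
#' @return logical array `[height, width, n_slices]`, indexed
#'   `[y + 1, x + 1, z + 1]`.
#' @export
boundary_safe_mask <- function(stack, bound_buffer) {
  h <- stack$height; w <- stack$width; nz <- stack$n_slices
  support <- array(FALSE, dim = c(h, w, nz))
  for (z in seq_len(nz) - 1L)
    support[, , z + 1L] <- stack_slice(stack, z) > 0
  b <- as.integer(bound_buffer)
  if (b == 0) return(support)
  pad <- array(FALSE, dim = c(h, w, nz) + 2L * b)
  pad[b + seq_len(h), b + seq_len(w), b + seq_len(nz)] <- support
  ball <- enumerate_endpoints(min(b, 11L), backstep = b, direction = 1L)
  ball <- rbind(ball, -ball)
  ball <- ball[rowSums(ball^2) <= b^2, , drop = FALSE]
  ball <- unique(ball)
  safe <- support
  for (i in seq_len(nrow(ball))) {
    o <- ball[i, ]
    safe <- safe & pad[b + o[2] + seq_len(h), b + o[1] + seq_len(w),
                       b + o[3] + seq_len(nz)]
    if (!any(safe)) break
  }
  safe
}

#' One step of the tracking walk
#'
#' Projects the spherical cap of candidate paths from `current`, scores each
#' path, and returns the endpoint minimizing the diagnostic value, or a stop
#' reason. The black-voxel statistics (per-path counts and the pooled
#' fraction) run over the projected voxels beyond the current point -- the
#' start voxel is the previous endpoint and bright by construction, and
#' counting it would bound the pooled fraction away from 1 so the
#' black-fraction stop could never fire; the gray-SD score uses the full
#' path. Stop conditions, in evaluation order: no candidate endpoint
#' remains inside the stack (`stack_edge`); the black-voxel fraction pooled
#' over all candidate paths reaches `black_frac` (`black_fraction`); every
#' remaining path crosses more than `allowed_black` black voxels
#' (`black_paths`); every path surviving the black filter ends within
#' `bound_buffer` of the muscle boundary (`boundary`); the only surviving
#' candidates would retrace the walk (`retrace`). Diagnostic-value ties
#' go to the candidate with the smallest trajectory deviation, then to cap
#' enumeration order, so walks are fully deterministic.
#'
#' Two retrace rules keep walks finite when `backstep > 0` admits in-plane
#' and backward moves: a step may not turn more than `max_turn_deg` from
#' the previous step direction (a fiber can still double back gradually
#' over several steps), and a walk may not re-enter territory it claimed
#' more than `self_avoid + 1` steps earlier (see [tracking_config()]).
#'
#' @param stack an `image_stack`.
#' @param current current voxel (length-3, 0-based).
#' @param prev_direction previous unit step direction or `NULL`.
#' @param config a [tracking_config()].
#' @param safe_mask from [boundary_safe_mask()].
#' @param geom cap geometry (internal; computed from `config` when `NULL`).
#' @param direction `+1` or `-1`.
#' @param claims a claim tracker created by `new_claims()` and fed by
#'   `claim_path()` (both internal; `track_fiber` manages one per walk), or
#'   `NULL` to disable self-avoidance.
#' @return list with either `point` (the chosen endpoint) and `direction`
#'   (its unit step vector), or `stop` (the reason).
#' @export
step_walk <- function(stack, current, prev_direction, config, safe_mask,
                      geom = NULL, direction = 1L, claims = NULL) {
  if (is.null(geom))
    geom <- cap_geometry(config$radius, config$backstep, direction)
  current <- as.numeric(current)
  ends <- sweep(geom$offsets, 2, -current)
  inext <- ends[, 1] >= 0 & ends[, 1] < stack$width &
           ends[, 2] >= 0 & ends[, 2] < stack$height &
           ends[, 3] >= 0 & ends[, 3] < stack$n_slices
  if (!any(inext)) return(list(stop = "stack_edge"))
  if (is.null(prev_direction)) {
    # first step from a seed: no trajectory exists yet, so the walk's
    # direction identity comes from a strictly advancing step; in-plane and
    # backward offsets open up once a trajectory is established
    adv <- inext & (direction * geom$offsets[, "dz"] >= 1)
    if (any(adv)) inext <- adv
  } else {
    dotp <- (geom$offsets %*% as.numeric(prev_direction))[, 1]
    inext <- inext & dotp >= cos(config$max_turn_deg * pi / 180) *
      sqrt(rowSums(geom$offsets^2))
  }
  if (!is.null(claims) && any(inext)) {
    w <- which(inext)
    st <- claims$stamp[cbind(ends[w, 2] + 1L, ends[w, 1] + 1L,
                             ends[w, 3] + 1L)]
    inext[w] <- !(st > 0L & st <= claims$step - claims$lag)
  }
  if (!any(inext)) return(list(stop = "retrace"))
  cand <- which(inext)
  vox_keep <- geom$pid %in% cand
  vox <- sweep(geom$rel[vox_keep, , drop = FALSE], 2, -current)
  pid <- geom$pid[vox_keep]
  g <- stack_gray(stack, vox)
  g[g < config$cutoff] <- 0
  # black statistics run over the projected voxels only (the start voxel is
  # the previous endpoint and always bright); the SD uses the full path
  fwd <- !geom$is_start[vox_keep]
  # condition 2: pooled black fraction across every candidate path
  if (sum(g[fwd] == 0) / sum(fwd) >= config$black_frac)
    return(list(stop = "black_fraction"))
  grp <- match(pid, cand)
  n <- as.numeric(geom$plen[cand])
  nb <- rowsum(as.numeric(g == 0 & fwd), grp)[, 1]
  ok_black <- nb <= config$allowed_black          # condition 1
  safe <- safe_mask[cbind(ends[cand, 2] + 1L, ends[cand, 1] + 1L,
                          ends[cand, 3] + 1L)]    # condition 3
  valid <- ok_black & safe
  if (!any(valid))
    return(list(stop = if (any(ok_black)) "boundary" else "black_paths"))
  s1 <- rowsum(g, grp)[, 1]
  s2 <- rowsum(g^2, grp)[, 1]
  sds <- sqrt(pmax(0, (s2 - s1^2 / n) / (n - 1)))
  vi <- cand[valid]
  tp <- trajectory_penalties(ends[vi, , drop = FALSE], current, prev_direction)
  vals <- diagnostic_values(sds[valid], tp$penalty, config$scalar)
  best <- order(vals, tp$deviation)[1]
  pt <- ends[vi[best], ]
  step <- pt - current
  list(point = as.numeric(pt), direction = step / sqrt(sum(step^2)))
}

# Self-avoidance bookkeeping: stamp[v] records the step at which voxel v was
# first claimed (0 = unclaimed). A step claims its rasterized path dilated by
# a ball of radius `self_avoid`; earlier claims are never overwritten, so the
# corridor just ahead of the walk head always carries recent stamps and stays
# open, while territory from earlier passes is blocked after `lag` steps.
new_claims <- function(stack, self_avoid) {
  if (self_avoid <= 0) return(NULL)
  cl <- new.env(parent = emptyenv())
  cl$stamp <- array(0L, dim = c(stack$height, stack$width, stack$n_slices))
  cl$step <- 1L
  cl$lag <- floor(self_avoid) + 1L
  b <- ceiling(self_avoid)
  ball <- as.matrix(expand.grid(dx = -b:b, dy = -b:b, dz = -b:b))
  cl$ball <- ball[rowSums(ball^2) <= self_avoid^2, , drop = FALSE]
  cl$dims <- dim(cl$stamp)
  cl
}

claim_path <- function(claims, path) {
  if (is.null(claims)) return(invisible(NULL))
  vox <- unique(path[rep(seq_len(nrow(path)), each = nrow(claims$ball)), ] +
                  claims$ball[rep(seq_len(nrow(claims$ball)), nrow(path)), ])
  keep <- vox[, 1] >= 0 & vox[, 1] < claims$dims[2] &
          vox[, 2] >= 0 & vox[, 2] < claims$dims[1] &
          vox[, 3] >= 0 & vox[, 3] < claims$dims[3]
  idx <- cbind(vox[keep, 2] + 1L, vox[keep, 1] + 1L, vox[keep, 3] + 1L)
  st <- claims$stamp[idx]
  fresh <- st == 0L
  if (any(fresh)) claims$stamp[idx[fresh, , drop = FALSE]] <- claims$step
  claims$step <- claims$step + 1L
  invisible(NULL)
}

walk_one_way <- function(stack, seed, config, safe_mask, geom, direction,
                         claims = NULL) {
  pts <- NULL
  current <- as.numeric(seed)
  prev_dir <- NULL
  reason <- "max_steps"
  for (i in seq_len(config$max_steps)) {
    st <- step_walk(stack, current, prev_dir, config, safe_mask, geom,
                    direction, claims)
    if (!is.null(st$stop)) { reason <- st$stop; break }
    if (!is.null(claims))
      claim_path(claims, rasterize_segment(current, st$point))
    pts <- rbind(pts, st$point)
    current <- st$point
    prev_dir <- st$direction
  }
  list(points = pts, reason = reason)
}

#' Track one fiber from a seed point
#'
#' Walks forward through the stack from the seed until a stop condition
#' fires, returns to the seed and walks backward with identical parameters,
#' then merges `reverse(backward) + seed + forward` into one stepwise track.
#' Seeds on post-cutoff black voxels, and merged tracks shorter than
#' `min_track_points`, produce no fiber (`NULL`).
#'
#' @inheritParams step_walk
#' @param seed voxel coordinate (length-3, 0-based).
#' @param geom_fwd,geom_bwd precomputed cap geometries (internal).
#' @return an object of class `fiber_track` (fields `seed`, `points`,
#'   `gray`, `stop_fwd`, `stop_bwd`) or `NULL` for a dropped seed.
#' @export
track_fiber <- function(stack, seed, config, safe_mask = NULL,
                        geom_fwd = NULL, geom_bwd = NULL) {
  seed <- as.numeric(seed)
  if (is.null(safe_mask)) safe_mask <- boundary_safe_mask(stack, config$bound_buffer)
  if (is.null(geom_fwd)) geom_fwd <- cap_geometry(config$radius, config$backstep, 1L)
  if (is.null(geom_bwd)) geom_bwd <- cap_geometry(config$radius, config$backstep, -1L)
  if (stack_gray(stack, matrix(seed, 1)) < config$cutoff) return(NULL)
  # one claim tracker for both walks: the backward walk may not re-track the
  # territory the forward walk already covered
  claims <- new_claims(stack, config$self_avoid)
  claim_path(claims, matrix(seed, 1))
  fwd <- walk_one_way(stack, seed, config, safe_mask, geom_fwd, 1L, claims)
  bwd <- walk_one_way(stack, seed, config, safe_mask, geom_bwd, -1L, claims)
  pts <- rbind(if (!is.null(bwd$points)) bwd$points[rev(seq_len(nrow(bwd$points))), , drop = FALSE],
               matrix(seed, 1), fwd$points)
  rownames(pts) <- NULL
  if (nrow(pts) < config$min_track_points) return(NULL)
  structure(list(seed = seed, points = pts, gray = stack_gray(stack, pts),
                 stop_fwd = fwd$reason, stop_bwd = bwd$reason),
            class = "fiber_track")
}

#' @export
print.fiber_track <- function(x, ...) {
  cat(sprintf("fiber_track: %d points, seed (%s), stops fwd=%s bwd=%s\n",
              nrow(x$points), paste(x$seed, collapse = ", "),
              x$stop_fwd, x$stop_bwd))
  invisible(x)
}

#' Track muscle fibers through a whole stack
#'
#' The full tracking stage: seeds are planned by UPGMA clustering in the
#' configured planes (see [plan_seeds()]), and a fiber is walked from each
#' seed with [track_fiber()]. During each walk at most
#' `radius + backstep + 1` decoded slices are held in memory (the slice
#' cache is capped accordingly for file-backed stacks), so arbitrarily deep
#' stacks can be tracked at a flat memory cost. The number of fibers
#' returned is at most the number of seeds; seeds in noise with no pathway
#' are dropped.
#'
#' @param stack an `image_stack`.
#' @param config a [tracking_config()]; `config$planes` must be set.
#' @return a [fiber_set()] holding the raw tracks (not yet smoothed).
#' @export
track_fibers <- function(stack, config) {
  if (is.null(config$planes)) stopf("config$planes must name the seed planes")
  old_limit <- stack$cache$limit
  stack_cache_limit(stack, config$radius + config$backstep + 1L)
  on.exit(stack_cache_limit(stack, old_limit))
  safe_mask <- boundary_safe_mask(stack, config$bound_buffer)
  seeds <- plan_seeds(stack, config$planes, config$seeds_per_plane,
                      config$threshold, config$start_seed)
  geom_fwd <- cap_geometry(config$radius, config$backstep, 1L)
  geom_bwd <- cap_geometry(config$radius, config$backstep, -1L)
  tracks <- list()
  dropped <- 0L
  cache_peak <- 0L
  if (nrow(seeds) == 0) warnf("no seeds found; empty fiber set")
  for (i in seq_len(nrow(seeds))) {
    stack_cache_reset(stack)
    tr <- track_fiber(stack, seeds[i, ], config, safe_mask, geom_fwd, geom_bwd)
    cache_peak <- max(cache_peak, stack_cache_stats(stack)$peak)
    if (is.null(tr)) dropped <- dropped + 1L else tracks[[length(tracks) + 1L]] <- tr
  }
  out <- fiber_set(tracks, config = config, offsets = stack$offsets,
                   log = sprintf("%d seeds planned, %d fibers tracked, %d seeds dropped",
                                 nrow(seeds), length(tracks), dropped))
  # peak decoded slices resident during any single walk (file-backed stacks)
  out$cache_peak <- cache_peak
  out
}
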