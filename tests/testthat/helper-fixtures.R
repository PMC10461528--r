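# Shared fixtures and independent oracles, built in code at test time.

# Small in-memory stack from a function of (x, y, z), 0-based coords.
make_stack <- function(w, h, nz, f) {
  a <- array(0, dim = c(h, w, nz))
  for (z in 0:(nz - 1)) for (y in 0:(h - 1))
    a[y + 1, , z + 1] <- vapply(0:(w - 1), function(x) f(x, y, z), 0)
  as_image_stack(a)
}

# Memoized small straight-tube phantom shared by several test files.
small_phantom <- local({
  cache <- NULL
  function() {
    if (is.null(cache))
      cache <<- generate_phantom(phantom_spec(n_fibers = 4, length = 40,
                                              seed = 7))
    cache
  }
})

# --- Independent oracles -------------------------------------------------

# Brute-force spherical-cap enumeration by explicit triple loop.
oracle_endpoints <- function(radius, backstep, direction) {
  out <- NULL
  dzmin <- if (backstep == 0) 1L else -backstep
  for (dz in -radius:radius) for (dy in -radius:radius)
    for (dx in -radius:radius) {
      if (dx == 0 && dy == 0 && dz == 0) next
      if (dx^2 + dy^2 + dz^2 > radius^2) next
      if (direction * dz < dzmin) next
      out <- rbind(out, c(dx, dy, dz))
    }
  out
}

# Step-by-step DDA line oracle (sampled from the lexicographically smaller
# endpoint, half-up rounding).
oracle_raster <- function(a, b) {
  d <- b - a
  if (d[which(d != 0)[1]] < 0) return(oracle_raster(b, a)[(max(abs(d)) + 1):1, ])
  n <- max(abs(b - a))
  t(vapply(0:n, function(k) floor(a + k / n * (b - a) + 0.5), numeric(3)))
}

# Naive average-linkage clustering; returns the partition at k clusters as a
# list of sorted index vectors (order-independent comparison).
oracle_upgma <- function(pts, k) {
  clusters <- as.list(seq_len(nrow(pts)))
  d <- as.matrix(stats::dist(pts))
  while (length(clusters) > k) {
    best <- c(Inf, NA, NA)
    for (i in seq_along(clusters)) for (j in seq_along(clusters)) {
      if (j <= i) next
      dij <- mean(d[clusters[[i]], clusters[[j]]])
      if (dij < best[1]) best <- c(dij, i, j)
    }
    clusters[[best[2]]] <- c(clusters[[best[2]]], clusters[[best[3]]])
    clusters[[best[3]]] <- NULL
  }
  unname(lapply(clusters, sort))
}

partition_of <- function(labels) {
  unname(lapply(split(seq_along(labels), labels), sort))
}

same_partition <- function(a, b) {
  key <- function(p) sort(vapply(p, function(v) paste(v, collapse = ","), ""))
  identical(key(a), key(b))
}

# Exhaustive scorer: an independent reimplementation of one tracking step
# with plain loops, sharing only the claim bookkeeping with the package.
oracle_step <- function(stack, current, prev_dir, config, safe_mask,
                        direction, claims = NULL) {
  offs <- oracle_endpoints(config$radius, config$backstep, direction)
  keep <- rep(TRUE, nrow(offs))
  for (i in seq_len(nrow(offs))) {
    e <- current + offs[i, ]
    if (e[1] < 0 || e[1] >= stack$width || e[2] < 0 || e[2] >= stack$height ||
        e[3] < 0 || e[3] >= stack$n_slices) keep[i] <- FALSE
  }
  if (!any(keep)) return(list(stop = "stack_edge"))
  if (is.null(prev_dir)) {
    adv <- keep & (direction * offs[, 3] >= 1)
    if (any(adv)) keep <- adv
  } else {
    for (i in which(keep))
      if (sum(offs[i, ] * prev_dir) <
          cos(config$max_turn_deg * pi / 180) * sqrt(sum(offs[i, ]^2)))
        keep[i] <- FALSE
  }
  if (!is.null(claims)) for (i in which(keep)) {
    e <- current + offs[i, ]
    st <- claims$stamp[e[2] + 1, e[1] + 1, e[3] + 1]
    if (st > 0 && st <= claims$step - claims$lag) keep[i] <- FALSE
  }
  if (!any(keep)) return(list(stop = "retrace"))
  cand <- which(keep)
  grays <- lapply(cand, function(i) {
    vox <- oracle_raster(current, current + offs[i, ])
    if (any(vox[1, ] != current)) vox <- vox[nrow(vox):1, ]
    g <- vapply(seq_len(nrow(vox)), function(r)
      stack_slice(stack, vox[r, 3])[vox[r, 2] + 1, vox[r, 1] + 1], 0)
    g[g < config$cutoff] <- 0
    g
  })
  # black statistics exclude each path's start voxel; the SD does not
  allg <- unlist(lapply(grays, `[`, -1))
  if (sum(allg == 0) / length(allg) >= config$black_frac)
    return(list(stop = "black_fraction"))
  nb <- vapply(grays, function(g) sum(g[-1] == 0), 0)
  ok_black <- nb <= config$allowed_black
  safe <- vapply(cand, function(i) {
    e <- current + offs[i, ]
    safe_mask[e[2] + 1, e[1] + 1, e[3] + 1]
  }, TRUE)
  valid <- ok_black & safe
  if (!any(valid))
    return(list(stop = if (any(ok_black)) "boundary" else "black_paths"))
  sds <- vapply(grays, stats::sd, 0)
  vi <- cand[valid]
  dev <- rep(0, length(vi))
  if (!is.null(prev_dir)) {
    for (j in seq_along(vi)) {
      step <- offs[vi[j], ]
      dev[j] <- sqrt(sum((step - sqrt(sum(step^2)) * prev_dir)^2))
    }
  }
  pen <- if (is.null(prev_dir) || diff(range(dev)) == 0) rep(1, length(vi))
         else 1 + (dev - min(dev)) / diff(range(dev))
  sdv <- sds[valid]
  sc <- if (max(sdv) == 0) rep(0, length(vi)) else sdv / max(sdv)
  vals <- sc * pen^config$scalar
  best <- order(vals, dev)[1]
  pt <- current + offs[vi[best], ]
  list(point = as.numeric(pt),
       direction = offs[vi[best], ] / sqrt(sum(offs[vi[best], ]^2)))
}

# Smooth random 20^3 test volumes: white noise blurred by neighbour
# averaging, rescaled to [0, 1].
random_blob_stack <- function(n = 20, passes = 3) {
  a <- array(stats::runif(n^3), dim = c(n, n, n))
  for (p in seq_len(passes)) {
    b <- a
    b[2:(n - 1), , ] <- (a[1:(n - 2), , ] + a[2:(n - 1), , ] + a[3:n, , ]) / 3
    a <- b
    b[, 2:(n - 1), ] <- (a[, 1:(n - 2), ] + a[, 2:(n - 1), ] + a[, 3:n, ]) / 3
    a <- b
    b[, , 2:(n - 1)] <- (a[, , 1:(n - 2)] + a[, , 2:(n - 1)] + a[, , 3:n]) / 3
    a <- b
  }
  a <- (a - min(a)) / (max(a) - min(a))
  as_image_stack(a)
}

# Undirected edge multiset of an STL triangle soup (for topology checks).
stl_edges <- function(tris) {
  key <- function(v) paste(signif(v, 7), collapse = ",")
  edges <- character()
  for (tri in tris) {
    vk <- vapply(1:3, function(i) key(tri[i, ]), "")
    for (p in list(c(1, 2), c(2, 3), c(3, 1)))
      edges <- c(edges, paste(sort(vk[p]), collapse = "|"))
  }
  edges
}

# Fabricate a smoothed_fiber directly from analytic dense points (for
# metric and export tests that do not need a tracked origin).
fake_fiber <- function(dense, id = 1L) {
  structure(list(id = id, source_ids = id, df = 1L,
                 points = dense, gray = rep(0.8, nrow(dense)),
                 dense_points = dense, mean_residual = 0,
                 quality_ratio = 1e-4,
                 raw_length = sum(sqrt(rowSums(diff(dense)^2)))),
            class = "smoothed_fiber")
}

fake_set <- function(fibers) {
  s <- fiber_set(list(), config = NULL, offsets = c(0, 0, 0))
  s$fibers <- fibers
  s$groups <- rep("muscle", length(fibers))
  s
}
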