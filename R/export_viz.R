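#' Sweep a polyline into a closed tube mesh
#'
#' Cross-section frames follow the curve by parallel transport (the normal
#' is rotated by the minimal rotation taking each tangent to the next), so
#' tubes do not twist at inflections. With `s` segments and `c` sides the
#' tube has `2*c*s` wall triangles plus two `c`-triangle cap fans.
#'
#' @param pts polyline vertices (n x 3, n >= 2).
#' @param radius tube radius.
#' @param n_sides cross-section vertex count (>= 3).
#' @return list `vertices` (one row per triangle corner, 9 columns per
#'   triangle flattened as v1,v2,v3) -- internally a `n_tri x 9` matrix.
#' @keywords internal
tube_mesh <- function(pts, radius, n_sides) {
  n <- nrow(pts)
  segs <- diff(pts)
  keep <- rowSums(segs^2) > 0
  pts <- pts[c(TRUE, keep), , drop = FALSE]
  n <- nrow(pts)
  segs <- diff(pts)
  tans <- segs / sqrt(rowSums(segs^2))
  tans <- rbind(tans, tans[nrow(tans), ])
  # vertex tangents: average adjacent segment tangents
  vt <- tans
  if (n > 2) vt[2:(n - 1), ] <- (tans[1:(n - 2), ] + tans[2:(n - 1), ])
  vt <- vt / sqrt(rowSums(vt^2))
  # parallel-transport frames
  ref <- c(1, 0, 0)
  if (abs(sum(ref * vt[1, ])) > 0.9) ref <- c(0, 1, 0)
  nrm <- ref - sum(ref * vt[1, ]) * vt[1, ]
  nrm <- nrm / sqrt(sum(nrm^2))
  normals <- matrix(0, n, 3)
  normals[1, ] <- nrm
  for (i in 2:n) {
    a <- vt[i - 1, ]; b <- vt[i, ]
    v <- c(a[2] * b[3] - a[3] * b[2], a[3] * b[1] - a[1] * b[3],
           a[1] * b[2] - a[2] * b[1])
    s2 <- sum(v^2)
    if (s2 < 1e-20) { normals[i, ] <- nrm } else {
      cth <- sum(a * b)
      # Rodrigues rotation of nrm about v
      k <- v / sqrt(s2)
      sth <- sqrt(s2)
      nrm <- nrm * cth + c(k[2] * nrm[3] - k[3] * nrm[2],
                           k[3] * nrm[1] - k[1] * nrm[3],
                           k[1] * nrm[2] - k[2] * nrm[1]) * sth +
        k * sum(k * nrm) * (1 - cth)
      nrm <- nrm - sum(nrm * b) * b
      nrm <- nrm / sqrt(sum(nrm^2))
      normals[i, ] <- nrm
    }
  }
  phi <- 2 * pi * (seq_len(n_sides) - 1) / n_sides
  rings <- lapply(seq_len(n), function(i) {
    b <- c(vt[i, 2] * normals[i, 3] - vt[i, 3] * normals[i, 2],
           vt[i, 3] * normals[i, 1] - vt[i, 1] * normals[i, 3],
           vt[i, 1] * normals[i, 2] - vt[i, 2] * normals[i, 1])
    outer(cos(phi), normals[i, ]) * radius + outer(sin(phi), b) * radius +
      matrix(pts[i, ], n_sides, 3, byrow = TRUE)
  })
  tri <- vector("list", 2 * n_sides * (n - 1) + 2 * n_sides)
  t_i <- 0L
  nxt <- c(seq_len(n_sides)[-1], 1L)
  for (i in seq_len(n - 1)) {
    r1 <- rings[[i]]; r2 <- rings[[i + 1]]
    for (k in seq_len(n_sides)) {
      t_i <- t_i + 1L; tri[[t_i]] <- rbind(r1[k, ], r2[k, ], r2[nxt[k], ])
      t_i <- t_i + 1L; tri[[t_i]] <- rbind(r1[k, ], r2[nxt[k], ], r1[nxt[k], ])
    }
  }
  for (k in seq_len(n_sides)) {  # start cap (fan, outward = -tangent)
    t_i <- t_i + 1L
    tri[[t_i]] <- rbind(pts[1, ], rings[[1]][nxt[k], ], rings[[1]][k, ])
  }
  for (k in seq_len(n_sides)) {  # end cap
    t_i <- t_i + 1L
    tri[[t_i]] <- rbind(pts[n, ], rings[[n]][k, ], rings[[n]][nxt[k], ])
  }
  tri
}

#' Export a fiber set as an STL tube mesh
#'
#' Each smoothed fiber is swept as a closed tube of radius `tube_radius`
#' with `n_sides`-gon cross-sections along its dense curve and written to
#' one STL file (binary by default). When `res` is given every coordinate is
#' multiplied by it, so the mesh is at the physical scale of the original
#' scan. Fibers with fewer than 2 distinct dense points are skipped with a
#' warning.
#'
#' @param set a smoothed, nonempty [fiber_set()].
#' @param path output `.stl` file.
#' @param tube_radius tube radius in voxels (scaled by `res` like the
#'   coordinates).
#' @param n_sides cross-section vertex count (>= 3).
#' @param res physical size per voxel, or `NULL` to stay in voxel units.
#' @param ascii write ASCII STL instead of binary.
#' @return invisibly, a list with `path`, `n_triangles` and
#'   `triangles_per_fiber`.
#' @export
export_stl <- function(set, path, tube_radius = 1, n_sides = 8L, res = NULL,
                       ascii = FALSE) {
  if (length(set$fibers) == 0) stopf("cannot export an empty fiber set")
  stopifnot(tube_radius > 0, n_sides >= 3)
  scale <- res %||% 1
  tris <- list()
  per_fiber <- integer()
  for (f in set$fibers) {
    dp <- unique(f$dense_points)
    if (nrow(dp) < 2) {
      warnf("skipping degenerate fiber %s (single point)",
            paste(f$source_ids, collapse = "+"))
      next
    }
    tf <- tube_mesh(dp * scale, tube_radius * scale, as.integer(n_sides))
    tris <- c(tris, tf)
    per_fiber <- c(per_fiber, length(tf))
  }
  if (length(tris) == 0) stopf("no non-degenerate fibers to export")
  if (ascii) write_stl_ascii(tris, path) else write_stl_binary(tris, path)
  invisible(list(path = path, n_triangles = length(tris),
                 triangles_per_fiber = per_fiber))
}

facet_normal <- function(tri) {
  u <- tri[2, ] - tri[1, ]; v <- tri[3, ] - tri[1, ]
  n <- c(u[2] * v[3] - u[3] * v[2], u[3] * v[1] - u[1] * v[3],
         u[1] * v[2] - u[2] * v[1])
  l <- sqrt(sum(n^2))
  if (l > 0) n / l else c(0, 0, 0)
}

write_stl_binary <- function(tris, path) {
  con <- file(path, "wb")
  on.exit(close(con))
  hdr <- charToRaw(sprintf("%-80s", "myotrace fiber tube mesh"))[1:80]
  writeBin(hdr, con)
  writeBin(as.integer(length(tris)), con, size = 4, endian = "little")
  for (tri in tris) {
    writeBin(as.numeric(c(facet_normal(tri), t(tri))), con, size = 4,
             endian = "little")
    writeBin(as.integer(0), con, size = 2, endian = "little")
  }
  invisible(path)
}

write_stl_ascii <- function(tris, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("solid myotrace", con)
  for (tri in tris) {
    n <- facet_normal(tri)
    writeLines(sprintf("  facet normal %.9g %.9g %.9g", n[1], n[2], n[3]), con)
    writeLines("    outer loop", con)
    for (i in 1:3)
      writeLines(sprintf("      vertex %.9g %.9g %.9g",
                         tri[i, 1], tri[i, 2], tri[i, 3]), con)
    writeLines("    endloop", con)
    writeLines("  endfacet", con)
  }
  writeLines("endsolid myotrace", con)
  invisible(path)
}

#' Read a binary STL file
#'
#' Minimal parser for validating exported meshes (triangle counts, vertex
#' round trips, topology).
#'
#' @param path a binary STL file.
#' @return list with `n_triangles` and `triangles` (list of 3 x 3 vertex
#'   matrices).
#' @export
read_stl <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  readBin(con, "raw", 80)
  n <- readBin(con, "integer", 1, size = 4, endian = "little")
  tris <- vector("list", n)
  for (i in seq_len(n)) {
    vals <- readBin(con, "numeric", 12, size = 4, endian = "little")
    readBin(con, "raw", 2)
    tris[[i]] <- matrix(vals[4:12], 3, 3, byrow = TRUE)
  }
  list(n_triangles = n, triangles = tris)
}

#' Combine fiber sets from several muscles
#'
#' Sets must already be realigned into the original scan frame (see
#' [realign()]); a warning is raised when a set still carries nonzero crop
#' offsets. Group labels are preserved (they drive coloring in
#' [render_figure()]) and fiber ids are made unique.
#'
#' @param ... two or more [fiber_set()] objects (a single set is returned
#'   unchanged).
#' @return one combined `fiber_set`.
#' @export
combine_sets <- function(...) {
  sets <- list(...)
  if (length(sets) == 1 && is.list(sets[[1]]) && !inherits(sets[[1]], "fiber_set"))
    sets <- sets[[1]]
  stopifnot(all(vapply(sets, inherits, TRUE, "fiber_set")))
  if (length(sets) == 1) return(sets[[1]])
  for (s in sets)
    if (any(s$offsets != 0))
      warnf("combining a set with nonzero offsets (%s); realign() first for a shared frame",
            paste(s$offsets, collapse = ", "))
  out <- sets[[1]]
  out$tracks <- do.call(c, lapply(sets, `[[`, "tracks"))
  out$fibers <- do.call(c, lapply(sets, `[[`, "fibers"))
  out$groups <- do.call(c, lapply(sets, `[[`, "groups"))
  out$log <- do.call(c, lapply(sets, `[[`, "log"))
  for (i in seq_along(out$fibers)) out$fibers[[i]]$id <- i
  out$offsets <- c(0, 0, 0)
  out
}

# Fixed orthographic projection used for static 3D renders.
project_3d <- function(m, theta = 30, phi = 20) {
  th <- theta * pi / 180; ph <- phi * pi / 180
  x <- m[, 1] * cos(th) - m[, 2] * sin(th)
  yy <- m[, 1] * sin(th) + m[, 2] * cos(th)
  cbind(u = x, v = m[, 3] * cos(ph) - yy * sin(ph))
}

#' Render a fiber set to a static 3D figure
#'
#' Orthographic line render of the smoothed fibers, colored by muscle group
#' or by a per-fiber metric, with a legend. Static output keeps rendering
#' reproducible and headless-safe; for interactive inspection export an STL
#' and open it in a mesh viewer.
#'
#' @param set a smoothed, nonempty [fiber_set()].
#' @param color_by `"group"`, `"length"` or `"angle"`.
#' @param path optional PNG file; when `NULL`, draws on the current device.
#' @param theta,phi view angles in degrees.
#' @return invisibly, the per-fiber colors used.
#' @export
render_figure <- function(set, color_by = c("group", "length", "angle"),
                          path = NULL, theta = 30, phi = 20) {
  color_by <- match.arg(color_by)
  if (length(set$fibers) == 0) stopf("cannot render an empty fiber set")
  nf <- length(set$fibers)
  if (color_by == "group") {
    gr <- factor(set$groups)
    pal <- grDevices::hcl.colors(max(2L, nlevels(gr)), "Dark 3")
    cols <- pal[as.integer(gr)]
    leg <- levels(gr); leg_col <- pal[seq_len(nlevels(gr))]
  } else {
    vals <- if (color_by == "length") vapply(set$fibers, fiber_length, 0)
            else vapply(set$fibers, fiber_angle, 0)
    ramp <- grDevices::hcl.colors(101, "Viridis")
    rngv <- range(vals)
    idx <- if (diff(rngv) == 0) rep(51L, nf) else
      1L + round(100 * (vals - rngv[1]) / diff(rngv))
    cols <- ramp[idx]
    leg <- sprintf("%.3g", seq(rngv[1], rngv[2], length.out = 5))
    leg_col <- ramp[c(1, 26, 51, 76, 101)]
  }
  if (!is.null(path)) {
    grDevices::png(path, width = 900, height = 700)
    on.exit(grDevices::dev.off())
  }
  proj <- lapply(set$fibers, function(f) project_3d(f$dense_points, theta, phi))
  all_uv <- do.call(rbind, proj)
  graphics::plot(NA, xlim = range(all_uv[, 1]), ylim = range(all_uv[, 2]),
                 asp = 1, xlab = "", ylab = "", axes = FALSE,
                 main = sprintf("fibers colored by %s", color_by))
  for (i in seq_len(nf))
    graphics::lines(proj[[i]][, 1], proj[[i]][, 2], col = cols[i], lwd = 2)
  graphics::legend("topright", legend = leg, col = leg_col, lwd = 3,
                   bty = "n", title = color_by, cex = 0.8)
  invisible(cols)
}

#' @export
plot.fiber_set <- function(x, color_by = "group", ...) {
  render_figure(x, color_by = color_by, path = NULL, ...)
}
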