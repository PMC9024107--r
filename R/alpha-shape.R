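# Alpha shapes of 2D point clouds: Delaunay triangles retained when their
# circumradius does not exceed the probe radius alpha (in nm, the
# coordinate unit), split into connected components with boundary polygons
# and areas.

#' Alpha shape of a point set
#'
#' A Delaunay triangle belongs to the shape iff its circumradius is at most
#' `alpha` (the probe radius in coordinate units). Connected components are
#' reported separately; the area is the total area of retained triangles.
#' With `alpha = Inf` the shape is the convex hull.
#'
#' @param points Two-column matrix or data.frame of coordinates, nm.
#' @param alpha Probe radius, nm.
#' @return An object of class `alpha_shape`: `points`, `triangles` (index
#'   matrix of retained triangles), `component` (component id per retained
#'   triangle), `area` (total), `component_areas`, `boundaries` (list per
#'   component of closed boundary loops, counter-clockwise coordinate
#'   matrices), `degenerate` flag. Fewer than 3 points, collinear input or
#'   no retained triangle yield a degenerate zero-area shape.
#' @export
alpha_shape <- function(points, alpha) {
  stopifnot(alpha > 0)
  pts <- as.matrix(points)[, 1:2, drop = FALSE]
  storage.mode(pts) <- "double"
  empty <- structure(list(points = pts,
                          triangles = matrix(integer(0), 0, 3),
                          component = integer(0), area = 0,
                          component_areas = numeric(0),
                          boundaries = list(), degenerate = TRUE),
                     class = "alpha_shape")
  if (nrow(pts) < 3) return(empty)
  tri <- .delaunay_cpp(pts[, 1], pts[, 2])
  if (nrow(tri) == 0) return(empty)
  tri <- .convexify_triangles(pts, tri)
  geom <- .tri_geometry(pts, tri)
  keep <- is.finite(geom$circumradius) & geom$circumradius <= alpha &
    geom$area > 0
  if (!any(keep)) return(empty)
  tri <- tri[keep, , drop = FALSE]
  areas <- geom$area[keep]
  comp <- .tri_components(tri)
  ids <- sort(unique(comp))
  comp <- match(comp, ids)
  comp_areas <- vapply(seq_along(ids), function(k) sum(areas[comp == k]),
                       numeric(1))
  boundaries <- lapply(seq_along(ids), function(k)
    .boundary_loops(pts, tri[comp == k, , drop = FALSE]))
  structure(list(points = pts, triangles = tri, component = comp,
                 area = sum(areas), component_areas = comp_areas,
                 boundaries = boundaries, degenerate = FALSE),
            class = "alpha_shape")
}

# Bowyer-Watson with a finite super-triangle can miss near-degenerate hull
# slivers whose circumcircles reach the super vertices; restore them by
# adding ear triangles along concave stretches of the outer boundary. Their
# circumradii are computed normally, so finite-alpha results are unchanged
# (such slivers never pass a data-scale alpha).
.convexify_triangles <- function(pts, tri) {
  loop <- .outer_index_loop(pts, tri)
  if (length(loop) < 4) return(tri)
  extra <- list()
  repeat {
    n <- length(loop)
    if (n < 4) break
    changed <- FALSE
    i <- 1L
    while (i <= length(loop) && length(loop) >= 4) {
      n <- length(loop)
      a <- loop[i]; b <- loop[(i %% n) + 1L]; c <- loop[((i + 1L) %% n) + 1L]
      cr <- (pts[b, 1] - pts[a, 1]) * (pts[c, 2] - pts[b, 2]) -
        (pts[b, 2] - pts[a, 2]) * (pts[c, 1] - pts[b, 1])
      if (cr < 0) {  # concave turn on a CCW outer boundary: missing ear
        extra[[length(extra) + 1L]] <- c(a, b, c)
        loop <- loop[-((i %% n) + 1L)]
        changed <- TRUE
      } else i <- i + 1L
    }
    if (!changed) break
  }
  if (length(extra)) tri <- rbind(tri, do.call(rbind, extra))
  tri
}

# outer boundary of a triangle set as a CCW loop of vertex indices
.outer_index_loop <- function(pts, tri) {
  area2 <- (pts[tri[, 2], 1] - pts[tri[, 1], 1]) *
    (pts[tri[, 3], 2] - pts[tri[, 1], 2]) -
    (pts[tri[, 2], 2] - pts[tri[, 1], 2]) *
    (pts[tri[, 3], 1] - pts[tri[, 1], 1])
  t2 <- tri
  flip <- area2 < 0
  t2[flip, c(2, 3)] <- tri[flip, c(3, 2)]
  e <- rbind(t2[, c(1, 2)], t2[, c(2, 3)], t2[, c(3, 1)])
  und <- paste0(pmin(e[, 1], e[, 2]), "_", pmax(e[, 1], e[, 2]))
  be <- e[und %in% names(which(table(und) == 1)), , drop = FALSE]
  if (!nrow(be)) return(integer(0))
  loops <- list()
  used <- rep(FALSE, nrow(be))
  nxt <- split(seq_len(nrow(be)), be[, 1])
  while (any(!used)) {
    start <- which(!used)[1]
    loop <- be[start, 1]
    cur <- start
    repeat {
      used[cur] <- TRUE
      v <- be[cur, 2]
      if (v == loop[1]) break
      loop <- c(loop, v)
      cands <- nxt[[as.character(v)]]
      cands <- cands[!used[cands]]
      if (!length(cands)) break
      cur <- cands[1]
    }
    loops[[length(loops) + 1L]] <- loop
  }
  loop_area <- function(ix) {
    j <- c(ix[-1], ix[1])
    abs(sum(pts[ix, 1] * pts[j, 2] - pts[j, 1] * pts[ix, 2])) / 2
  }
  loops[[which.max(vapply(loops, loop_area, numeric(1)))]]
}

# per-triangle signed area (made positive) and circumradius
.tri_geometry <- function(pts, tri) {
  ax <- pts[tri[, 1], 1]; ay <- pts[tri[, 1], 2]
  bx <- pts[tri[, 2], 1]; by <- pts[tri[, 2], 2]
  cx <- pts[tri[, 3], 1]; cy <- pts[tri[, 3], 2]
  area2 <- (bx - ax) * (cy - ay) - (by - ay) * (cx - ax)
  area <- abs(area2) / 2
  la <- sqrt((bx - cx)^2 + (by - cy)^2)
  lb <- sqrt((ax - cx)^2 + (ay - cy)^2)
  lc <- sqrt((ax - bx)^2 + (ay - by)^2)
  R <- ifelse(area > 0, la * lb * lc / (4 * area), Inf)
  list(area = area, circumradius = R)
}

# connected components of triangles sharing an edge (union-find)
.tri_components <- function(tri) {
  n <- nrow(tri)
  parent <- seq_len(n)
  find <- function(i) { while (parent[i] != i) i <- parent[i]; i }
  ekey <- function(a, b) paste0(pmin(a, b), "_", pmax(a, b))
  keys <- c(ekey(tri[, 1], tri[, 2]), ekey(tri[, 2], tri[, 3]),
            ekey(tri[, 3], tri[, 1]))
  owner <- rep(seq_len(n), 3)
  by_edge <- split(owner, keys)
  for (tris in by_edge) {
    if (length(tris) < 2) next
    r <- find(tris[1])
    for (t in tris[-1]) {
      r2 <- find(t)
      if (r2 != r) parent[r2] <- r
    }
  }
  vapply(seq_len(n), find, integer(1))
}

# closed boundary loops of a triangle set: directed edges (CCW triangles)
# whose undirected edge occurs exactly once, chained start -> end
.boundary_loops <- function(pts, tri) {
  if (!nrow(tri)) return(list())
  # ensure CCW orientation
  area2 <- (pts[tri[, 2], 1] - pts[tri[, 1], 1]) *
    (pts[tri[, 3], 2] - pts[tri[, 1], 2]) -
    (pts[tri[, 2], 2] - pts[tri[, 1], 2]) *
    (pts[tri[, 3], 1] - pts[tri[, 1], 1])
  flip <- area2 < 0
  t2 <- tri
  t2[flip, c(2, 3)] <- tri[flip, c(3, 2)]
  e <- rbind(t2[, c(1, 2)], t2[, c(2, 3)], t2[, c(3, 1)])
  und <- paste0(pmin(e[, 1], e[, 2]), "_", pmax(e[, 1], e[, 2]))
  once <- und %in% names(which(table(und) == 1))
  be <- e[once, , drop = FALSE]
  loops <- list()
  used <- rep(FALSE, nrow(be))
  nxt <- split(seq_len(nrow(be)), be[, 1])
  while (any(!used)) {
    start <- which(!used)[1]
    loop <- be[start, 1]
    cur <- start
    repeat {
      used[cur] <- TRUE
      v <- be[cur, 2]
      if (v == loop[1]) break
      loop <- c(loop, v)
      cands <- nxt[[as.character(v)]]
      cands <- cands[!used[cands]]
      if (!length(cands)) break  # open chain (numerical degeneracy)
      cur <- cands[1]
    }
    loops[[length(loops) + 1L]] <- pts[loop, , drop = FALSE]
  }
  loops
}

#' @export
print.alpha_shape <- function(x, ...) {
  cat(sprintf("Alpha shape: %d triangle(s), %d component(s), area %.0f nm^2%s\n",
              nrow(x$triangles), length(x$component_areas), x$area,
              if (x$degenerate) " (degenerate)" else ""))
  invisible(x)
}

#' @export
plot.alpha_shape <- function(x, add = FALSE, col = "grey40", ...) {
  if (!add)
    graphics::plot(x$points, asp = 1, pch = 16, cex = 0.4,
                   col = "grey70", xlab = "x (nm)", ylab = "y (nm)", ...)
  for (b in x$boundaries)
    for (loop in b)
      graphics::polygon(loop, border = col, lwd = 1.5)
  invisible(x)
}

# intersection area of two alpha-shape-like triangle sets
.shape_intersection_area <- function(shape_a, shape_b) {
  if (!nrow(shape_a$triangles) || !nrow(shape_b$triangles)) return(0)
  .triset_intersection_area_cpp(shape_a$points, shape_a$triangles,
                                shape_b$points, shape_b$triangles)
}

# uniform sample of n points inside a triangle set (area-weighted triangle
# choice + barycentric coordinates); uses the calling RNG state
.sample_in_triangles <- function(pts, tri, n) {
  g <- .tri_geometry(pts, tri)
  ti <- sample.int(nrow(tri), n, replace = TRUE, prob = g$area)
  r1 <- sqrt(runif(n)); r2 <- runif(n)
  A <- pts[tri[ti, 1], , drop = FALSE]
  B <- pts[tri[ti, 2], , drop = FALSE]
  C <- pts[tri[ti, 3], , drop = FALSE]
  (1 - r1) * A + r1 * (1 - r2) * B + r1 * r2 * C
}
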