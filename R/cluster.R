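# Core coordinate analysis: local density, scaffold segmentation, HDR
# detection against a uniform-randomization null, and overlap
# classification.

#' Local-density parameters
#'
#' The local density of a localization is the count of other localizations
#' within `neighbor_radius` (self excluded). The scaffold segmentation
#' discards points whose density lies in the lower `range_fraction` of the
#' observed min-max density range.
#'
#' @param neighbor_radius Neighbourhood radius, nm; default 25 (the nanodomain scale; see the methods vignette).
#' @param range_fraction Fraction of the density range treated as outside
#'   the synaptic region; default 0.10.
#' @return An object of class `density_params`.
#' @export
density_params <- function(neighbor_radius = 25, range_fraction = 0.10) {
  stopifnot(neighbor_radius > 0, range_fraction > 0, range_fraction < 1)
  structure(list(neighbor_radius = neighbor_radius,
                 range_fraction = range_fraction),
            class = "density_params")
}

#' Scaffold segmentation parameters
#'
#' @param alpha_scaffold Alpha-shape probe radius for scaffold boundaries,
#'   nm; default 100.
#' @param min_area Minimum retained region area, nm^2; default 1500.
#' @return An object of class `scaffold_params`.
#' @export
scaffold_params <- function(alpha_scaffold = 100, min_area = 1500) {
  stopifnot(alpha_scaffold > 0, min_area >= 0)
  structure(list(alpha_scaffold = alpha_scaffold, min_area = min_area),
            class = "scaffold_params")
}

#' HDR detection parameters
#'
#' The density cutoff is the mean plus `sd_multiplier` standard deviations
#' of the pooled local densities of `n_randomizations` uniform
#' randomizations of the region's localizations across its boundary.
#' `n_randomizations = 1` reproduces a single-draw null; the default of 10
#' pooled draws stabilizes the threshold.
#'
#' @param n_randomizations Uniform randomization draws; default 10.
#' @param sd_multiplier SD multiplier of the cutoff; default 2.
#' @param alpha_hdr Alpha-shape probe radius for HDR boundaries, nm;
#'   default 7.
#' @param min_points Minimum localizations per HDR; default 10.
#' @param seed Integer seed for the randomization null.
#' @return An object of class `hdr_params`.
#' @export
hdr_params <- function(n_randomizations = 10L, sd_multiplier = 2,
                       alpha_hdr = 7, min_points = 10L, seed = 1L) {
  stopifnot(n_randomizations >= 1, sd_multiplier > 0, alpha_hdr > 0,
            min_points >= 1)
  structure(list(n_randomizations = as.integer(n_randomizations),
                 sd_multiplier = sd_multiplier, alpha_hdr = alpha_hdr,
                 min_points = as.integer(min_points),
                 seed = as.integer(seed)),
            class = "hdr_params")
}

#' Overlap classification parameters
#'
#' @param synaptic_threshold Minimum fraction of an HDR's area overlapping
#'   the partner scaffold for the HDR to be classified synaptic;
#'   default 0.23.
#' @return An object of class `overlap_params`.
#' @export
overlap_params <- function(synaptic_threshold = 0.23) {
  stopifnot(synaptic_threshold >= 0, synaptic_threshold <= 1)
  structure(list(synaptic_threshold = synaptic_threshold),
            class = "overlap_params")
}

#' Coordinate-by-coordinate local density
#'
#' @param points Two-column matrix/data.frame of coordinates, nm.
#' @param params A [density_params()].
#' @return Integer vector: for each point, the number of other points
#'   within `neighbor_radius`.
#' @export
local_density <- function(points, params = density_params()) {
  pts <- as.matrix(points)[, 1:2, drop = FALSE]
  if (nrow(pts) == 0) return(integer(0))
  .count_within_radius_cpp(pts[, 1], pts[, 2], params$neighbor_radius)
}

#' Segment scaffold regions from localization densities
#'
#' Points with local density below `min + range_fraction * (max - min)` are
#' treated as outside the synaptic region; the alpha shape of the remainder
#' at `alpha_scaffold` is split into connected components and components
#' with area below `min_area` are discarded.
#'
#' @param points Two-column coordinates, nm.
#' @param densities Local densities from [local_density()] on the same
#'   points.
#' @param sp A [scaffold_params()].
#' @param dp A [density_params()].
#' @param channel Channel label recorded in the regions.
#' @return List of `scaffold_region` objects; an attribute `dropped` notes
#'   why regions (or all points) were discarded.
#' @export
segment_scaffold <- function(points, densities, sp = scaffold_params(),
                             dp = density_params(), channel = "ch1") {
  pts <- as.matrix(points)[, 1:2, drop = FALSE]
  stopifnot(length(densities) == nrow(pts))
  dropped <- character(0)
  if (!nrow(pts)) return(structure(list(), dropped = "no points"))
  rng <- range(densities)
  thr <- rng[1] + dp$range_fraction * (rng[2] - rng[1])
  keep <- densities >= thr
  idx <- which(keep)
  if (length(idx) < 3)
    return(structure(list(), dropped = "fewer than 3 retained points"))
  shape <- alpha_shape(pts[idx, , drop = FALSE], sp$alpha_scaffold)
  if (shape$degenerate)
    return(structure(list(), dropped = "degenerate alpha shape"))
  regions <- list()
  for (k in seq_along(shape$component_areas)) {
    if (shape$component_areas[k] < sp$min_area) {
      dropped <- c(dropped, sprintf("component %d below min_area (%.0f nm^2)",
                                    k, shape$component_areas[k]))
      next
    }
    tr <- shape$triangles[shape$component == k, , drop = FALSE]
    vert <- sort(unique(as.vector(tr)))
    # re-index triangles to the member subset
    tr_local <- matrix(match(tr, vert), ncol = 3)
    members <- idx[vert]
    regions[[length(regions) + 1L]] <- structure(list(
      channel = channel,
      member_idx = members,
      points = pts[members, , drop = FALSE],
      densities = densities[members],
      triangles = tr_local,
      area = shape$component_areas[k],
      boundary = shape$boundaries[[k]]),
      class = "scaffold_region")
  }
  structure(regions, dropped = dropped)
}

#' @export
print.scaffold_region <- function(x, ...) {
  cat(sprintf("Scaffold region (%s): %d localizations, area %.0f nm^2\n",
              x$channel, nrow(x$points), x$area))
  invisible(x)
}

#' Detect high-density regions against a uniform-randomization null
#'
#' For each of `n_randomizations` draws, as many points as the region holds
#' are placed uniformly inside its boundary and their local densities
#' computed. The cutoff is the mean plus `sd_multiplier` SDs of the pooled
#' randomized densities. Experimental members above the cutoff are grouped
#' by alpha-complex connectivity at `alpha_hdr` (shared retained triangles
#' or Delaunay edges not longer than `2 * alpha_hdr`); groups of at least
#' `min_points` become HDRs bounded by their alpha shape.
#'
#' @param region A `scaffold_region` from [segment_scaffold()], or any list
#'   with `points` (and either `triangles` or a `polygon` as the
#'   randomization domain).
#' @param hp An [hdr_params()].
#' @param dp A [density_params()].
#' @return List of `hdr` objects (members, boundary, `area` nm^2,
#'   `peak_density`, parent channel), with attribute `threshold` (the null
#'   cutoff).
#' @export
detect_hdrs <- function(region, hp = hdr_params(), dp = density_params()) {
  pts <- region$points
  n <- if (is.null(pts)) 0L else nrow(pts)
  if (n == 0) return(structure(list(), threshold = NA_real_))
  if (n < hp$min_points) return(structure(list(), threshold = NA_real_))
  has_tris <- !is.null(region$triangles) && nrow(region$triangles) > 0
  if (!has_tris && is.null(region$polygon))
    stop("region has no boundary (triangles or polygon) to randomize across")
  if (has_tris) {
    g <- .tri_geometry(pts, region$triangles)
    if (sum(g$area) <= 0) stop("region boundary has zero area")
  }
  set.seed(hp$seed)
  null_dens <- unlist(lapply(seq_len(hp$n_randomizations), function(i) {
    rnd <- if (has_tris)
      .sample_in_triangles(pts, region$triangles, n)
    else .sample_in_polygon(region$polygon, n)
    local_density(rnd, dp)
  }))
  threshold <- mean(null_dens) + hp$sd_multiplier * sd(null_dens)
  dens <- if (!is.null(region$densities) &&
              length(region$densities) == n) {
    region$densities
  } else local_density(pts, dp)
  hot <- which(dens > threshold)
  out <- list()
  if (length(hot) >= hp$min_points) {
    comp <- .alpha_complex_groups(pts[hot, , drop = FALSE], hp$alpha_hdr)
    for (cid in unique(comp)) {
      sel <- hot[comp == cid]
      if (length(sel) < hp$min_points) next
      shape <- alpha_shape(pts[sel, , drop = FALSE], hp$alpha_hdr)
      if (shape$degenerate || shape$area <= 0) next
      out[[length(out) + 1L]] <- structure(list(
        channel = region$channel,
        member_idx = if (!is.null(region$member_idx))
          region$member_idx[sel] else sel,
        region_idx = sel,
        points = pts[sel, , drop = FALSE],
        shape = shape,
        area = shape$area,
        boundary = unlist(shape$boundaries, recursive = FALSE),
        peak_density = max(dens[sel]),
        overlap_fraction_scaffold = NA_real_,
        overlap_fraction_hdr = NA_real_,
        synaptic = NA),
        class = "hdr")
    }
  }
  structure(out, threshold = threshold)
}

# connected grouping of points by the alpha complex at probe radius alpha:
# points sharing a retained Delaunay triangle (circumradius <= alpha) or a
# Delaunay edge of length <= 2 * alpha are in the same group
.alpha_complex_groups <- function(pts, alpha) {
  n <- nrow(pts)
  if (n == 1) return(1L)
  parent <- seq_len(n)
  find <- function(i) { while (parent[i] != i) i <- parent[i]; i }
  unite <- function(a, b) {
    ra <- find(a); rb <- find(b)
    if (ra != rb) parent[rb] <<- ra
  }
  if (n == 2) {
    if (sqrt(sum((pts[1, ] - pts[2, ])^2)) <= 2 * alpha) unite(1L, 2L)
    return(vapply(seq_len(n), find, integer(1)))
  }
  tri <- .delaunay_cpp(pts[, 1], pts[, 2])
  if (nrow(tri)) {
    g <- .tri_geometry(pts, tri)
    keep_tri <- is.finite(g$circumradius) & g$circumradius <= alpha
    for (t in which(keep_tri)) {
      unite(tri[t, 1], tri[t, 2]); unite(tri[t, 2], tri[t, 3])
    }
    e <- rbind(tri[, c(1, 2)], tri[, c(2, 3)], tri[, c(3, 1)])
    len <- sqrt((pts[e[, 1], 1] - pts[e[, 2], 1])^2 +
                  (pts[e[, 1], 2] - pts[e[, 2], 2])^2)
    for (k in which(len <= 2 * alpha)) unite(e[k, 1], e[k, 2])
  }
  vapply(seq_len(n), find, integer(1))
}

.sample_in_polygon <- function(polygon, n) {
  poly <- as.matrix(polygon)
  bb <- c(range(poly[, 1]), range(poly[, 2]))
  out <- matrix(NA_real_, 0, 2)
  while (nrow(out) < n) {
    m <- 2 * (n - nrow(out)) + 10
    cand <- cbind(runif(m, bb[1], bb[2]), runif(m, bb[3], bb[4]))
    ok <- .points_in_polygon_cpp(cand[, 1], cand[, 2], poly[, 1], poly[, 2])
    out <- rbind(out, cand[ok, , drop = FALSE])
  }
  out[seq_len(n), , drop = FALSE]
}

#' @export
print.hdr <- function(x, ...) {
  cat(sprintf("HDR (%s): %d localizations, area %.0f nm^2%s\n",
              x$channel, nrow(x$points), x$area,
              if (!is.na(x$synaptic))
                if (x$synaptic) ", synaptic" else ", extrasynaptic"
              else ""))
  invisible(x)
}

#' Classify HDR overlap with the partner channel
#'
#' For each HDR of channel A, computes the fraction of its area overlapping
#' the union of channel-B scaffold regions and the union of channel-B HDRs.
#' The HDR is synaptic when the scaffold overlap fraction is at least the
#' threshold (default 0.23).
#'
#' @param hdrs_a List of `hdr` objects (channel A).
#' @param regions_b List of `scaffold_region` objects (channel B).
#' @param hdrs_b List of `hdr` objects (channel B); may be empty.
#' @param op An [overlap_params()].
#' @return List with `hdrs` (annotated channel-A HDRs), `table` (one row per
#'   HDR: area, overlap fractions, synaptic flag) and `histogram` (counts of
#'   scaffold- and HDR-overlap fractions in bins of 0.1).
#' @export
classify_overlap <- function(hdrs_a, regions_b, hdrs_b = list(),
                             op = overlap_params()) {
  frac_vs <- function(hdr, others) {
    if (!length(others) || hdr$area <= 0) return(0)
    inter <- sum(vapply(others, function(o) {
      shp <- if (inherits(o, "hdr")) o$shape else
        list(points = o$points, triangles = o$triangles)
      .shape_intersection_area(hdr$shape, shp)
    }, numeric(1)))
    min(1, inter / hdr$area)
  }
  rows <- list()
  for (i in seq_along(hdrs_a)) {
    h <- hdrs_a[[i]]
    h$overlap_fraction_scaffold <- frac_vs(h, regions_b)
    h$overlap_fraction_hdr <- frac_vs(h, hdrs_b)
    h$synaptic <- h$overlap_fraction_scaffold >= op$synaptic_threshold
    hdrs_a[[i]] <- h
    rows[[i]] <- data.frame(
      hdr = i, channel = h$channel, area = h$area,
      n_locs = nrow(h$points),
      overlap_fraction_scaffold = h$overlap_fraction_scaffold,
      overlap_fraction_hdr = h$overlap_fraction_hdr,
      synaptic = h$synaptic, stringsAsFactors = FALSE)
  }
  tab <- if (length(rows)) do.call(rbind, rows) else
    data.frame(hdr = integer(0), channel = character(0), area = numeric(0),
               n_locs = integer(0), overlap_fraction_scaffold = numeric(0),
               overlap_fraction_hdr = numeric(0), synaptic = logical(0))
  breaks <- seq(0, 1, by = 0.1)
  histo <- list(
    breaks = breaks,
    scaffold = table(cut(tab$overlap_fraction_scaffold, breaks,
                         include.lowest = TRUE)),
    hdr = table(cut(tab$overlap_fraction_hdr, breaks,
                    include.lowest = TRUE)))
  list(hdrs = hdrs_a, table = tab, histogram = histo)
}
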