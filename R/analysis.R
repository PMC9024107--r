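# Per-ROI orchestration of the coordinate analysis and batch summaries.

#' ROI sets
#'
#' An ROI set is a list of labeled rectangles or polygons in nm
#' coordinates selecting synapses for analysis. The JSON dialect is
#' `[{"label": ..., "type": "rect", "coords": [xmin, ymin, xmax, ymax]}, ...]`
#' or `"type": "polygon"` with `coords` an array of `[x, y]` vertices.
#'
#' @param rois List of ROI entries (`label`, `type`, `coords`).
#' @return An object of class `roi_set`.
#' @export
roi_set <- function(rois) {
  rois <- lapply(seq_along(rois), function(i) {
    r <- rois[[i]]
    if (is.null(r$label)) r$label <- paste0("roi", i)
    r$polygon <- roi_polygon(r)
    a <- abs(.polygon_area(r$polygon))
    if (a <= 0) stop("ROI '", r$label, "' has zero area")
    if (.polygon_self_intersects(r$polygon))
      stop("ROI '", r$label, "' polygon self-intersects")
    r
  })
  structure(rois, class = "roi_set")
}

#' @rdname roi_set
#' @param roi A single ROI entry.
#' @return `roi_polygon()` returns the ROI as a closed polygon coordinate
#'   matrix.
#' @export
roi_polygon <- function(roi) {
  if (!is.null(roi$polygon)) return(roi$polygon)
  if (identical(roi$type, "rect")) {
    cc <- as.numeric(unlist(roi$coords))
    stopifnot(length(cc) == 4)
    cbind(x = cc[c(1, 3, 3, 1)], y = cc[c(2, 2, 4, 4)])
  } else {
    m <- roi$coords
    if (is.list(m)) m <- do.call(rbind, lapply(m, as.numeric))
    m <- as.matrix(m)
    colnames(m) <- c("x", "y")
    m
  }
}

.polygon_area <- function(poly) {
  n <- nrow(poly)
  j <- c(2:n, 1)
  sum(poly[, 1] * poly[j, 2] - poly[j, 1] * poly[, 2]) / 2
}

.polygon_self_intersects <- function(poly) {
  n <- nrow(poly)
  if (n < 4) return(FALSE)
  seg_int <- function(p1, p2, p3, p4) {
    d <- function(a, b, c)
      (b[1] - a[1]) * (c[2] - a[2]) - (b[2] - a[2]) * (c[1] - a[1])
    d1 <- d(p3, p4, p1); d2 <- d(p3, p4, p2)
    d3 <- d(p1, p2, p3); d4 <- d(p1, p2, p4)
    ((d1 > 0 & d2 < 0) | (d1 < 0 & d2 > 0)) &&
      ((d3 > 0 & d4 < 0) | (d3 < 0 & d4 > 0))
  }
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      if (abs(i - j) <= 1 || (i == 1 && j == n) || (i == n && j == 1)) next
      if (seg_int(poly[i, ], poly[if (i == n) 1 else i + 1, ],
                  poly[j, ], poly[if (j == n) 1 else j + 1, ]))
        return(TRUE)
    }
  }
  FALSE
}

#' @rdname roi_set
#' @param path JSON file path.
#' @export
read_roi_json <- function(path) {
  roi_set(jsonlite::read_json(path, simplifyVector = FALSE))
}

#' @rdname roi_set
#' @param rset An `roi_set`.
#' @export
write_roi_json <- function(rset, path) {
  out <- lapply(rset, function(r)
    list(label = r$label,
         type = if (identical(r$type, "rect")) "rect" else "polygon",
         coords = if (identical(r$type, "rect")) r$coords else
           lapply(seq_len(nrow(r$polygon)), function(i)
             as.numeric(r$polygon[i, ]))))
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Restrict a localization table to an ROI
#'
#' @param tab A [loc_table()].
#' @param roi A single ROI entry (from an [roi_set()]).
#' @return The records whose coordinates fall inside (or on) the ROI.
#' @export
crop_to_roi <- function(tab, roi) {
  validate_loc_table(tab)
  poly <- roi_polygon(roi)
  keep <- .points_in_polygon_cpp(tab$x, tab$y, poly[, 1], poly[, 2])
  out <- tab[keep, , drop = FALSE]
  rownames(out) <- NULL
  as_loc_table(out)
}

#' Analyze one synapse ROI in two channels
#'
#' Runs the full coordinate analysis for a single ROI: local densities,
#' scaffold segmentation, HDR detection per region (and, when an ROI
#' polygon is given, among off-region localizations with the ROI as the
#' randomization domain), and overlap classification of channel-A HDRs
#' against the channel-B scaffold and HDRs.
#'
#' @param tab_a,tab_b Localization tables of the two channels (channel B
#'   carries the reference scaffold, e.g. gephyrin); `tab_b = NULL` runs a
#'   single-channel analysis.
#' @param roi Optional single ROI entry; tables are cropped to it and
#'   extrasynaptic HDR candidates outside segmented regions are evaluated
#'   against a uniform null over the ROI.
#' @param dp,sp,hp,op Parameter objects ([density_params()],
#'   [scaffold_params()], [hdr_params()], [overlap_params()]).
#' @return An object of class `synapse_analysis` with per-channel regions,
#'   HDRs, null thresholds and the overlap table.
#' @export
analyze_synapse <- function(tab_a, tab_b = NULL, roi = NULL,
                            dp = density_params(), sp = scaffold_params(),
                            hp = hdr_params(), op = overlap_params()) {
  chans <- list(a = tab_a)
  if (!is.null(tab_b)) chans$b <- tab_b
  res <- list()
  for (nm in names(chans)) {
    tab <- chans[[nm]]
    if (!is.null(roi)) tab <- crop_to_roi(tab, roi)
    pts <- cbind(tab$x, tab$y)
    dens <- local_density(pts, dp)
    regions <- segment_scaffold(pts, dens, sp, dp,
                                channel = tab$channel[1] %||% nm)
    hdrs <- list()
    thresholds <- numeric(0)
    for (rg in regions) {
      h <- detect_hdrs(rg, hp, dp)
      thresholds <- c(thresholds, attr(h, "threshold"))
      hdrs <- c(hdrs, h)
    }
    # extrasynaptic candidates: points outside every region, null over ROI
    if (!is.null(roi) && nrow(tab)) {
      inside <- unique(unlist(lapply(regions, `[[`, "member_idx")))
      out_idx <- setdiff(seq_len(nrow(tab)), inside)
      if (length(out_idx) >= hp$min_points) {
        pseudo <- list(channel = tab$channel[1] %||% nm,
                       points = pts[out_idx, , drop = FALSE],
                       member_idx = out_idx,
                       polygon = roi_polygon(roi))
        h <- detect_hdrs(pseudo, hp, dp)
        hdrs <- c(hdrs, h)
      }
    }
    res[[nm]] <- list(table = tab, densities = dens, regions = regions,
                      hdrs = hdrs, thresholds = thresholds)
  }
  overlap <- NULL
  if (!is.null(tab_b)) {
    overlap <- classify_overlap(res$a$hdrs, res$b$regions, res$b$hdrs, op)
    res$a$hdrs <- overlap$hdrs
  }
  structure(list(channels = res, overlap = overlap,
                 roi_label = if (!is.null(roi)) roi$label else NA_character_,
                 params = list(dp = dp, sp = sp, hp = hp, op = op)),
            class = "synapse_analysis")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.synapse_analysis <- function(x, ...) {
  cat("Synapse coordinate analysis",
      if (!is.na(x$roi_label)) paste0(" [", x$roi_label, "]"), "\n", sep = "")
  for (nm in names(x$channels)) {
    ch <- x$channels[[nm]]
    cat(sprintf("  channel %s: %d localizations, %d region(s) (%.0f nm^2), %d HDR(s)\n",
                nm, nrow(ch$table), length(ch$regions),
                sum(vapply(ch$regions, `[[`, numeric(1), "area")),
                length(ch$hdrs)))
  }
  if (!is.null(x$overlap) && nrow(x$overlap$table))
    cat(sprintf("  synaptic channel-a HDRs: %d of %d (threshold %.2f)\n",
                sum(x$overlap$table$synaptic), nrow(x$overlap$table),
                x$params$op$synaptic_threshold))
  invisible(x)
}

#' @export
summary.synapse_analysis <- function(object, ...) {
  x <- object
  out <- list(roi = x$roi_label)
  for (nm in names(x$channels)) {
    ch <- x$channels[[nm]]
    out[[paste0("n_regions_", nm)]] <- length(ch$regions)
    out[[paste0("scaffold_area_", nm)]] <-
      sum(vapply(ch$regions, `[[`, numeric(1), "area"))
    out[[paste0("n_hdrs_", nm)]] <- length(ch$hdrs)
    out[[paste0("hdr_area_", nm)]] <-
      if (length(ch$hdrs))
        mean(vapply(ch$hdrs, `[[`, numeric(1), "area")) else NA_real_
  }
  if (!is.null(x$overlap))
    out$n_synaptic_a <- sum(x$overlap$table$synaptic)
  as.data.frame(out, stringsAsFactors = FALSE)
}

#' Density heat-map plot of an analyzed channel
#'
#' Localizations colored by local density, with scaffold boundaries (grey)
#' and HDR boundaries (red) overlaid.
#'
#' @param x A `synapse_analysis`.
#' @param channel `"a"` or `"b"`.
#' @param ... Passed to [graphics::plot()].
#' @export
plot.synapse_analysis <- function(x, channel = "a", ...) {
  ch <- x$channels[[channel]]
  dens <- ch$densities
  pal <- grDevices::hcl.colors(64, "viridis")
  col <- pal[pmax(1, ceiling(64 * (dens - min(dens) + 1) /
                               (diff(range(dens)) + 1)))]
  graphics::plot(ch$table$x, ch$table$y, asp = 1, pch = 16, cex = 0.5,
                 col = col, xlab = "x (nm)", ylab = "y (nm)", ...)
  for (rg in ch$regions)
    for (loop in rg$boundary)
      graphics::polygon(loop, border = "grey40", lwd = 2)
  for (h in ch$hdrs)
    for (loop in h$boundary)
      graphics::polygon(loop, border = "firebrick", lwd = 1.5)
  invisible(x)
}

#' Export region and HDR boundaries as GeoJSON
#'
#' Coordinates are in nm in the image frame (x right, y down).
#'
#' @param analysis A `synapse_analysis`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_boundaries_geojson <- function(analysis, path) {
  feat <- list()
  close_ring <- function(loop) {
    m <- rbind(loop, loop[1, , drop = FALSE])
    lapply(seq_len(nrow(m)), function(i) as.numeric(m[i, ]))
  }
  for (nm in names(analysis$channels)) {
    ch <- analysis$channels[[nm]]
    for (i in seq_along(ch$regions)) {
      rg <- ch$regions[[i]]
      for (loop in rg$boundary)
        feat[[length(feat) + 1L]] <- list(
          type = "Feature",
          properties = list(kind = "scaffold", channel = rg$channel,
                            region = i, area_nm2 = rg$area),
          geometry = list(type = "Polygon",
                          coordinates = list(close_ring(loop))))
    }
    for (i in seq_along(ch$hdrs)) {
      h <- ch$hdrs[[i]]
      for (loop in h$boundary)
        feat[[length(feat) + 1L]] <- list(
          type = "Feature",
          properties = list(kind = "hdr", channel = h$channel, hdr = i,
                            area_nm2 = h$area, synaptic = h$synaptic),
          geometry = list(type = "Polygon",
                          coordinates = list(close_ring(loop))))
    }
  }
  jsonlite::write_json(list(type = "FeatureCollection", features = feat),
                       path, auto_unbox = TRUE, digits = NA, null = "null")
  invisible(path)
}

#' Summarize a batch of analyzed synapses
#'
#' One row per ROI (scaffold areas, HDR counts and areas, synaptic labels)
#' plus pooled outputs: the least-squares line and correlation between
#' channel-B scaffold area and HDR counts in each channel, the HDR-count
#' correlation between channels, and pooled overlap-fraction histograms.
#'
#' @param analyses List of `synapse_analysis` objects.
#' @return An object of class `synapse_summary` with `rois` (per-ROI
#'   table), `hdrs` (per-HDR table) and `correlations`.
#' @export
summarize_synapses <- function(analyses) {
  rois <- do.call(rbind, lapply(analyses, summary))
  if (is.null(rois))
    rois <- data.frame(roi = character(0), n_regions_a = integer(0),
                       scaffold_area_a = numeric(0), n_hdrs_a = integer(0),
                       hdr_area_a = numeric(0))
  hdr_rows <- list()
  for (i in seq_along(analyses)) {
    an <- analyses[[i]]
    for (nm in names(an$channels))
      for (h in an$channels[[nm]]$hdrs)
        hdr_rows[[length(hdr_rows) + 1L]] <- data.frame(
          roi = an$roi_label, channel_slot = nm, channel = h$channel,
          area = h$area, n_locs = nrow(h$points),
          overlap_fraction_scaffold = h$overlap_fraction_scaffold,
          overlap_fraction_hdr = h$overlap_fraction_hdr,
          synaptic = h$synaptic, stringsAsFactors = FALSE)
  }
  hdrs <- if (length(hdr_rows)) do.call(rbind, hdr_rows) else
    data.frame(roi = character(0), channel_slot = character(0),
               channel = character(0), area = numeric(0),
               n_locs = integer(0), overlap_fraction_scaffold = numeric(0),
               overlap_fraction_hdr = numeric(0), synaptic = logical(0))
  correlations <- list()
  corr_of <- function(x, y) {
    ok <- is.finite(x) & is.finite(y)
    if (sum(ok) < 3 || sd(x[ok]) == 0 || sd(y[ok]) == 0) return(NULL)
    fit <- lm(y[ok] ~ x[ok])
    list(slope = unname(coef(fit)[2]), intercept = unname(coef(fit)[1]),
         r = cor(x[ok], y[ok]), n = sum(ok))
  }
  if (nrow(rois) && "scaffold_area_b" %in% names(rois)) {
    correlations$area_b_vs_nhdr_b <-
      corr_of(rois$scaffold_area_b, rois$n_hdrs_b)
    correlations$area_b_vs_nhdr_a <-
      corr_of(rois$scaffold_area_b, rois$n_hdrs_a)
    correlations$nhdr_b_vs_nhdr_a <- corr_of(rois$n_hdrs_b, rois$n_hdrs_a)
  } else if (nrow(rois)) {
    correlations$area_a_vs_nhdr_a <-
      corr_of(rois$scaffold_area_a, rois$n_hdrs_a)
  }
  structure(list(rois = rois, hdrs = hdrs, correlations = correlations),
            class = "synapse_summary")
}

#' @export
print.synapse_summary <- function(x, ...) {
  cat(sprintf("Synapse batch: %d ROI(s), %d HDR(s)\n",
              nrow(x$rois), nrow(x$hdrs)))
  if (nrow(x$rois)) print(head(x$rois, 10))
  for (nm in names(x$correlations)) {
    cc <- x$correlations[[nm]]
    if (!is.null(cc))
      cat(sprintf("  %s: slope %.3g, r = %.2f (n = %d)\n",
                  nm, cc$slope, cc$r, cc$n))
  }
  invisible(x)
}
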