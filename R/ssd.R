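# 3D-SIM-side geometry: statistics of labeled compartment / SSD volumes,
# inter-channel overlap, and centroid nearest-neighbour distances.

#' Labeled 3D volume of compartments and SSDs
#'
#' @param ssd Integer 3D array of SSD labels (0 = background).
#' @param comp Integer 3D array of compartment labels (0 = background), same
#'   dimensions.
#' @param voxel_size Voxel size `c(x, y, z)`, nm.
#' @param parent Named integer vector mapping SSD label to its compartment
#'   label; derived from the voxel data when `NULL`.
#' @return An object of class `label_volume`. Construction fails if any SSD
#'   voxel lies outside every compartment of its channel.
#' @export
label_volume <- function(ssd, comp, voxel_size, parent = NULL) {
  stopifnot(identical(dim(ssd), dim(comp)), length(dim(ssd)) == 3,
            all(voxel_size > 0), length(voxel_size) == 3)
  storage.mode(ssd) <- "integer"
  storage.mode(comp) <- "integer"
  labs <- setdiff(sort(unique(as.vector(ssd))), 0L)
  derived <- integer(0)
  for (l in labs) {
    comps <- comp[ssd == l]
    if (any(comps == 0L))
      stop("SSD label ", l, " has voxel(s) outside every compartment")
    derived[as.character(l)] <- as.integer(names(which.max(table(comps))))
  }
  if (is.null(parent)) parent <- derived
  structure(list(ssd = ssd, comp = comp,
                 voxel_size = as.numeric(voxel_size),
                 parent = parent),
            class = "label_volume")
}

#' @export
print.label_volume <- function(x, ...) {
  cat(sprintf("Label volume %s, voxel %s nm: %d compartment(s), %d SSD(s)\n",
              paste(dim(x$ssd), collapse = "x"),
              paste(x$voxel_size, collapse = "x"),
              length(setdiff(unique(as.vector(x$comp)), 0L)),
              length(setdiff(unique(as.vector(x$ssd)), 0L))))
  invisible(x)
}

# centroid (nm) and voxel count per label of a 3D label array
.label_stats <- function(arr, voxel_size) {
  idx <- which(arr != 0L)
  if (!length(idx))
    return(data.frame(label = integer(0), n_voxels = integer(0),
                      x = numeric(0), y = numeric(0), z = numeric(0),
                      volume = numeric(0)))
  lab <- arr[idx]
  d <- dim(arr)
  i <- ((idx - 1L) %% d[1]) + 1L
  j <- (((idx - 1L) %/% d[1]) %% d[2]) + 1L
  k <- ((idx - 1L) %/% (d[1] * d[2])) + 1L
  vox_vol <- prod(voxel_size)
  agg <- function(v) vapply(split(v, lab), mean, numeric(1))
  cnt <- vapply(split(lab, lab), length, integer(1))
  labs <- as.integer(names(cnt))
  data.frame(label = labs, n_voxels = as.integer(cnt),
             x = (agg(i) - 0.5) * voxel_size[1],
             y = (agg(j) - 0.5) * voxel_size[2],
             z = (agg(k) - 0.5) * voxel_size[3],
             volume = cnt * vox_vol, row.names = NULL)
}

#' Per-compartment and per-SSD statistics of a label volume
#'
#' Volume is voxel count times voxel volume; centroids are unweighted voxel
#' centroids in nm.
#'
#' @param vol A [label_volume()].
#' @return List of class `ssd_stats` with `ssds` (label, parent
#'   compartment, voxel count, centroid, volume) and `compartments` (label,
#'   voxel count, centroid, volume, SSD count).
#' @export
compartment_stats <- function(vol) {
  stopifnot(inherits(vol, "label_volume"))
  ssds <- .label_stats(vol$ssd, vol$voxel_size)
  comps <- .label_stats(vol$comp, vol$voxel_size)
  ssds$compartment <- if (nrow(ssds))
    as.integer(vol$parent[as.character(ssds$label)]) else integer(0)
  comps$n_ssds <- if (nrow(comps))
    vapply(comps$label, function(l) sum(ssds$compartment == l, na.rm = TRUE),
           integer(1)) else integer(0)
  structure(list(ssds = ssds, compartments = comps,
                 voxel_size = vol$voxel_size),
            class = "ssd_stats")
}

#' @export
print.ssd_stats <- function(x, ...) {
  cat(sprintf("SSD stats: %d SSD(s) in %d compartment(s); mean SSDs/compartment %.2f\n",
              nrow(x$ssds), nrow(x$compartments),
              if (nrow(x$compartments)) mean(x$compartments$n_ssds) else NA))
  invisible(x)
}

#' Voxel-wise overlap of SSDs between two channels
#'
#' For each SSD of channel A, the overlap fraction is the share of its
#' voxels covered by any channel-B SSD. An SSD overlaps when the fraction
#' is positive; the percentage of overlapping SSDs is reported over all
#' channel-A SSDs.
#'
#' @param vol_a,vol_b [label_volume()]s on the same grid and voxel size.
#' @return List with `fractions` (per channel-A SSD: label, overlap
#'   fraction) and `percent_overlapping`.
#' @export
ssd_overlap <- function(vol_a, vol_b) {
  stopifnot(inherits(vol_a, "label_volume"), inherits(vol_b, "label_volume"))
  if (!identical(dim(vol_a$ssd), dim(vol_b$ssd)))
    stop("grid mismatch: ", paste(dim(vol_a$ssd), collapse = "x"), " vs ",
         paste(dim(vol_b$ssd), collapse = "x"))
  if (!isTRUE(all.equal(vol_a$voxel_size, vol_b$voxel_size)))
    stop("voxel size mismatch")
  idx <- which(vol_a$ssd != 0L)
  lab <- vol_a$ssd[idx]
  hit <- vol_b$ssd[idx] != 0L
  labs <- sort(unique(lab))
  frac <- vapply(labs, function(l) mean(hit[lab == l]), numeric(1))
  data_frac <- data.frame(label = labs, overlap_fraction = frac)
  list(fractions = data_frac,
       percent_overlapping = if (length(frac)) 100 * mean(frac > 0) else
         NA_real_)
}

#' Center-to-center nearest-neighbour SSD distances
#'
#' For each SSD centroid in `stats_a`, the Euclidean distance (nm,
#' anisotropic voxel size already folded into the centroids) to the nearest
#' SSD centroid in `stats_b`.
#'
#' @param stats_a,stats_b `ssd_stats` from [compartment_stats()].
#' @return `data.frame` with the channel-A SSD label, the nearest channel-B
#'   label and the distance in nm; distances are `NA` (flagged) when
#'   channel B has no SSDs.
#' @export
nn_distances <- function(stats_a, stats_b) {
  a <- stats_a$ssds; b <- stats_b$ssds
  if (!nrow(a))
    return(data.frame(label = integer(0), nearest = integer(0),
                      distance = numeric(0)))
  if (!nrow(b))
    return(data.frame(label = a$label, nearest = NA_integer_,
                      distance = NA_real_))
  d2 <- outer(a$x, b$x, "-")^2 + outer(a$y, b$y, "-")^2 +
    outer(a$z, b$z, "-")^2
  j <- apply(d2, 1, which.min)
  data.frame(label = a$label, nearest = b$label[j],
             distance = sqrt(d2[cbind(seq_len(nrow(a)), j)]))
}

#' Count / volume relationships over a batch of synapses
#'
#' Pools per-compartment rows from paired channel statistics and reports
#' (i) the mean partner-channel SSD count grouped by own-channel SSD count
#' and (ii) the mean own-channel SSD count grouped by partner compartment
#' volume bins.
#'
#' @param batch `data.frame` with one row per compartment and columns
#'   `n_ssds_own`, `n_ssds_partner`, `volume_partner` (nm^3).
#' @param volume_breaks Bin edges for the partner compartment volume, nm^3;
#'   default quartile edges of the data.
#' @return List with `by_count` and `by_volume` summary tables; empty
#'   groups are absent (reported as missing), not zero.
#' @export
count_volume_correlations <- function(batch, volume_breaks = NULL) {
  stopifnot(all(c("n_ssds_own", "n_ssds_partner", "volume_partner") %in%
                  names(batch)))
  if (!nrow(batch))
    return(list(by_count = data.frame(n_ssds_own = integer(0),
                                      mean_partner = numeric(0),
                                      n = integer(0)),
                by_volume = data.frame(bin = character(0),
                                       mean_own = numeric(0),
                                       n = integer(0))))
  by_count <- do.call(rbind, lapply(split(batch, batch$n_ssds_own),
                                    function(g) data.frame(
    n_ssds_own = g$n_ssds_own[1],
    mean_partner = mean(g$n_ssds_partner), n = nrow(g))))
  rownames(by_count) <- NULL
  if (is.null(volume_breaks)) {
    volume_breaks <- unique(quantile(batch$volume_partner,
                                     probs = seq(0, 1, 0.25), names = FALSE))
    if (length(volume_breaks) < 2)
      volume_breaks <- range(batch$volume_partner) + c(-1, 1)
  }
  bins <- cut(batch$volume_partner, volume_breaks, include.lowest = TRUE)
  by_volume <- do.call(rbind, lapply(split(batch, bins), function(g)
    if (nrow(g)) data.frame(bin = as.character(bins[match(g$volume_partner[1],
                                                          batch$volume_partner)]),
                            mean_own = mean(g$n_ssds_own), n = nrow(g))))
  rownames(by_volume) <- NULL
  list(by_count = by_count, by_volume = by_volume)
}

#' Read / write labeled volumes as TIFF plus JSON sidecar
#'
#' The SSD and compartment channels are stored as multi-page 16-bit TIFFs;
#' voxel size and the SSD-to-compartment parent map go to `<path>.json`.
#'
#' @param vol A [label_volume()].
#' @param path Base output path (two TIFFs `<path>_ssd.tif`,
#'   `<path>_comp.tif` and one sidecar are written).
#' @return `path` invisibly; `read_label_volume()` returns the volume.
#' @export
write_label_volume <- function(vol, path) {
  stopifnot(inherits(vol, "label_volume"))
  to_pages <- function(arr) {
    lapply(seq_len(dim(arr)[3]), function(k) arr[, , k] / 65535)
  }
  tiff::writeTIFF(to_pages(vol$ssd), paste0(path, "_ssd.tif"),
                  bits.per.sample = 16L)
  tiff::writeTIFF(to_pages(vol$comp), paste0(path, "_comp.tif"),
                  bits.per.sample = 16L)
  jsonlite::write_json(list(voxel_size = vol$voxel_size,
                            parent = as.list(vol$parent),
                            dims = dim(vol$ssd)),
                       paste0(path, ".json"), auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_label_volume
#' @export
read_label_volume <- function(path) {
  meta <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  from_pages <- function(file, dims) {
    pages <- tiff::readTIFF(file, all = TRUE)
    arr <- array(0L, dims)
    for (k in seq_along(pages))
      arr[, , k] <- as.integer(round(pages[[k]] * 65535))
    arr
  }
  dims <- as.integer(meta$dims)
  parent <- unlist(meta$parent)
  label_volume(from_pages(paste0(path, "_ssd.tif"), dims),
               from_pages(paste0(path, "_comp.tif"), dims),
               meta$voxel_size,
               setNames(as.integer(parent), names(parent)))
}
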