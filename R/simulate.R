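# Synthetic-data generators. Every input the pipeline consumes can be
# produced here with a full ground-truth record, so each downstream stage is
# testable against known truth without microscope data.

#' Simulate two-channel dSTORM localizations of one synapse
#'
#' Emitter positions are drawn per nanodomain (Gaussian around the
#' nanodomain center, rejected outside the scaffold radius) plus a uniform
#' background over a disc of 1.5 x the scaffold radius. The number of
#' localizations per nanodomain is Poisson around `locs_per_nanodomain`;
#' each emitter re-appears (blinks) `1 + Geometric(blink_p)` times, each
#' appearance jittered by its localization precision. Channel 2 carries the
#' nanodomains displaced by `model$partner_offset`. Optional drift and
#' inter-channel distortion are applied to the observed positions and
#' recorded in the ground truth.
#'
#' @param model A [synapse_model()].
#' @param noise A [noise_model()].
#' @param seed Integer seed; fixed seed gives bitwise-identical output.
#' @param drift Optional [drift_model()] applied to both channels.
#' @param distortion Optional [distortion_model()] applied to channel 2.
#' @return A list of class `synapse_sim` with elements `ch1`, `ch2`
#'   (localization tables) and `truth` (emitter table, per-localization
#'   ground truth, the models and the seed).
#' @export
simulate_synapse <- function(model, noise, seed = 1L,
                             drift = NULL, distortion = NULL) {
  stopifnot(inherits(model, "synapse_model"), inherits(noise, "noise_model"))
  set.seed(as.integer(seed))

  centers <- model$nanodomain_centers
  if (is.null(centers) && model$n_nanodomains > 0) {
    centers <- .place_centers(model)
  }

  ch1 <- .sim_channel(model, noise, centers, channel = "ch1")
  centers2 <- if (!is.null(centers))
    sweep(centers, 2, -model$partner_offset) else NULL
  ch2 <- .sim_channel(model, noise, centers2, channel = "ch2")

  truth_locs <- rbind(ch1$truth, ch2$truth)
  tab1 <- ch1$tab; tab2 <- ch2$tab

  if (!is.null(drift)) {
    stopifnot(inherits(drift, "drift_model"))
    for (nm in c("tab1", "tab2")) {
      tb <- get(nm)
      d <- eval_drift(drift, tb$frame)
      tb$x <- tb$x + d[, 1]; tb$y <- tb$y + d[, 2]
      assign(nm, tb)
    }
  }
  if (!is.null(distortion)) {
    stopifnot(inherits(distortion, "distortion_model"))
    d <- eval_distortion(distortion, tab2$x, tab2$y)
    tab2$x <- tab2$x + d[, 1]; tab2$y <- tab2$y + d[, 2]
  }

  emitters <- rbind(ch1$emitters, ch2$emitters)
  structure(list(
    ch1 = as_loc_table(tab1),
    ch2 = as_loc_table(tab2),
    truth = list(emitters = emitters, locs = truth_locs,
                 nanodomain_centers = centers,
                 drift = drift, distortion = distortion,
                 model = model, noise = noise, seed = as.integer(seed))
  ), class = "synapse_sim")
}

# nanodomain centers: uniform in 0.75 * scaffold_radius with a minimum
# pairwise separation, by rejection with whole-configuration restarts
.place_centers <- function(model) {
  n <- model$n_nanodomains
  for (restart in seq_len(500)) {
    centers <- matrix(NA_real_, n, 2)
    ok <- TRUE
    for (k in seq_len(n)) {
      placed <- FALSE
      for (try in seq_len(200)) {
        p <- model$scaffold_center +
          .runif_disc(1, 0.75 * model$scaffold_radius)
        if (k == 1 ||
            min(sqrt(rowSums(sweep(centers[seq_len(k - 1), , drop = FALSE],
                                   2, p)^2))) >= model$min_separation) {
          centers[k, ] <- p
          placed <- TRUE
          break
        }
      }
      if (!placed) { ok <- FALSE; break }
    }
    if (ok) return(centers)
  }
  stop("could not place ", n, " nanodomains at ", model$min_separation,
       " nm separation inside the scaffold")
}

.runif_disc <- function(n, r) {
  th <- runif(n, 0, 2 * pi)
  rr <- r * sqrt(runif(n))
  cbind(rr * cos(th), rr * sin(th))
}

# one channel: nanodomain emitters + blinks + uniform background
.sim_channel <- function(model, noise, centers, channel) {
  em_x <- numeric(0); em_y <- numeric(0); em_nd <- integer(0)
  blinks <- integer(0)
  n_nd <- if (is.null(centers)) 0L else nrow(centers)
  for (k in seq_len(n_nd)) {
    n_locs <- rpois(1, model$locs_per_nanodomain)
    got <- 0L
    while (got < n_locs) {
      b <- 1L + rgeom(1, noise$blink_p)
      b <- min(b, n_locs - got)
      # emitter position: Gaussian around the center, kept inside the scaffold
      repeat {
        p <- centers[k, ] + rnorm(2, 0, model$nanodomain_sigma)
        if (sqrt(sum((p - model$scaffold_center)^2)) <= model$scaffold_radius)
          break
      }
      em_x <- c(em_x, p[1]); em_y <- c(em_y, p[2])
      em_nd <- c(em_nd, k); blinks <- c(blinks, b)
      got <- got + b
    }
  }
  n_bg <- rpois(1, model$background_locs)
  if (n_bg > 0) {
    p <- .runif_disc(n_bg, 1.5 * model$scaffold_radius)
    em_x <- c(em_x, model$scaffold_center[1] + p[, 1])
    em_y <- c(em_y, model$scaffold_center[2] + p[, 2])
    em_nd <- c(em_nd, rep(0L, n_bg))
    blinks <- c(blinks, rep(1L, n_bg))
  }
  n_em <- length(em_x)
  ntot <- sum(blinks)
  em_id <- seq_len(n_em)

  idx <- rep(em_id, blinks)
  frame <- integer(ntot)
  pos <- 1L
  for (i in seq_len(n_em)) {
    b <- blinks[i]
    fr <- if (noise$blink_runs && b > 1L) {
      st <- sample.int(max(1L, noise$n_frames - b + 1L), 1)
      st:(st + b - 1L)
    } else sort(sample.int(noise$n_frames, min(b, noise$n_frames),
                           replace = b > noise$n_frames))
    frame[pos:(pos + b - 1L)] <- fr
    pos <- pos + b
  }
  prec <- pmax(0, rnorm(ntot, noise$precision_mean, noise$precision_spread))
  x <- em_x[idx] + rnorm(ntot, 0, 1) * prec
  y <- em_y[idx] + rnorm(ntot, 0, 1) * prec
  sig <- pmax(1, rnorm(ntot, noise$sigma_mean, noise$sigma_spread))
  inten <- rlnorm(ntot, noise$intensity_meanlog, noise$intensity_sdlog)

  tab <- data.frame(id = seq_len(ntot), frame = frame, x = x, y = y,
                    sigma = sig, intensity = inten, offset = 0, bkgstd = 0,
                    uncertainty = prec, channel = channel,
                    detections_merged = 1L, stringsAsFactors = FALSE)
  o <- order(tab$frame, tab$id)
  truth <- data.frame(channel = channel, id = tab$id, emitter = idx,
                      nanodomain = em_nd[idx],
                      true_x = em_x[idx], true_y = em_y[idx],
                      stringsAsFactors = FALSE)
  tab <- tab[o, ]; truth <- truth[o, ]
  tab$id <- seq_len(ntot); truth$id <- tab$id
  rownames(tab) <- rownames(truth) <- NULL
  emitters <- data.frame(channel = channel, emitter = em_id,
                         nanodomain = em_nd, x = em_x, y = em_y,
                         blinks = blinks, stringsAsFactors = FALSE)
  list(tab = tab, truth = truth, emitters = emitters)
}

#' Simulate a batch of synapses with varying nanodomain counts
#'
#' Study-condition batch generator: synapse `i` receives
#' `counts[((i - 1) %% length(counts)) + 1]` nanodomains and a scaffold
#' radius of `base_radius * sqrt(n_nanodomains)`, so the scaffold area per
#' nanodomain is roughly constant and larger compartments hold more
#' nanodomains, as observed for inhibitory postsynaptic scaffolds.
#' Background localizations scale with the nanodomain count at a
#' nanodomain-to-background density contrast well above 5x.
#'
#' @param n_synapses Number of synapses.
#' @param counts Nanodomain counts cycled over the batch; default `1:4`.
#' @param base_radius Scaffold radius for a single-nanodomain synapse, nm.
#' @param background_per_domain Expected background localizations per
#'   nanodomain.
#' @param noise A [noise_model()].
#' @param seed Integer seed; synapse `i` uses sub-seed `seed * 1000 + i`.
#' @param ... Further arguments to [synapse_model()].
#' @return List of `synapse_sim` objects; each carries its `synapse_model`
#'   in `truth$model`.
#' @export
simulate_synapse_batch <- function(n_synapses = 50, counts = 1:4,
                                   base_radius = 110,
                                   background_per_domain = 100,
                                   noise = noise_model(), seed = 1L, ...) {
  lapply(seq_len(n_synapses), function(i) {
    nd <- counts[((i - 1L) %% length(counts)) + 1L]
    m <- synapse_model(n_nanodomains = nd,
                       scaffold_radius = base_radius * sqrt(max(nd, 1)),
                       background_locs = background_per_domain * max(nd, 1),
                       ...)
    simulate_synapse(m, noise,
                     seed = (as.numeric(seed) * 1000 + i) %% 2147483647)
  })
}

#' Simulate paired bead localizations for channel calibration
#'
#' Channel-1 bead positions are uniform over the field; channel-2 positions
#' are the same beads displaced by the distortion field. Isotropic Gaussian
#' localization noise of SD `precision` is added independently per bead and
#' per channel.
#'
#' @param distortion A [distortion_model()].
#' @param n_beads Number of beads.
#' @param precision Localization noise SD per channel, nm.
#' @param seed Integer seed.
#' @param field Field of view (width, height), nm; defaults to the
#'   distortion model's field.
#' @return List of class `bead_sim`: `ch1`, `ch2` (data.frames with x, y) and
#'   `truth` (true positions, true displacements, the model, the seed).
#' @export
simulate_bead_pairs <- function(distortion, n_beads = 100, precision = 5,
                                seed = 1L, field = NULL) {
  stopifnot(inherits(distortion, "distortion_model"),
            n_beads >= 1, precision >= 0)
  if (is.null(field)) field <- distortion$field
  ncoef <- length(distortion$coef_x)
  if (n_beads < ncoef)
    warning(sprintf(
      "only %d beads for a distortion field with %d coefficients; later fits may be under-determined",
      n_beads, ncoef))
  set.seed(as.integer(seed))
  tx <- runif(n_beads, 0, field[1])
  ty <- runif(n_beads, 0, field[2])
  d <- eval_distortion(distortion, tx, ty)
  ch1 <- data.frame(x = tx + rnorm(n_beads, 0, precision),
                    y = ty + rnorm(n_beads, 0, precision))
  ch2 <- data.frame(x = tx + d[, 1] + rnorm(n_beads, 0, precision),
                    y = ty + d[, 2] + rnorm(n_beads, 0, precision))
  structure(list(ch1 = ch1, ch2 = ch2,
                 truth = list(x = tx, y = ty, dx = d[, 1], dy = d[, 2],
                              distortion = distortion, precision = precision,
                              seed = as.integer(seed))),
            class = "bead_sim")
}

#' Simulate a raw camera frame stack from blink events
#'
#' Renders each blink event as an integrated-Gaussian PSF spot with Poisson
#' photon noise over a uniform Poisson background, converted to digital
#' units via the camera's ADU-per-photoelectron gain and baseline offset.
#'
#' @param events `data.frame` with columns `frame`, `x`, `y` (nm),
#'   `photons` (expected photons per appearance) and optionally `psf_sigma`
#'   (nm, default 130).
#' @param camera A [camera_model()].
#' @param dims Image size `c(ny, nx)` in pixels.
#' @param n_frames Stack length; defaults to `max(events$frame)`.
#' @param background_photons Expected background photons per pixel per frame.
#' @param seed Integer seed; `NULL` for a noiseless (expected-value) stack.
#' @return Numeric array `[ny, nx, n_frames]` in ADU with attribute
#'   `pixel_size`. Events outside the field are dropped with a message.
#' @export
simulate_frame_stack <- function(events, camera, dims = c(32L, 32L),
                                 n_frames = NULL, background_photons = 0,
                                 seed = 1L) {
  stopifnot(inherits(camera, "camera_model"))
  if (is.null(events$psf_sigma)) events$psf_sigma <- rep(130, nrow(events))
  px <- camera$pixel_size
  if (is.null(n_frames))
    n_frames <- if (nrow(events)) max(events$frame) else 1L
  ny <- dims[1]; nx <- dims[2]
  inside <- !nrow(events) |
    (events$x >= 0 & events$x <= nx * px & events$y >= 0 & events$y <= ny * px)
  if (nrow(events) && any(!inside)) {
    message(sum(!inside), " event(s) outside the field of view excluded")
    events <- events[inside, , drop = FALSE]
  }
  expected <- array(background_photons, dim = c(ny, nx, n_frames))
  for (i in seq_len(nrow(events))) {
    f <- events$frame[i]
    if (f < 1 || f > n_frames) next
    # pixel-center coordinates: column c spans ((c-1)*px, c*px]
    cx <- events$x[i] / px; cy <- events$y[i] / px
    s <- events$psf_sigma[i] / px
    half <- ceiling(4 * s) + 1L
    c0 <- max(1L, floor(cx) - half); c1 <- min(nx, ceiling(cx) + half)
    r0 <- max(1L, floor(cy) - half); r1 <- min(ny, ceiling(cy) + half)
    if (c0 > c1 || r0 > r1) next
    ex <- .igauss_1d(c0:c1, cx, s)
    ey <- .igauss_1d(r0:r1, cy, s)
    expected[r0:r1, c0:c1, f] <- expected[r0:r1, c0:c1, f] +
      events$photons[i] * outer(ey, ex)
  }
  if (is.null(seed)) {
    photons <- expected
  } else {
    set.seed(as.integer(seed))
    photons <- array(rpois(length(expected), expected), dim = dim(expected))
  }
  out <- camera$offset + photons * camera$adu_per_photon
  attr(out, "pixel_size") <- px
  out
}

# fraction of a unit-mass Gaussian at center mu (pixel units) integrating
# over pixel p, whose extent is (p-1, p]
.igauss_1d <- function(p, mu, s) {
  pnorm(p, mu, s) - pnorm(p - 1, mu, s)
}

#' Simulate labeled 3D volumes of synaptic compartments and SSDs
#'
#' Spherical compartments are placed on a grid; each holds the requested
#' number of spherical subsynaptic domains (SSDs), drawn at positions that
#' keep them inside the compartment. The second channel carries the same
#' compartments with its SSDs displaced by `channel_offset`, producing
#' partial inter-channel overlaps with analytically known volumes.
#'
#' @param n_compartments Number of compartments (>= 0).
#' @param ssd_counts Integer vector (recycled) of SSDs per compartment.
#' @param ssd_radius SSD radius, nm (recycled per compartment).
#' @param compartment_radius Compartment radius, nm.
#' @param voxel_size Voxel size `c(x, y, z)`, nm.
#' @param channel_offset Channel-2 SSD displacement `c(x, y, z)`, nm.
#' @param seed Integer seed.
#' @return List of class `volume_sim`: `vol_a`, `vol_b` ([label_volume()]s)
#'   and `truth` (per-SSD table with centers, radii, analytic volumes and
#'   analytic pairwise overlap volumes between matched channel SSDs).
#' @export
simulate_label_volume <- function(n_compartments = 3, ssd_counts = 2,
                                  ssd_radius = 80, compartment_radius = 250,
                                  voxel_size = c(40, 40, 120),
                                  channel_offset = c(60, 0, 0),
                                  seed = 1L) {
  stopifnot(n_compartments >= 0, all(voxel_size > 0),
            length(voxel_size) == 3, length(channel_offset) == 3)
  ssd_counts <- rep_len(as.integer(ssd_counts), max(1L, n_compartments))
  ssd_radius <- rep_len(as.numeric(ssd_radius), max(1L, n_compartments))
  if (any(ssd_radius > compartment_radius))
    stop("SSD radius exceeds compartment radius")
  set.seed(as.integer(seed))

  pitch <- 4 * compartment_radius
  margin <- compartment_radius + max(abs(channel_offset)) + 2 * max(voxel_size)
  if (n_compartments == 0) {
    dims <- c(4L, 4L, 4L)
    empty <- array(0L, dims)
    va <- label_volume(empty, empty, voxel_size, parent = integer(0))
    return(structure(list(vol_a = va, vol_b = va,
                          truth = .empty_ssd_truth()),
                     class = "volume_sim"))
  }
  ncol_grid <- ceiling(sqrt(n_compartments))
  comp_centers <- t(vapply(seq_len(n_compartments) - 1L, function(i) {
    c(margin + (i %% ncol_grid) * pitch,
      margin + (i %/% ncol_grid) * pitch,
      margin)
  }, numeric(3)))
  ext <- c(max(comp_centers[, 1]) + margin,
           max(comp_centers[, 2]) + margin,
           max(comp_centers[, 3]) + margin)
  dims <- as.integer(ceiling(ext / voxel_size))  # (nx, ny, nz) voxels

  comp_a <- array(0L, dims); ssd_a <- array(0L, dims)
  comp_b <- array(0L, dims); ssd_b <- array(0L, dims)
  parent_a <- integer(0); parent_b <- integer(0)
  rows <- list()
  ssd_label <- 0L
  for (ci in seq_len(n_compartments)) {
    cc <- comp_centers[ci, ]
    comp_a <- .paint_sphere(comp_a, cc, compartment_radius, voxel_size, ci)
    comp_b <- .paint_sphere(comp_b, cc, compartment_radius, voxel_size, ci)
    for (k in seq_len(ssd_counts[ci])) {
      r <- ssd_radius[ci]
      # keep the SSD (and its channel-2 copy) inside the compartment
      maxd <- compartment_radius - r - max(abs(channel_offset))
      p <- cc + .runif_ball(max(0, maxd))
      ssd_label <- ssd_label + 1L
      ssd_a <- .paint_sphere(ssd_a, p, r, voxel_size, ssd_label)
      pb <- p + channel_offset
      ssd_b <- .paint_sphere(ssd_b, pb, r, voxel_size, ssd_label)
      parent_a[as.character(ssd_label)] <- ci
      parent_b[as.character(ssd_label)] <- ci
      rows[[length(rows) + 1L]] <- data.frame(
        ssd = ssd_label, compartment = ci,
        x_a = p[1], y_a = p[2], z_a = p[3],
        x_b = pb[1], y_b = pb[2], z_b = pb[3],
        radius = r, volume = 4 / 3 * pi * r^3,
        overlap_volume = .sphere_overlap_volume(r, r,
                                                sqrt(sum(channel_offset^2))))
    }
  }
  truth <- if (length(rows)) do.call(rbind, rows) else .empty_ssd_truth()
  structure(list(
    vol_a = label_volume(ssd_a, comp_a, voxel_size, parent_a),
    vol_b = label_volume(ssd_b, comp_b, voxel_size, parent_b),
    truth = truth), class = "volume_sim")
}

.empty_ssd_truth <- function() {
  data.frame(ssd = integer(0), compartment = integer(0),
             x_a = numeric(0), y_a = numeric(0), z_a = numeric(0),
             x_b = numeric(0), y_b = numeric(0), z_b = numeric(0),
             radius = numeric(0), volume = numeric(0),
             overlap_volume = numeric(0))
}

.runif_ball <- function(r) {
  if (r <= 0) return(c(0, 0, 0))
  repeat {
    p <- runif(3, -r, r)
    if (sum(p^2) <= r^2) return(p)
  }
}

# label voxels whose centers fall inside the sphere; voxel (i,j,k) center is
# at ((i-0.5)*vx, (j-0.5)*vy, (k-0.5)*vz)
.paint_sphere <- function(arr, center, radius, voxel_size, label) {
  dims <- dim(arr)
  idx_rng <- function(c, r, v, n) {
    lo <- max(1L, floor((c - r) / v))
    hi <- min(n, ceiling((c + r) / v) + 1L)
    if (lo > hi) integer(0) else lo:hi
  }
  is <- idx_rng(center[1], radius, voxel_size[1], dims[1])
  js <- idx_rng(center[2], radius, voxel_size[2], dims[2])
  ks <- idx_rng(center[3], radius, voxel_size[3], dims[3])
  if (!length(is) || !length(js) || !length(ks)) return(arr)
  xs <- (is - 0.5) * voxel_size[1] - center[1]
  ys <- (js - 0.5) * voxel_size[2] - center[2]
  zs <- (ks - 0.5) * voxel_size[3] - center[3]
  d2 <- outer(outer(xs^2, ys^2, "+"), zs^2, "+")
  sel <- d2 <= radius^2
  sub <- arr[is, js, ks, drop = FALSE]
  sub[sel] <- as.integer(label)
  arr[is, js, ks] <- sub
  arr
}

# lens volume of two intersecting spheres at center distance d
.sphere_overlap_volume <- function(R, r, d) {
  if (d >= R + r) return(0)
  if (d <= abs(R - r)) return(4 / 3 * pi * min(R, r)^3)
  pi * (R + r - d)^2 *
    (d^2 + 2 * d * r - 3 * r^2 + 2 * d * R + 6 * r * R - 3 * R^2) / (12 * d)
}

#' Write a simulation's ground truth and parameters to JSON
#'
#' @param sim A `synapse_sim` or `bead_sim` object.
#' @param path Output JSON path.
#' @return `path`, invisibly.
#' @export
write_ground_truth <- function(sim, path) {
  strip <- function(x) {
    if (is.list(x)) lapply(unclass(x), strip) else x
  }
  jsonlite::write_json(strip(sim["truth"]), path, auto_unbox = TRUE,
                       digits = NA, null = "null")
  invisible(path)
}
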