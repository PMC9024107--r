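# Raw-frame processing: temporal quantile background filtering, a-trous
# B-spline wavelet spot detection, and weighted least-squares fitting of an
# integrated Gaussian PSF.

#' Temporal quantile filter parameters
#'
#' The background at each pixel is a running quantile over a centered
#' temporal window. It is computed only at key frames and linearly
#' interpolated between them.
#'
#' @param radius Window length in frames (odd, >= 3); default 51.
#' @param key_frame_distance Frames between explicit computations; default 10.
#' @param quantile Quantile used as the background estimate; default 0.20.
#' @return An object of class `temporal_filter_params`.
#' @export
temporal_filter_params <- function(radius = 51L, key_frame_distance = 10L,
                                   quantile = 0.20) {
  stopifnot(radius >= 3, radius %% 2 == 1, key_frame_distance >= 1,
            quantile > 0, quantile < 1)
  structure(list(radius = as.integer(radius),
                 key_frame_distance = as.integer(key_frame_distance),
                 quantile = quantile),
            class = "temporal_filter_params")
}

#' Remove non-homogeneous background with a temporal quantile filter
#'
#' @param stack Numeric array `[ny, nx, n_frames]`.
#' @param params A [temporal_filter_params()].
#' @return List with `background` (interpolated per-frame estimate) and
#'   `filtered` (`raw - background`, floored at 0), both arrays like `stack`.
#'   Windows are truncated at the stack edges.
#' @export
temporal_background_filter <- function(stack, params = temporal_filter_params()) {
  d <- dim(stack)
  if (length(d) != 3) stop("stack must be a [ny, nx, n_frames] array")
  nf <- d[3]
  if (nf <= params$radius)
    stop(sprintf("stack has %d frames; the temporal filter needs more than %d",
                 nf, params$radius))
  half <- (params$radius - 1L) %/% 2L
  keys <- unique(c(seq(1L, nf, by = params$key_frame_distance), nf))
  npix <- d[1] * d[2]
  flat <- matrix(stack, npix, nf)
  key_bg <- matrix(NA_real_, npix, length(keys))
  for (i in seq_along(keys)) {
    k <- keys[i]
    win <- max(1L, k - half):min(nf, k + half)
    key_bg[, i] <- apply(flat[, win, drop = FALSE], 1, quantile,
                         probs = params$quantile, names = FALSE)
  }
  bg <- matrix(NA_real_, npix, nf)
  bg[, keys] <- key_bg
  for (f in seq_len(nf)) {
    if (f %in% keys) next
    i <- findInterval(f, keys)
    k1 <- keys[i]; k2 <- keys[i + 1L]
    w <- (f - k1) / (k2 - k1)
    bg[, f] <- (1 - w) * bg[, k1] + w * bg[, k2]
  }
  background <- array(bg, d)
  filtered <- pmax(stack - background, 0)
  list(background = background, filtered = filtered)
}

#' Wavelet detection parameters
#'
#' @param bspline_order B-spline order of the a-trous filter bank; default 3.
#' @param wavelet_scale Scale parameter of the first filter level; default 2.
#' @param threshold_multiplier Peak threshold as a multiple of the SD of the
#'   first wavelet level; default 3.
#' @return An object of class `detection_params`.
#' @export
detection_params <- function(bspline_order = 3L, wavelet_scale = 2.0,
                             threshold_multiplier = 3.0) {
  stopifnot(bspline_order >= 1, wavelet_scale > 0, threshold_multiplier > 0)
  structure(list(bspline_order = as.integer(bspline_order),
                 wavelet_scale = wavelet_scale,
                 threshold_multiplier = threshold_multiplier),
            class = "detection_params")
}

# sampled B-spline kernel of the stated order and scale, normalized to sum 1
.bspline_kernel <- function(order, scale) {
  half <- ceiling(order * scale / 2)
  x <- (seq(-half, half)) / scale
  k <- vapply(x, .bspline_basis, numeric(1), order = order)
  k / sum(k)
}

# centered cardinal B-spline of the given order evaluated at x
.bspline_basis <- function(x, order) {
  # B-spline of order n (degree n-1) on [-n/2, n/2] via Cox-de Boor recursion
  n <- order
  b <- function(x, k) {
    if (k == 1) return(as.numeric(x >= -0.5 & x < 0.5))
    ((x + k / 2) * b(x + 0.5, k - 1) + (k / 2 - x) * b(x - 0.5, k - 1)) / (k - 1)
  }
  b(x, n)
}

# separable convolution with replicate padding; holes > 0 inserts zeros
# between taps (a-trous)
.conv_sep <- function(img, kernel, holes = 0L) {
  if (holes > 0) {
    k2 <- rep(0, (length(kernel) - 1) * (holes + 1) + 1)
    k2[seq(1, length(k2), by = holes + 1)] <- kernel
    kernel <- k2
  }
  half <- (length(kernel) - 1L) %/% 2L
  pad_conv <- function(m) {
    n <- nrow(m)
    idx <- pmin(pmax(seq(1 - half, n + half), 1L), n)
    mp <- m[idx, , drop = FALSE]
    out <- matrix(0, n, ncol(m))
    for (t in seq_along(kernel))
      out <- out + kernel[t] * mp[seq(t, t + n - 1L), , drop = FALSE]
    out
  }
  t(pad_conv(t(pad_conv(img))))
}

# a-trous B-spline wavelet levels: W1 = I - F1, W2 = F1 - F2
.wavelet_levels <- function(frame, params) {
  k <- .bspline_kernel(params$bspline_order, params$wavelet_scale)
  f1 <- .conv_sep(frame, k, holes = 0L)
  f2 <- .conv_sep(f1, k, holes = 1L)
  list(w1 = frame - f1, w2 = f1 - f2)
}

#' Detect candidate molecules in one frame
#'
#' Candidates are 8-connected local maxima of the second a-trous wavelet
#' level exceeding `threshold_multiplier` times the standard deviation of
#' the first wavelet level.
#'
#' @param frame Numeric matrix (one camera frame).
#' @param params A [detection_params()].
#' @return `data.frame` with integer pixel positions `row`, `col` and the
#'   wavelet response `value`. A constant frame yields zero candidates.
#' @export
detect_candidates <- function(frame, params = detection_params()) {
  stopifnot(is.matrix(frame), all(is.finite(frame)))
  lv <- .wavelet_levels(frame, params)
  thr <- params$threshold_multiplier * sd(lv$w1)
  if (!is.finite(thr) || thr <= 0)
    return(data.frame(row = integer(0), col = integer(0), value = numeric(0)))
  w2 <- lv$w2
  nr <- nrow(w2); nc <- ncol(w2)
  if (nr < 3 || nc < 3)
    return(data.frame(row = integer(0), col = integer(0), value = numeric(0)))
  core <- w2[2:(nr - 1), 2:(nc - 1)]
  is_max <- core > thr
  for (dr in -1:1) for (dc in -1:1) {
    if (dr == 0 && dc == 0) next
    nb <- w2[2:(nr - 1) + dr, 2:(nc - 1) + dc]
    is_max <- is_max & (core >= nb)
  }
  idx <- which(is_max, arr.ind = TRUE)
  data.frame(row = idx[, 1] + 1L, col = idx[, 2] + 1L,
             value = core[is_max])
}

#' Spot-fitting parameters
#'
#' @param fitting_radius Half-width of the square fit window, pixels
#'   (default 4; window is `(2 * radius + 1)^2` pixels).
#' @param initial_sigma Starting PSF sigma, pixels (default 1.2).
#' @return An object of class `fit_params`.
#' @export
fit_params <- function(fitting_radius = 4L, initial_sigma = 1.2) {
  stopifnot(fitting_radius >= 2, initial_sigma > 0)
  structure(list(fitting_radius = as.integer(fitting_radius),
                 initial_sigma = initial_sigma),
            class = "fit_params")
}

#' Fit an integrated Gaussian to candidate spots
#'
#' Weighted least squares on the integrated-Gaussian model
#' `I(p) = N * Ex(p) * Ey(p) + b`, where `Ex`, `Ey` are the per-pixel
#' integrals of a unit Gaussian, with Poisson weights `1 / max(I, 1)`.
#' Pixel values are converted to photons with the camera gain before
#' fitting. Candidates closer than `fitting_radius` to the frame border are
#' discarded; non-convergent fits are dropped and tallied.
#'
#' @param frame Numeric matrix in ADU (background-filtered or raw).
#' @param candidates `data.frame` with `row`, `col` from
#'   [detect_candidates()].
#' @param camera A [camera_model()].
#' @param params A [fit_params()].
#' @param offset_adu Camera baseline already present in `frame`, ADU;
#'   defaults to `camera$offset`. Use 0 for temporally filtered frames.
#' @param frame_index Frame number recorded in the output table.
#' @return A [loc_table()] with one row per converged fit (positions in nm,
#'   sigma in nm, intensity and offset in photons, Thompson-style lateral
#'   uncertainty in nm) plus attribute `n_failed`.
#' @export
fit_spots <- function(frame, candidates, camera = camera_model(),
                      params = fit_params(), offset_adu = camera$offset,
                      frame_index = 1L) {
  r <- params$fitting_radius
  nr <- nrow(frame); nc <- ncol(frame)
  keep <- candidates$row > r & candidates$row <= nr - r &
    candidates$col > r & candidates$col <= nc - r
  candidates <- candidates[keep, , drop = FALSE]
  rows <- list()
  n_failed <- 0L
  photons <- (frame - offset_adu) / camera$adu_per_photon
  for (i in seq_len(nrow(candidates))) {
    rr <- (candidates$row[i] - r):(candidates$row[i] + r)
    cc <- (candidates$col[i] - r):(candidates$col[i] + r)
    win <- photons[rr, cc]
    fit <- .fit_igauss(win, cc0 = candidates$col[i], rr0 = candidates$row[i],
                       cols = cc, rowsv = rr, sigma0 = params$initial_sigma)
    if (is.null(fit)) { n_failed <- n_failed + 1L; next }
    px <- camera$pixel_size
    # Thompson-style lateral uncertainty from photon statistics
    s_nm <- fit$sigma * px
    a <- px
    N <- max(fit$N, 1)
    b2 <- max(fit$b, 0)  # background variance per pixel (Poisson)
    unc <- sqrt((s_nm^2 + a^2 / 12) / N +
                  8 * pi * s_nm^4 * b2 / (a^2 * N^2))
    rows[[length(rows) + 1L]] <- data.frame(
      id = NA_integer_, frame = as.integer(frame_index),
      x = fit$x0 * px, y = fit$y0 * px,
      sigma = s_nm, intensity = fit$N, offset = fit$b,
      bkgstd = sqrt(b2), uncertainty = unc,
      channel = "ch1", detections_merged = 1L,
      stringsAsFactors = FALSE)
  }
  tab <- if (length(rows)) do.call(rbind, rows) else
    loc_table(numeric(0), numeric(0))[0, ]
  tab$id <- seq_len(nrow(tab))
  tab <- as_loc_table(tab)
  attr(tab, "n_failed") <- n_failed
  tab
}

# Levenberg-Marquardt weighted least squares of the integrated Gaussian;
# coordinates in pixel units where column c spans (c-1, c]
.fit_igauss <- function(win, cc0, rr0, cols, rowsv, sigma0) {
  b0 <- max(min(win), 0)
  N0 <- max(sum(win - b0), 1)
  start <- c(x0 = cc0 - 0.5, y0 = rr0 - 0.5, lsig = log(sigma0),
             N = N0, b = b0)
  w <- 1 / pmax(win, 1)
  resid_fn <- function(p) {
    s <- exp(p[3])
    ex <- .igauss_1d(cols, p[1], s)
    ey <- .igauss_1d(rowsv, p[2], s)
    model <- p[4] * outer(ey, ex) + p[5]
    as.vector(sqrt(w) * (model - win))
  }
  fit <- tryCatch(
    minpack.lm::nls.lm(par = start, fn = resid_fn,
                       control = minpack.lm::nls.lm.control(
                         maxiter = 100, ptol = 1e-10, ftol = 1e-10)),
    error = function(e) NULL)
  if (is.null(fit)) return(NULL)
  p <- fit$par
  s <- exp(p[3])
  # sanity: center must stay inside the window, sigma positive and bounded
  if (p[1] < min(cols) - 1 || p[1] > max(cols) ||
      p[2] < min(rowsv) - 1 || p[2] > max(rowsv) ||
      !is.finite(s) || s <= 0.2 || s > length(cols) || p[4] <= 0)
    return(NULL)
  list(x0 = unname(p[1]), y0 = unname(p[2]), sigma = unname(s),
       N = unname(p[4]), b = unname(p[5]))
}

#' Localize molecules in a full frame stack
#'
#' Runs [detect_candidates()] and [fit_spots()] frame by frame, optionally
#' after [temporal_background_filter()].
#'
#' @param stack Numeric array `[ny, nx, n_frames]` in ADU.
#' @param camera A [camera_model()].
#' @param detection A [detection_params()].
#' @param fitting A [fit_params()].
#' @param temporal A [temporal_filter_params()] or `NULL` to skip background
#'   filtering. When the filter is used the fit offset is taken as zero, as
#'   for offset-subtracted input.
#' @param channel Channel label for the output table.
#' @return A [loc_table()] with attribute `n_failed`.
#' @export
localize_stack <- function(stack, camera = camera_model(),
                           detection = detection_params(),
                           fitting = fit_params(),
                           temporal = NULL, channel = "ch1") {
  offset_adu <- camera$offset
  if (!is.null(temporal)) {
    stack <- temporal_background_filter(stack, temporal)$filtered
    offset_adu <- 0
  }
  nf <- dim(stack)[3]
  tabs <- vector("list", nf)
  n_failed <- 0L
  for (f in seq_len(nf)) {
    cand <- detect_candidates(stack[, , f], detection)
    tab <- fit_spots(stack[, , f], cand, camera, fitting,
                     offset_adu = offset_adu, frame_index = f)
    n_failed <- n_failed + attr(tab, "n_failed")
    tabs[[f]] <- as.data.frame(tab)
  }
  out <- do.call(rbind, tabs)
  out$id <- seq_len(nrow(out))
  out$channel <- channel
  out <- as_loc_table(out)
  attr(out, "n_failed") <- n_failed
  out
}
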