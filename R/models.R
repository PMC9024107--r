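# Generative models for the synthetic-data module. Each constructor
# validates its invariants once so downstream code can trust the objects.

#' Synapse model for the localization simulator
#'
#' Describes one synaptic compartment: a roughly disc-shaped scaffold of
#' radius `scaffold_radius` containing `n_nanodomains` Gaussian nanodomains
#' over a uniform localization background. The second channel carries
#' nanodomains displaced by `partner_offset`, emulating a partner protein.
#'
#' @param scaffold_center Numeric length-2, nm.
#' @param scaffold_radius Scaffold radius, nm.
#' @param n_nanodomains Number of nanodomains (>= 0).
#' @param nanodomain_centers Optional matrix (n x 2) of centers, nm; drawn
#'   uniformly within `0.7 * scaffold_radius` of the center when `NULL`.
#' @param nanodomain_sigma Nanodomain Gaussian SD, nm.
#' @param locs_per_nanodomain Expected localizations per nanodomain.
#' @param background_locs Expected background localizations (uniform over a
#'   disc of `1.5 * scaffold_radius`, so off-scaffold structure can be added).
#' @param partner_offset Numeric length-2 displacement of channel-2
#'   nanodomains relative to channel 1, nm.
#' @param min_separation Minimum center-to-center distance between
#'   nanodomains when centers are drawn, nm; nanodomains are distinct
#'   structures with typical spacings of order 100 nm or more.
#' @return An object of class `synapse_model`.
#' @export
synapse_model <- function(scaffold_center = c(1000, 1000),
                          scaffold_radius = 150,
                          n_nanodomains = 2,
                          nanodomain_centers = NULL,
                          nanodomain_sigma = 25,
                          locs_per_nanodomain = 150,
                          background_locs = 100,
                          partner_offset = c(0, 0),
                          min_separation = 80) {
  stopifnot(length(scaffold_center) == 2, scaffold_radius > 0,
            n_nanodomains >= 0, nanodomain_sigma > 0,
            locs_per_nanodomain >= 0, background_locs >= 0,
            length(partner_offset) == 2, min_separation >= 0)
  if (!is.null(nanodomain_centers)) {
    nanodomain_centers <- matrix(as.numeric(nanodomain_centers), ncol = 2)
    if (nrow(nanodomain_centers) != n_nanodomains)
      stop("nanodomain_centers must have one row per nanodomain")
    d <- sqrt(rowSums(sweep(nanodomain_centers, 2, scaffold_center)^2))
    if (any(d > scaffold_radius))
      stop("all nanodomain centers must lie within scaffold_radius of the center")
  }
  structure(list(scaffold_center = as.numeric(scaffold_center),
                 scaffold_radius = scaffold_radius,
                 n_nanodomains = as.integer(n_nanodomains),
                 nanodomain_centers = nanodomain_centers,
                 nanodomain_sigma = nanodomain_sigma,
                 locs_per_nanodomain = locs_per_nanodomain,
                 background_locs = background_locs,
                 partner_offset = as.numeric(partner_offset),
                 min_separation = min_separation),
            class = "synapse_model")
}

#' Noise model: per-localization attributes and blinking
#'
#' Per-localization precision, PSF sigma and intensity are drawn
#' independently of position. The number of appearances (blinks) per emitter
#' is `1 + Geometric(blink_p)`; appearances occupy random frames, or a
#' consecutive run when `blink_runs = TRUE` (to exercise frame-gap merging).
#'
#' @param precision_mean,precision_spread Lateral localization precision
#'   mean/SD, nm.
#' @param sigma_mean,sigma_spread Fitted PSF sigma mean/SD, nm.
#' @param intensity_meanlog,intensity_sdlog Log-normal photon-count
#'   parameters.
#' @param blink_p Geometric parameter; expected blinks per emitter is
#'   `1 + (1 - blink_p) / blink_p`.
#' @param n_frames Number of camera frames.
#' @param blink_runs Logical; appearances in consecutive frames.
#' @return An object of class `noise_model`.
#' @export
noise_model <- function(precision_mean = 8, precision_spread = 2,
                        sigma_mean = 110, sigma_spread = 15,
                        intensity_meanlog = log(2000), intensity_sdlog = 0.4,
                        blink_p = 0.5, n_frames = 5000L,
                        blink_runs = FALSE) {
  stopifnot(precision_mean > 0, precision_spread >= 0, sigma_mean > 0,
            sigma_spread >= 0, intensity_sdlog >= 0,
            blink_p > 0, blink_p <= 1, n_frames >= 1)
  structure(list(precision_mean = precision_mean,
                 precision_spread = precision_spread,
                 sigma_mean = sigma_mean, sigma_spread = sigma_spread,
                 intensity_meanlog = intensity_meanlog,
                 intensity_sdlog = intensity_sdlog,
                 blink_p = blink_p, n_frames = as.integer(n_frames),
                 blink_runs = isTRUE(blink_runs)),
            class = "noise_model")
}

#' Smooth inter-channel distortion field
#'
#' Polynomial displacement field `dx(x, y)`, `dy(x, y)` (nm) mapping channel
#' 1 positions to channel 2. Coefficients index the monomial basis
#' `1, u, v, u^2, u*v, v^2, ...` (degree-graded) in scaled coordinates
#' `u = x / field[1]`, `v = y / field[2]`, so coefficient magnitudes are in
#' nm. The evaluated magnitude is rescaled at construction so its maximum
#' over the field equals `max_magnitude`.
#'
#' @param coef_x,coef_y Numeric coefficient vectors (equal length, a
#'   triangular number: 1, 3, 6, 10 ...).
#' @param max_magnitude Peak displacement magnitude over the field, nm; `NULL`
#'   leaves coefficients unscaled.
#' @param field Field of view extent (width, height), nm.
#' @return An object of class `distortion_model`.
#' @export
distortion_model <- function(coef_x = c(30, 40, -25, 20, -15, 10),
                             coef_y = c(-20, 25, 35, -10, 15, -20),
                             max_magnitude = 100,
                             field = c(25000, 25000)) {
  stopifnot(length(coef_x) == length(coef_y), length(field) == 2,
            all(field > 0))
  deg <- .poly2d_degree(length(coef_x))
  m <- structure(list(coef_x = as.numeric(coef_x),
                      coef_y = as.numeric(coef_y),
                      degree = deg, field = as.numeric(field),
                      max_magnitude = max_magnitude),
                 class = "distortion_model")
  if (!is.null(max_magnitude)) {
    stopifnot(max_magnitude >= 0)
    g <- expand.grid(x = seq(0, field[1], length.out = 41),
                     y = seq(0, field[2], length.out = 41))
    d <- eval_distortion(m, g$x, g$y)
    peak <- max(sqrt(d[, 1]^2 + d[, 2]^2))
    if (peak > 0) {
      m$coef_x <- m$coef_x * max_magnitude / peak
      m$coef_y <- m$coef_y * max_magnitude / peak
    }
  }
  m
}

# number of monomials up to degree d is (d+1)(d+2)/2
.poly2d_degree <- function(ncoef) {
  d <- (sqrt(8 * ncoef + 1) - 3) / 2
  if (abs(d - round(d)) > 1e-9)
    stop("coefficient count must be a triangular number (1, 3, 6, 10, ...)")
  as.integer(round(d))
}

# degree-graded monomial design matrix: 1, u, v, u^2, uv, v^2, ...
.poly2d_design <- function(u, v, degree) {
  cols <- list()
  for (d in 0:degree)
    for (i in d:0)
      cols[[length(cols) + 1L]] <- u^i * v^(d - i)
  do.call(cbind, cols)
}

#' Evaluate a distortion field
#'
#' @param model A [distortion_model()].
#' @param x,y Coordinates in nm.
#' @return A two-column matrix of displacements (dx, dy) in nm.
#' @export
eval_distortion <- function(model, x, y) {
  X <- .poly2d_design(x / model$field[1], y / model$field[2], model$degree)
  cbind(dx = drop(X %*% model$coef_x), dy = drop(X %*% model$coef_y))
}

#' Lateral stage-drift trajectory
#'
#' Piecewise-linear drift `(dx(t), dy(t))` in nm over frames, defined by
#' knots at `knot_frames`. Drift at frame 1 is zero by construction when the
#' first knot is `(0, 0)`.
#'
#' @param knot_frames Increasing integer frames, first must be 1.
#' @param knot_dx,knot_dy Displacements at the knots, nm.
#' @return An object of class `drift_model`.
#' @export
drift_model <- function(knot_frames = c(1L, 5000L),
                        knot_dx = c(0, 100), knot_dy = c(0, 0)) {
  stopifnot(length(knot_frames) >= 2, knot_frames[1] == 1,
            all(diff(knot_frames) > 0),
            length(knot_dx) == length(knot_frames),
            length(knot_dy) == length(knot_frames))
  structure(list(knot_frames = as.integer(knot_frames),
                 knot_dx = as.numeric(knot_dx),
                 knot_dy = as.numeric(knot_dy)),
            class = "drift_model")
}

#' Evaluate drift at given frames
#'
#' Frames beyond the last knot hold the final displacement.
#'
#' @param model A [drift_model()].
#' @param frames Integer frames.
#' @return Two-column matrix (dx, dy), nm.
#' @export
eval_drift <- function(model, frames) {
  dx <- approx(model$knot_frames, model$knot_dx, xout = frames,
               rule = 2)$y
  dy <- approx(model$knot_frames, model$knot_dy, xout = frames,
               rule = 2)$y
  cbind(dx = dx, dy = dy)
}

#' EMCCD camera model
#'
#' With the EM gain at 100 one photoelectron converts to 1.65 digital units,
#' and the image pixel corresponds to 100 nm in the sample plane.
#'
#' @param em_gain EM gain setting (bookkeeping only).
#' @param adu_per_photon Digital units per photoelectron.
#' @param offset Camera baseline, ADU.
#' @param pixel_size Pixel size in the sample plane, nm.
#' @return An object of class `camera_model`.
#' @export
camera_model <- function(em_gain = 100, adu_per_photon = 1.65,
                         offset = 100, pixel_size = 100) {
  stopifnot(adu_per_photon > 0, pixel_size > 0, offset >= 0)
  structure(list(em_gain = em_gain, adu_per_photon = adu_per_photon,
                 offset = offset, pixel_size = pixel_size),
            class = "camera_model")
}
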