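# Rendering localization tables into images: average shifted histograms
# (ASH) at dSTORM resolution and fixed-width Gaussian "pseudo-SIM"
# renderings for cross-modality comparison.

#' Rendering parameters
#'
#' The output pixel size is the camera pixel divided by the magnification:
#' 10 nm for ASH at magnification 10, 40 nm for pseudo-SIM Gaussian
#' rendering at magnification 2.5.
#'
#' @param method `"ash"` or `"gaussian"`.
#' @param magnification Output magnification relative to the camera pixel.
#' @param ash_lateral_shift ASH lateral shift, nm (default 2).
#' @param gaussian_sigma Locked Gaussian kernel SD, nm (default 60).
#' @param camera_pixel Camera pixel size, nm (default 100).
#' @return An object of class `render_params`.
#' @export
render_params <- function(method = c("ash", "gaussian"),
                          magnification = NULL, ash_lateral_shift = 2,
                          gaussian_sigma = 60, camera_pixel = 100) {
  method <- match.arg(method)
  if (is.null(magnification))
    magnification <- if (method == "ash") 10 else 2.5
  stopifnot(magnification > 0, gaussian_sigma > 0, ash_lateral_shift > 0,
            camera_pixel > 0)
  pixel_size <- camera_pixel / magnification
  if (method == "ash" && ash_lateral_shift >= pixel_size)
    stop("ash_lateral_shift must be smaller than the output pixel size (",
         pixel_size, " nm)")
  structure(list(method = method, magnification = magnification,
                 ash_lateral_shift = ash_lateral_shift,
                 gaussian_sigma = gaussian_sigma,
                 camera_pixel = camera_pixel, pixel_size = pixel_size),
            class = "render_params")
}

.render_grid <- function(tab, pixel_size, extent, pad) {
  if (is.null(extent)) {
    if (nrow(tab)) {
      extent <- c(floor((min(tab$x) - pad) / pixel_size) * pixel_size,
                  ceiling((max(tab$x) + pad) / pixel_size) * pixel_size,
                  floor((min(tab$y) - pad) / pixel_size) * pixel_size,
                  ceiling((max(tab$y) + pad) / pixel_size) * pixel_size)
    } else extent <- c(0, pixel_size, 0, pixel_size)
  }
  nx <- max(1L, round((extent[2] - extent[1]) / pixel_size))
  ny <- max(1L, round((extent[4] - extent[3]) / pixel_size))
  list(origin = c(extent[1], extent[3]), nx = nx, ny = ny)
}

.new_rendered <- function(img, origin, pixel_size, method) {
  structure(list(img = img, origin = origin, pixel_size = pixel_size,
                 method = method),
            class = "rendered_image")
}

#' Average-shifted-histogram rendering
#'
#' Averages the 2D histograms computed on grids offset by all integer
#' multiples of the lateral shift that tile one output pixel in each axis.
#' Total image mass equals the number of localizations.
#'
#' @param tab A [loc_table()].
#' @param params A [render_params()] with `method = "ash"`.
#' @param extent Optional `c(xmin, xmax, ymin, ymax)` nm; derived from the
#'   data otherwise.
#' @return A `rendered_image` (row = y, column = x; pixel `[1,1]` covers the
#'   origin corner).
#' @export
render_ash <- function(tab, params = render_params("ash"), extent = NULL) {
  validate_loc_table(tab)
  stopifnot(params$method == "ash")
  ps <- params$pixel_size
  g <- .render_grid(tab, ps, extent, pad = ps)
  img <- matrix(0, g$ny, g$nx)
  n_sh <- max(1L, round(ps / params$ash_lateral_shift))
  offsets <- (seq_len(n_sh) - 1L) * params$ash_lateral_shift
  if (nrow(tab)) {
    for (ox in offsets) for (oy in offsets) {
      ix <- floor((tab$x - g$origin[1] + ox) / ps) + 1L
      iy <- floor((tab$y - g$origin[2] + oy) / ps) + 1L
      ok <- ix >= 1 & ix <= g$nx & iy >= 1 & iy <= g$ny
      if (any(ok)) {
        t1 <- tabulate((ix[ok] - 1L) * g$ny + iy[ok], nbins = g$nx * g$ny)
        img <- img + matrix(t1, g$ny, g$nx)
      }
    }
    img <- img / n_sh^2
  }
  .new_rendered(img, g$origin, ps, "ash")
}

#' Fixed-width Gaussian (pseudo-SIM) rendering
#'
#' Each localization contributes a unit-mass isotropic Gaussian of the
#' locked sigma, integrated exactly over the output pixels and truncated at
#' 4 sigma.
#'
#' @inheritParams render_ash
#' @param params A [render_params()] with `method = "gaussian"`.
#' @return A `rendered_image`.
#' @export
render_gaussian <- function(tab, params = render_params("gaussian"),
                            extent = NULL) {
  validate_loc_table(tab)
  stopifnot(params$method == "gaussian")
  ps <- params$pixel_size
  s <- params$gaussian_sigma
  g <- .render_grid(tab, ps, extent, pad = 4 * s + ps)
  img <- matrix(0, g$ny, g$nx)
  half <- ceiling(4 * s / ps)
  for (i in seq_len(nrow(tab))) {
    cx <- (tab$x[i] - g$origin[1]) / ps
    cy <- (tab$y[i] - g$origin[2]) / ps
    c0 <- max(1L, floor(cx) - half); c1 <- min(g$nx, ceiling(cx) + half)
    r0 <- max(1L, floor(cy) - half); r1 <- min(g$ny, ceiling(cy) + half)
    if (c0 > c1 || r0 > r1) next
    ex <- .igauss_1d(c0:c1, cx, s / ps)
    ey <- .igauss_1d(r0:r1, cy, s / ps)
    img[r0:r1, c0:c1] <- img[r0:r1, c0:c1] + outer(ey, ex)
  }
  .new_rendered(img, g$origin, ps, "gaussian")
}

#' @export
print.rendered_image <- function(x, ...) {
  cat(sprintf("%s rendering: %d x %d px at %.1f nm/px, mass %.1f\n",
              toupper(x$method), ncol(x$img), nrow(x$img), x$pixel_size,
              sum(x$img)))
  invisible(x)
}

#' @export
plot.rendered_image <- function(x, ...) {
  graphics::image(t(x$img)[, rev(seq_len(nrow(x$img)))],
                  col = grDevices::hcl.colors(64, "inferno"),
                  asp = nrow(x$img) / ncol(x$img), axes = FALSE, ...)
  invisible(x)
}

#' Write a rendered image as TIFF with a JSON sidecar
#'
#' The image is stored as 32-bit float TIFF scaled to `[0, 1]`; the scale
#' factor, origin and pixel size round-trip through the sidecar
#' (`<path>.json`).
#'
#' @param x A `rendered_image`.
#' @param path Output TIFF path.
#' @return `path`, invisibly.
#' @export
write_rendered_tiff <- function(x, path) {
  stopifnot(inherits(x, "rendered_image"))
  peak <- max(x$img, 1e-12)
  tiff::writeTIFF(x$img / peak, path, bits.per.sample = 32L)
  jsonlite::write_json(
    list(scale = peak, origin = x$origin, pixel_size = x$pixel_size,
         method = x$method),
    paste0(path, ".json"), auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_rendered_tiff
#' @export
read_rendered_tiff <- function(path) {
  img <- tiff::readTIFF(path)
  meta <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  .new_rendered(img * meta$scale, meta$origin, meta$pixel_size, meta$method)
}
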