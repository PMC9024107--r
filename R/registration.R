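# Bead-based two-channel registration: mutual-nearest-neighbour matching,
# displacement-field fitting (2D polynomial or localized weighted
# averaging), and application to localization tables.

#' Match bead localizations between channels
#'
#' Mutual nearest neighbours within a distance cutoff. The cutoff default
#' (300 nm) is three times the scale of the largest expected inter-channel
#' distortion.
#'
#' @param beads_ch1,beads_ch2 `data.frame`s with columns `x`, `y` (nm).
#' @param cutoff Maximum match distance, nm.
#' @return `data.frame` of matched pairs (`x1`, `y1`, `x2`, `y2`, `dx`,
#'   `dy`, `dist`), with attributes `unmatched_ch1` / `unmatched_ch2`
#'   (indices). Zero matches is an error.
#' @export
register_bead_pairs <- function(beads_ch1, beads_ch2, cutoff = 300) {
  stopifnot(nrow(beads_ch1) > 0, nrow(beads_ch2) > 0, cutoff > 0)
  d <- outer(beads_ch1$x, beads_ch2$x, "-")^2 +
    outer(beads_ch1$y, beads_ch2$y, "-")^2
  nn12 <- apply(d, 1, which.min)
  nn21 <- apply(d, 2, which.min)
  i <- seq_len(nrow(beads_ch1))
  mutual <- nn21[nn12] == i & sqrt(d[cbind(i, nn12)]) <= cutoff
  if (!any(mutual))
    stop("no mutual-nearest-neighbour bead matches within ", cutoff, " nm")
  i1 <- i[mutual]; i2 <- nn12[mutual]
  pairs <- data.frame(
    x1 = beads_ch1$x[i1], y1 = beads_ch1$y[i1],
    x2 = beads_ch2$x[i2], y2 = beads_ch2$y[i2])
  pairs$dx <- pairs$x1 - pairs$x2
  pairs$dy <- pairs$y1 - pairs$y2
  pairs$dist <- sqrt(d[cbind(i1, i2)])
  attr(pairs, "unmatched_ch1") <- setdiff(i, i1)
  attr(pairs, "unmatched_ch2") <- setdiff(seq_len(nrow(beads_ch2)), i2)
  pairs
}

#' Fit a two-channel calibration model
#'
#' Estimates the smooth displacement field `(dx(x, y), dy(x, y))` that maps
#' channel-2 positions onto channel 1, either as a 2D polynomial
#' least-squares fit or by localized (Gaussian-kernel) weighted averaging of
#' the bead displacements.
#'
#' @param pairs Matched pairs from [register_bead_pairs()], or any
#'   `data.frame` with `x2`, `y2`, `dx`, `dy`.
#' @param method `"polynomial"` or `"lwa"` (localized weighted averaging).
#' @param degree Polynomial degree (default 2).
#' @param bandwidth Gaussian kernel SD for `"lwa"`, nm; default is the
#'   median nearest-neighbour bead spacing.
#' @param cv Logical; when `TRUE` also report a leave-one-out RMS residual.
#' @return An object of class `calibration_model` with the fitted field,
#'   `rms_residual` (nm, on the fitting pairs) and `n_beads`.
#' @export
fit_calibration <- function(pairs, method = c("polynomial", "lwa"),
                            degree = 2L, bandwidth = NULL, cv = FALSE) {
  method <- match.arg(method)
  stopifnot(all(c("x2", "y2", "dx", "dy") %in% names(pairs)))
  n <- nrow(pairs)
  scale <- c(max(abs(pairs$x2), 1), max(abs(pairs$y2), 1))
  if (method == "polynomial") {
    ncoef <- (degree + 1) * (degree + 2) / 2
    if (n < ncoef)
      stop(sprintf("%d pairs cannot determine a degree-%d field (%d coefficients)",
                   n, degree, ncoef))
    X <- .poly2d_design(pairs$x2 / scale[1], pairs$y2 / scale[2], degree)
    qrX <- qr(X)
    if (qrX$rank < ncoef)
      stop("rank-deficient design (collinear beads?); try a lower degree")
    cx <- qr.coef(qrX, pairs$dx)
    cy <- qr.coef(qrX, pairs$dy)
    model <- structure(list(method = "polynomial", degree = as.integer(degree),
                            coef_x = cx, coef_y = cy, scale = scale,
                            n_beads = n,
                            bbox = c(range(pairs$x2), range(pairs$y2))),
                       class = "calibration_model")
  } else {
    if (is.null(bandwidth)) {
      d <- as.matrix(dist(cbind(pairs$x2, pairs$y2)))
      diag(d) <- Inf
      bandwidth <- max(median(apply(d, 1, min)), 1e-6)
    }
    model <- structure(list(method = "lwa", bandwidth = bandwidth,
                            anchors_x = pairs$x2, anchors_y = pairs$y2,
                            anchors_dx = pairs$dx, anchors_dy = pairs$dy,
                            scale = scale, n_beads = n,
                            bbox = c(range(pairs$x2), range(pairs$y2))),
                       class = "calibration_model")
  }
  pred <- predict(model, pairs$x2, pairs$y2)
  res <- sqrt((pred[, 1] - pairs$dx)^2 + (pred[, 2] - pairs$dy)^2)
  model$rms_residual <- sqrt(mean(res^2))
  if (cv) {
    cvres <- vapply(seq_len(n), function(i) {
      m <- fit_calibration(pairs[-i, , drop = FALSE], method = method,
                           degree = degree, bandwidth = bandwidth, cv = FALSE)
      p <- predict(m, pairs$x2[i], pairs$y2[i])
      (p[, 1] - pairs$dx[i])^2 + (p[, 2] - pairs$dy[i])^2
    }, numeric(1))
    model$rms_residual_cv <- sqrt(mean(cvres))
  }
  model
}

#' Evaluate a calibration model
#'
#' @param object A `calibration_model`.
#' @param x,y Coordinates (nm) at which to evaluate the displacement field.
#' @param ... Unused.
#' @return Two-column matrix `(dx, dy)`, nm.
#' @export
predict.calibration_model <- function(object, x, y, ...) {
  if (object$method == "polynomial") {
    X <- .poly2d_design(x / object$scale[1], y / object$scale[2],
                        object$degree)
    cbind(dx = drop(X %*% object$coef_x), dy = drop(X %*% object$coef_y))
  } else {
    dx <- numeric(length(x)); dy <- numeric(length(x))
    b2 <- 2 * object$bandwidth^2
    for (i in seq_along(x)) {
      w <- exp(-((object$anchors_x - x[i])^2 +
                   (object$anchors_y - y[i])^2) / b2)
      if (sum(w) < 1e-300) {
        # far outside the anchor cloud: fall back to the nearest anchor
        j <- which.min((object$anchors_x - x[i])^2 +
                         (object$anchors_y - y[i])^2)
        w <- replace(numeric(length(w)), j, 1)
      }
      dx[i] <- sum(w * object$anchors_dx) / sum(w)
      dy[i] <- sum(w * object$anchors_dy) / sum(w)
    }
    cbind(dx = dx, dy = dy)
  }
}

#' @export
print.calibration_model <- function(x, ...) {
  cat(sprintf("Channel calibration (%s%s): %d beads, RMS residual %.2f nm\n",
              x$method,
              if (x$method == "polynomial")
                paste0(", degree ", x$degree)
              else sprintf(", bandwidth %.0f nm", x$bandwidth),
              x$n_beads, x$rms_residual))
  invisible(x)
}

#' Apply a calibration to a localization table
#'
#' Displaces each record by the evaluated field; all other attributes are
#' unchanged. Coordinates outside the bead-spanned bounding box (plus 10%)
#' are displaced by the model's extrapolation with a warning.
#'
#' @param tab A [loc_table()].
#' @param model A `calibration_model` from [fit_calibration()].
#' @return The aligned table.
#' @export
apply_calibration <- function(tab, model) {
  validate_loc_table(tab)
  stopifnot(inherits(model, "calibration_model"))
  if (!nrow(tab)) return(tab)
  bb <- model$bbox
  mx <- 0.1 * (bb[2] - bb[1]); my <- 0.1 * (bb[4] - bb[3])
  out_of_range <- tab$x < bb[1] - mx | tab$x > bb[2] + mx |
    tab$y < bb[3] - my | tab$y > bb[4] + my
  if (any(out_of_range))
    warning(sum(out_of_range),
            " localization(s) outside the bead-calibrated region; ",
            "displaced by extrapolation")
  d <- predict(model, tab$x, tab$y)
  tab$x <- tab$x + d[, 1]
  tab$y <- tab$y + d[, 2]
  tab
}

#' Save / load a calibration model as JSON
#'
#' @param model A `calibration_model`.
#' @param path JSON file path.
#' @return `write_calibration()` returns `path` invisibly;
#'   `read_calibration()` returns the model.
#' @export
write_calibration <- function(model, path) {
  stopifnot(inherits(model, "calibration_model"))
  jsonlite::write_json(unclass(model), path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_calibration
#' @export
read_calibration <- function(path) {
  m <- jsonlite::read_json(path, simplifyVector = TRUE)
  m$degree <- if (!is.null(m$degree)) as.integer(m$degree)
  structure(m, class = "calibration_model")
}
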