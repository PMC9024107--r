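# Redundant cross-correlation (RCC) drift estimation: pairwise shifts
# between temporal segments from 2D-histogram cross-correlation, solved as
# an over-determined linear system with outlier-pair rejection.

#' RCC parameters
#'
#' @param segment_length Frames per temporal segment; default 500.
#' @param bin_size Histogram bin size, nm; default 10.
#' @param error_threshold Pairwise-residual rejection threshold, camera
#'   pixels; default 5.
#' @param pixel_size Camera pixel size used to convert the threshold to nm;
#'   default 100.
#' @return An object of class `rcc_params`.
#' @export
rcc_params <- function(segment_length = 500L, bin_size = 10,
                       error_threshold = 5, pixel_size = 100) {
  stopifnot(segment_length >= 2, bin_size > 0, error_threshold > 0,
            pixel_size > 0)
  structure(list(segment_length = as.integer(segment_length),
                 bin_size = bin_size, error_threshold = error_threshold,
                 pixel_size = pixel_size),
            class = "rcc_params")
}

# cross-correlation of two equally-sized 2D histograms via FFT;
# returns the sub-bin shift (in bins) of b relative to a, located by the
# correlation peak refined with a 3x3 centroid
.xcorr_shift <- function(a, b) {
  d <- dim(a)
  # zero-pad to avoid circular wrap
  P <- 2 * d
  A <- matrix(0, P[1], P[2]); A[1:d[1], 1:d[2]] <- a
  B <- matrix(0, P[1], P[2]); B[1:d[1], 1:d[2]] <- b
  cc <- Re(fft(fft(A) * Conj(fft(B)), inverse = TRUE))
  pk <- unname(which(cc == max(cc), arr.ind = TRUE)[1, ])
  # lag indices: position k corresponds to shift (k-1), wrapped
  lag <- function(k, n) { s <- k - 1L; if (s > n) s - 2L * n else s }
  s_r <- lag(pk[1], d[1]); s_c <- lag(pk[2], d[2])
  # 3x3 centroid around the peak (circular indexing on the padded grid)
  wrap <- function(k, n) ((k - 1) %% n) + 1
  rows <- wrap(pk[1] + (-1:1), P[1]); cols <- wrap(pk[2] + (-1:1), P[2])
  w <- cc[rows, cols]
  w <- w - min(w)
  if (sum(w) > 0) {
    dr <- sum((-1:1) * rowSums(w)) / sum(w)
    dc <- sum((-1:1) * colSums(w)) / sum(w)
  } else dr <- dc <- 0
  c(row = s_r + dr, col = s_c + dc)
}

#' Estimate lateral drift by redundant cross-correlation
#'
#' Localizations are binned into per-segment 2D histograms; shifts between
#' all segment pairs are estimated from the cross-correlation peak with
#' sub-bin (3x3 centroid) refinement, and per-segment drift is solved by
#' least squares over the redundant pairwise system. Pairs whose residual
#' exceeds the error threshold (converted to nm via the camera pixel size)
#' are discarded once and the system re-solved. The per-frame trace
#' interpolates linearly between segment midpoints and is zero at the first
#' (reference) segment.
#'
#' @param tab A [loc_table()] spanning at least two segments.
#' @param params An [rcc_params()].
#' @return An object of class `drift_trace`: per-segment estimates, the
#'   per-frame interpolated trace, and the retained pair set.
#' @export
estimate_drift_rcc <- function(tab, params = rcc_params()) {
  validate_loc_table(tab)
  f0 <- min(tab$frame); f1 <- max(tab$frame)
  n_seg <- floor((f1 - f0 + 1) / params$segment_length)
  if (n_seg < 2)
    stop("table spans fewer than 2 segments of ", params$segment_length,
         " frames")
  seg_of <- pmin(((tab$frame - f0) %/% params$segment_length) + 1L, n_seg)
  bs <- params$bin_size
  xr <- range(tab$x); yr <- range(tab$y)
  xb <- seq(floor(xr[1] / bs) * bs, xr[2] + bs, by = bs)
  yb <- seq(floor(yr[1] / bs) * bs, yr[2] + bs, by = bs)
  nxb <- length(xb) - 1L; nyb <- length(yb) - 1L
  H <- lapply(seq_len(n_seg), function(s) {
    sel <- seg_of == s
    if (!any(sel)) return(matrix(0, nyb, nxb))
    ix <- findInterval(tab$x[sel], xb, rightmost.closed = TRUE)
    iy <- findInterval(tab$y[sel], yb, rightmost.closed = TRUE)
    matrix(tabulate((ix - 1L) * nyb + iy, nbins = nxb * nyb), nyb, nxb)
  })
  pairs <- t(utils::combn(n_seg, 2))
  shifts <- matrix(NA_real_, nrow(pairs), 2)  # dx, dy of segment j vs i, nm
  for (k in seq_len(nrow(pairs))) {
    s <- .xcorr_shift(H[[pairs[k, 2]]], H[[pairs[k, 1]]])
    shifts[k, ] <- c(s["col"], s["row"]) * bs
  }
  # design: d_j - d_i = shift_ij, with d_1 = 0 (reference segment)
  solve_pairs <- function(keep) {
    A <- matrix(0, sum(keep), n_seg - 1L)
    for (r in seq_len(nrow(pairs))[keep]) {
      i <- pairs[r, 1]; j <- pairs[r, 2]
      rr <- sum(keep[seq_len(r)])
      if (i > 1) A[rr, i - 1L] <- -1
      if (j > 1) A[rr, j - 1L] <- 1
    }
    qa <- qr(A)
    dx <- qr.coef(qa, shifts[keep, 1])
    dy <- qr.coef(qa, shifts[keep, 2])
    dx[is.na(dx)] <- 0; dy[is.na(dy)] <- 0
    list(dx = c(0, dx), dy = c(0, dy), A = A)
  }
  keep <- rep(TRUE, nrow(pairs))
  sol <- solve_pairs(keep)
  # residual magnitude per pair; single re-solve after rejection
  resid <- sqrt((sol$dx[pairs[, 2]] - sol$dx[pairs[, 1]] - shifts[, 1])^2 +
                  (sol$dy[pairs[, 2]] - sol$dy[pairs[, 1]] - shifts[, 2])^2)
  thr_nm <- params$error_threshold * params$pixel_size
  drop_pairs <- keep & resid > thr_nm
  if (any(drop_pairs)) {
    keep <- keep & !drop_pairs
    if (sum(keep) < n_seg - 1L)
      stop("too many segment pairs rejected (residual quartiles: ",
           paste(signif(quantile(resid), 3), collapse = ", "), " nm)")
    sol <- solve_pairs(keep)
  }
  mids <- f0 + (seq_len(n_seg) - 0.5) * params$segment_length
  frames <- f0:f1
  per_frame <- cbind(
    frame = frames,
    dx = approx(mids, sol$dx, xout = frames, rule = 2)$y,
    dy = approx(mids, sol$dy, xout = frames, rule = 2)$y)
  structure(list(segment_midframes = mids,
                 segment_dx = sol$dx, segment_dy = sol$dy,
                 trace = as.data.frame(per_frame),
                 pairs = pairs, pair_shifts = shifts,
                 pair_residuals = resid, pair_kept = keep,
                 params = params),
            class = "drift_trace")
}

#' @export
print.drift_trace <- function(x, ...) {
  cat(sprintf(
    "RCC drift trace: %d segments, %d/%d pairs retained, max |drift| %.1f nm\n",
    length(x$segment_dx), sum(x$pair_kept), nrow(x$pairs),
    max(sqrt(x$trace$dx^2 + x$trace$dy^2))))
  invisible(x)
}

#' @export
plot.drift_trace <- function(x, ...) {
  graphics::matplot(x$trace$frame, cbind(x$trace$dx, x$trace$dy),
                    type = "l", lty = 1, col = c("steelblue", "firebrick"),
                    xlab = "frame", ylab = "drift (nm)", ...)
  graphics::legend("topleft", c("x", "y"), lty = 1,
                   col = c("steelblue", "firebrick"), bty = "n")
  invisible(x)
}

#' Apply a drift correction to a localization table
#'
#' Subtracts the per-frame trace from each record's position.
#'
#' @param tab A [loc_table()].
#' @param trace A `drift_trace` from [estimate_drift_rcc()], or a
#'   `data.frame` with `frame`, `dx`, `dy` covering all frames in `tab`.
#' @return The corrected table.
#' @export
apply_drift_correction <- function(tab, trace) {
  validate_loc_table(tab)
  tr <- if (inherits(trace, "drift_trace")) trace$trace else trace
  if (!nrow(tab)) return(tab)
  idx <- match(tab$frame, tr$frame)
  if (anyNA(idx))
    stop("trace does not cover frame(s) ",
         paste(head(unique(tab$frame[is.na(idx)]), 5), collapse = ", "))
  tab$x <- tab$x - tr$dx[idx]
  tab$y <- tab$y - tr$dy[idx]
  tab
}
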