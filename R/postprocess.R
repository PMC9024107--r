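# Quality filtering and temporal merging of localization tables.

#' Quality-filter thresholds
#'
#' Defaults follow the standard acquisition settings: uncertainty below
#' 20 nm, sigma between 50 and 150 nm, and a per-dye intensity ceiling
#' (10,000 photons for CF568-like dyes, 15,000 for Alexa647-like dyes).
#'
#' @param max_uncertainty Maximum lateral uncertainty, nm (exclusive).
#' @param sigma_min,sigma_max Allowed fitted sigma range, nm (inclusive).
#' @param max_intensity Named numeric vector of per-channel intensity
#'   ceilings (exclusive), photons; or a single unnamed ceiling for all
#'   channels.
#' @return An object of class `filter_thresholds`.
#' @export
filter_thresholds <- function(max_uncertainty = 20,
                              sigma_min = 50, sigma_max = 150,
                              max_intensity = c(CF568 = 10000, A647 = 15000)) {
  max_intensity <- unlist(max_intensity)
  stopifnot(max_uncertainty > 0, sigma_min < sigma_max, sigma_min > 0,
            all(max_intensity > 0))
  structure(list(max_uncertainty = max_uncertainty,
                 sigma_min = sigma_min, sigma_max = sigma_max,
                 max_intensity = max_intensity),
            class = "filter_thresholds")
}

#' Filter localizations on uncertainty, sigma and intensity
#'
#' A record is kept iff `uncertainty < max_uncertainty`,
#' `sigma_min <= sigma <= sigma_max` and `intensity` is below the ceiling of
#' its channel. Record order is preserved; per-criterion rejection counts
#' are attached as attribute `rejections`.
#'
#' @param tab A [loc_table()].
#' @param thresholds A [filter_thresholds()].
#' @return The filtered table.
#' @export
filter_localizations <- function(tab, thresholds = filter_thresholds()) {
  validate_loc_table(tab)
  t <- thresholds
  if (!nrow(tab)) {
    attr(tab, "rejections") <- c(uncertainty = 0L, sigma = 0L, intensity = 0L)
    return(tab)
  }
  if (is.null(names(t$max_intensity)) || length(t$max_intensity) == 1) {
    ceiling_i <- rep(t$max_intensity[[1]], nrow(tab))
  } else {
    unknown <- setdiff(unique(tab$channel), names(t$max_intensity))
    if (length(unknown))
      stop("no intensity threshold for channel(s) ",
           paste(unknown, collapse = ", "), "; known: ",
           paste(names(t$max_intensity), collapse = ", "))
    ceiling_i <- t$max_intensity[tab$channel]
  }
  ok_u <- tab$uncertainty < t$max_uncertainty
  ok_s <- tab$sigma >= t$sigma_min & tab$sigma <= t$sigma_max
  ok_i <- tab$intensity < ceiling_i
  out <- tab[ok_u & ok_s & ok_i, , drop = FALSE]
  rownames(out) <- NULL
  out <- as_loc_table(out)
  attr(out, "rejections") <- c(uncertainty = sum(!ok_u),
                               sigma = sum(!ok_s),
                               intensity = sum(!ok_i))
  out
}

#' Merge parameters for repeated blink detections
#'
#' A frame-gap allowance of 1 permits one dark frame between consecutive
#' appearances of the same molecule.
#'
#' @param radius Merge radius, nm; default 50.
#' @param frame_gap Allowed dark frames between appearances; default 1.
#' @param intensity_weighted Use intensity-weighted mean positions (default);
#'   `FALSE` for unweighted means.
#' @return An object of class `merge_params`.
#' @export
merge_params <- function(radius = 50, frame_gap = 1L,
                         intensity_weighted = TRUE) {
  if (radius <= 0) stop("merge radius must be positive")
  stopifnot(frame_gap >= 0)
  structure(list(radius = radius, frame_gap = as.integer(frame_gap),
                 intensity_weighted = isTRUE(intensity_weighted)),
            class = "merge_params")
}

#' Merge repeated localizations of the same molecule
#'
#' Records are grouped greedily in frame order: a record joins an open group
#' if it lies within `radius` of the group's current mean position and its
#' frame exceeds the group's last frame by at most `frame_gap + 1`. Ties
#' between open groups go to the nearer mean, then to the lower group id.
#' A merged record carries the (intensity-weighted) mean position, summed
#' intensity, first frame, minimum uncertainty, and
#' `detections_merged = group size`.
#'
#' @param tab A [loc_table()]; sorted by frame if it is not.
#' @param params A [merge_params()].
#' @return The merged table (`sum(detections_merged)` equals the input row
#'   count).
#' @export
merge_localizations <- function(tab, params = merge_params()) {
  validate_loc_table(tab)
  if (!nrow(tab)) return(tab)
  if (is.unsorted(tab$frame)) tab <- tab[order(tab$frame, tab$id), ]
  n <- nrow(tab)
  grp <- integer(n)
  # open groups: running weighted mean, weight sum, last frame
  gx <- numeric(0); gy <- numeric(0); gw <- numeric(0); glast <- integer(0)
  open <- integer(0)  # indices into g* vectors that are still open
  max_jump <- params$frame_gap + 1L
  r2 <- params$radius^2
  for (i in seq_len(n)) {
    f <- tab$frame[i]
    if (length(open)) open <- open[f - glast[open] <= max_jump]
    best <- 0L
    if (length(open)) {
      d2 <- (gx[open] - tab$x[i])^2 + (gy[open] - tab$y[i])^2
      ok <- d2 <= r2
      if (any(ok)) {
        cand <- open[ok]
        best <- cand[order(d2[ok], cand)][1]
      }
    }
    w <- if (params$intensity_weighted) max(tab$intensity[i], 1e-12) else 1
    if (best == 0L) {
      gx <- c(gx, tab$x[i]); gy <- c(gy, tab$y[i])
      gw <- c(gw, w); glast <- c(glast, f)
      best <- length(gx)
      open <- c(open, best)
    } else {
      wt <- gw[best] + w
      gx[best] <- (gx[best] * gw[best] + tab$x[i] * w) / wt
      gy[best] <- (gy[best] * gw[best] + tab$y[i] * w) / wt
      gw[best] <- wt
      glast[best] <- f
    }
    grp[i] <- best
  }
  idx <- split(seq_len(n), grp)
  rows <- lapply(idx, function(ii) {
    w <- if (params$intensity_weighted)
      pmax(tab$intensity[ii], 1e-12) else rep(1, length(ii))
    data.frame(
      id = NA_integer_,
      frame = min(tab$frame[ii]),
      x = sum(tab$x[ii] * w) / sum(w),
      y = sum(tab$y[ii] * w) / sum(w),
      sigma = sum(tab$sigma[ii] * w) / sum(w),
      intensity = sum(tab$intensity[ii]),
      offset = mean(tab$offset[ii]),
      bkgstd = mean(tab$bkgstd[ii]),
      uncertainty = min(tab$uncertainty[ii]),
      channel = tab$channel[ii][1],
      detections_merged = sum(tab$detections_merged[ii]),
      stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out <- out[order(out$frame), , drop = FALSE]
  out$id <- seq_len(nrow(out))
  rownames(out) <- NULL
  as_loc_table(out)
}
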