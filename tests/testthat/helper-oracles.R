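# Independent brute-force oracles used across the suite. Each one is a
# from-first-principles reimplementation kept deliberately naive and
# separate from the package's code paths.

# direct per-pixel running-quantile background (no key-frame interpolation)
oracle_temporal_quantile <- function(stack, radius, q) {
  d <- dim(stack)
  half <- (radius - 1L) %/% 2L
  bg <- array(NA_real_, d)
  for (f in seq_len(d[3])) {
    win <- max(1L, f - half):min(d[3], f + half)
    for (i in seq_len(d[1]))
      for (j in seq_len(d[2]))
        bg[i, j, f] <- quantile(stack[i, j, win], probs = q, names = FALSE)
  }
  bg
}

# exhaustive transcription of the greedy merge rule, recomputing group means
# from scratch at every step (no running update, no vectorization)
oracle_merge_groups <- function(tab, radius, frame_gap,
                                intensity_weighted = TRUE) {
  o <- order(tab$frame, tab$id)
  tab <- tab[o, ]
  n <- nrow(tab)
  group <- integer(n)
  ngroups <- 0L
  for (i in seq_len(n)) {
    best <- 0L; best_d <- Inf
    for (g in seq_len(ngroups)) {
      members <- which(group[seq_len(i - 1L)] == g)
      if (!length(members)) next
      if (tab$frame[i] - max(tab$frame[members]) > frame_gap + 1L) next
      w <- if (intensity_weighted) pmax(tab$intensity[members], 1e-12)
           else rep(1, length(members))
      mx <- sum(tab$x[members] * w) / sum(w)
      my <- sum(tab$y[members] * w) / sum(w)
      d <- sqrt((tab$x[i] - mx)^2 + (tab$y[i] - my)^2)
      if (d <= radius && (d < best_d - 1e-12 ||
                          (abs(d - best_d) <= 1e-12 && g < best))) {
        best <- g; best_d <- d
      }
    }
    if (best == 0L) { ngroups <- ngroups + 1L; best <- ngroups }
    group[i] <- best
  }
  # return membership as a canonical list of sorted original ids
  split(tab$id, group)
}

# mutual nearest neighbours by exhaustive O(n^2) search
oracle_mutual_nn <- function(a, b, cutoff) {
  out <- list()
  for (i in seq_len(nrow(a))) {
    d <- sqrt((b$x - a$x[i])^2 + (b$y - a$y[i])^2)
    j <- which.min(d)
    d2 <- sqrt((a$x - b$x[j])^2 + (a$y - b$y[j])^2)
    if (which.min(d2) == i && d[j] <= cutoff)
      out[[length(out) + 1L]] <- c(i, j)
  }
  do.call(rbind, out)
}

# naive ASH: explicit loop over every offset histogram
oracle_ash <- function(tab, origin, nx, ny, pixel, shift) {
  n_sh <- round(pixel / shift)
  acc <- matrix(0, ny, nx)
  for (ox in (seq_len(n_sh) - 1) * shift) {
    for (oy in (seq_len(n_sh) - 1) * shift) {
      h <- matrix(0, ny, nx)
      for (k in seq_len(nrow(tab))) {
        ix <- floor((tab$x[k] - origin[1] + ox) / pixel) + 1
        iy <- floor((tab$y[k] - origin[2] + oy) / pixel) + 1
        if (ix >= 1 && ix <= nx && iy >= 1 && iy <= ny)
          h[iy, ix] <- h[iy, ix] + 1
      }
      acc <- acc + h
    }
  }
  acc / n_sh^2
}

# alpha-shape area from an independent Delaunay triangulation
# (scipy.spatial.Delaunay through the system python)
oracle_alpha_area_scipy <- function(pts, alpha) {
  fin <- tempfile(fileext = ".csv"); fout <- tempfile(fileext = ".txt")
  write.csv(data.frame(x = pts[, 1], y = pts[, 2]), fin, row.names = FALSE)
  script <- sprintf('
import numpy as np
from scipy.spatial import Delaunay
pts = np.loadtxt(%s, delimiter=",", skiprows=1)
tri = Delaunay(pts)
area = 0.0
for s in tri.simplices:
    a, b, c = pts[s[0]], pts[s[1]], pts[s[2]]
    u, v = b - a, c - a
    A = abs(u[0] * v[1] - u[1] * v[0]) / 2.0
    if A <= 0:
        continue
    la, lb, lc = np.linalg.norm(b - c), np.linalg.norm(a - c), np.linalg.norm(a - b)
    R = la * lb * lc / (4.0 * A)
    if R <= %.17g:
        area += A
print("%%.17g" %% area)
', deparse(fin), alpha)
  fpy <- tempfile(fileext = ".py")
  writeLines(script, fpy)
  out <- system2("python", fpy, stdout = TRUE)
  as.numeric(out[length(out)])
}

# convex hull area (base chull + shoelace)
oracle_chull_area <- function(pts) {
  h <- chull(pts)
  j <- c(h[-1], h[1])
  abs(sum(pts[h, 1] * pts[j, 2] - pts[j, 1] * pts[h, 2])) / 2
}

# direct pseudo-inverse solve of the redundant pairwise drift system
oracle_rcc_solve <- function(pairs, shifts, kept, n_seg) {
  A <- matrix(0, sum(kept), n_seg - 1L)
  r <- 0L
  for (k in which(kept)) {
    r <- r + 1L
    if (pairs[k, 1] > 1) A[r, pairs[k, 1] - 1L] <- -1
    if (pairs[k, 2] > 1) A[r, pairs[k, 2] - 1L] <- 1
  }
  pinv <- MASS::ginv(A)
  list(dx = c(0, pinv %*% shifts[kept, 1]),
       dy = c(0, pinv %*% shifts[kept, 2]))
}

# fixture: localization table with explicit positions on chosen frames
fix_tab <- function(x, y, frame = seq_along(x), intensity = 1000, ...) {
  loc_table(x, y, frame = frame, intensity = intensity, sigma = 120,
            uncertainty = 10, ...)
}
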