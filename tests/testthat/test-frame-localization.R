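test_that("temporal filter background of a constant stack is the constant", {
  st <- array(100, c(6, 6, 120))
  tf <- temporal_background_filter(st, temporal_filter_params())
  expect_true(all(tf$background == 100))
  expect_true(all(tf$filtered == 0))
})

test_that("20% quantile background is robust to a single-frame spike", {
  st <- array(100, c(6, 6, 120))
  st[3, 3, 60] <- 1000
  tf <- temporal_background_filter(st, temporal_filter_params())
  # oracle: direct per-pixel window quantile (no key-frame interpolation)
  bg <- oracle_temporal_quantile(st, radius = 51, q = 0.20)
  expect_equal(tf$background[3, 3, 60], bg[3, 3, 60])
  expect_equal(tf$background[3, 3, 60], 100)
  expect_equal(tf$filtered[3, 3, 60], 900)
})

test_that("key_frame_distance = 1 equals the per-frame quantile oracle exactly", {
  set.seed(21)
  st <- array(rpois(5 * 5 * 80, 50), c(5, 5, 80))
  tf <- temporal_background_filter(
    st, temporal_filter_params(radius = 21, key_frame_distance = 1))
  bg <- oracle_temporal_quantile(st, radius = 21, q = 0.20)
  expect_equal(tf$background, bg, tolerance = 1e-12)
})

test_that("key-frame interpolation tracks a linear ramp within 1 ADU", {
  nf <- 300
  st <- array(0, c(4, 4, nf))
  for (f in seq_len(nf)) st[, , f] <- seq(100, 200, length.out = nf)[f]
  p10 <- temporal_background_filter(
    st, temporal_filter_params(radius = 51, key_frame_distance = 10))
  p1 <- temporal_background_filter(
    st, temporal_filter_params(radius = 51, key_frame_distance = 1))
  expect_lt(max(abs(p10$background - p1$background)), 1)
})

test_that("stack shorter than the filter radius is rejected with the minimum", {
  expect_error(temporal_background_filter(array(0, c(4, 4, 30)),
                                          temporal_filter_params()),
               "more than 51")
})

test_that("candidate detection finds isolated spots and nothing on flat frames", {
  expect_identical(nrow(detect_candidates(matrix(0, 32, 32))), 0L)
  expect_identical(nrow(detect_candidates(matrix(7, 32, 32))), 0L)

  set.seed(3)
  fr <- matrix(rnorm(64 * 64, 10, 1), 64, 64)
  # integrated-Gaussian spot centered on pixel (20, 20)
  cam <- camera_model(offset = 0)
  ev <- data.frame(frame = 1, x = 1950, y = 1950, photons = 5000,
                   psf_sigma = 130)
  spot <- simulate_frame_stack(ev, cam, dims = c(64, 64), seed = NULL)[, , 1]
  cand <- detect_candidates(fr + spot)
  expect_identical(nrow(cand), 1L)
  expect_identical(c(cand$row, cand$col), c(20L, 20L))
})

test_that("detection is translation-equivariant away from borders", {
  cam <- camera_model(offset = 0)
  set.seed(8)
  base <- matrix(rnorm(48 * 48, 10, 1), 48, 48)
  ev <- data.frame(frame = 1, x = 2050, y = 1850, photons = 4000,
                   psf_sigma = 130)
  fr <- base + simulate_frame_stack(ev, cam, dims = c(48, 48),
                                    seed = NULL)[, , 1]
  sh <- 5L
  fr2 <- matrix(0, 48, 48)
  fr2[(1 + sh):48, (1 + sh):48] <- fr[1:(48 - sh), 1:(48 - sh)]
  fr2[1:sh, ] <- 10; fr2[, 1:sh] <- 10
  c1 <- detect_candidates(fr)
  c2 <- detect_candidates(fr2)
  expect_identical(nrow(c2), nrow(c1))
  expect_identical(c2$row, c1$row + sh)
  expect_identical(c2$col, c1$col + sh)
})

test_that("detection recovers a field of well-separated spots at SNR ~ 10", {
  cam <- camera_model(offset = 0)
  set.seed(12)
  grid <- expand.grid(gx = 1:8, gy = 1:7)[1:50, ]
  ev <- data.frame(frame = 1,
                   x = (grid$gx * 9 - 4 + runif(50, -0.3, 0.3)) * 100,
                   y = (grid$gy * 9 - 4 + runif(50, -0.3, 0.3)) * 100,
                   photons = 3000, psf_sigma = 130)
  st <- simulate_frame_stack(ev, cam, dims = c(64, 76),
                             background_photons = 10, seed = 99)
  cand <- detect_candidates(st[, , 1])
  # pixel holding position x is x/100 + 0.5 in column units
  tc <- ev$x / 100 + 0.5; tr <- ev$y / 100 + 0.5
  # every detection within 1 px of a true spot, at least 48 of 50 found
  dmin_true <- vapply(seq_len(nrow(ev)), function(i)
    min(sqrt((cand$col - tc[i])^2 + (cand$row - tr[i])^2)), numeric(1))
  dmin_det <- vapply(seq_len(nrow(cand)), function(i)
    min(sqrt((cand$col[i] - tc)^2 + (cand$row[i] - tr)^2)), numeric(1))
  expect_gte(sum(dmin_true <= 1), 48)
  expect_true(all(dmin_det <= 1))
})

test_that("integrated-Gaussian fits recover noiseless generating parameters", {
  cam <- camera_model(offset = 100)
  ev <- data.frame(frame = 1, x = 20.30 * 100, y = 15.70 * 100,
                   photons = 2000, psf_sigma = 1.2 * 100)
  st <- simulate_frame_stack(ev, cam, dims = c(32, 32), seed = NULL)
  tab <- fit_spots(st[, , 1], data.frame(row = 16L, col = 20L), cam)
  expect_identical(nrow(tab), 1L)
  expect_lt(abs(tab$x / 100 - 20.30), 0.02)
  expect_lt(abs(tab$y / 100 - 15.70), 0.02)
  expect_lt(abs(tab$sigma - 120) / 120, 0.01)
  expect_equal(tab$intensity, 2000, tolerance = 0.01)
})

test_that("a spot centered on a pixel fits with zero sub-pixel offset", {
  cam <- camera_model(offset = 0)
  ev <- data.frame(frame = 1, x = 1550, y = 1550, photons = 3000,
                   psf_sigma = 120)
  st <- simulate_frame_stack(ev, cam, dims = c(32, 32), seed = NULL)
  tab <- fit_spots(st[, , 1], data.frame(row = 16L, col = 16L), cam,
                   offset_adu = 0)
  expect_equal(tab$x, 1550, tolerance = 1e-6)
  expect_equal(tab$y, 1550, tolerance = 1e-6)
})

test_that("empirical localization error is within 1.5x the reported uncertainty", {
  cam <- camera_model(offset = 100)
  set.seed(5)
  errs <- numeric(0); uncs <- numeric(0)
  for (i in 1:220) {
    ev <- data.frame(frame = 1, x = (15 + runif(1)) * 100,
                     y = (15 + runif(1)) * 100,
                     photons = 1200, psf_sigma = 120)
    st <- simulate_frame_stack(ev, cam, dims = c(32, 32),
                               background_photons = 8, seed = 7000 + i)
    tab <- fit_spots(st[, , 1], data.frame(row = 16L, col = 16L), cam)
    if (nrow(tab) != 1) next
    errs <- c(errs, c(tab$x - ev$x, tab$y - ev$y))
    uncs <- c(uncs, tab$uncertainty)
  }
  expect_gte(length(uncs), 200)
  rms <- sqrt(mean(errs^2))            # per-axis empirical RMS, nm
  expect_lt(rms, 1.5 * mean(uncs))
  expect_gt(rms, mean(uncs) / 1.5)
})

test_that("candidates at the border are discarded, failures tallied", {
  cam <- camera_model(offset = 0)
  fr <- matrix(10, 20, 20)
  tab <- fit_spots(fr, data.frame(row = c(2L, 10L), col = c(2L, 10L)), cam,
                   offset_adu = 0)
  # border candidate dropped before fitting; flat window fails the fit
  expect_identical(nrow(tab), 0L)
  expect_identical(attr(tab, "n_failed"), 1L)
})
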