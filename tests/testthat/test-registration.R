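test_that("bead matching handles identical, shifted and spurious beads", {
  set.seed(2)
  b1 <- data.frame(x = runif(40, 0, 20000), y = runif(40, 0, 20000))
  p0 <- register_bead_pairs(b1, b1)
  expect_identical(nrow(p0), 40L)
  expect_true(all(p0$dx == 0 & p0$dy == 0))

  b2 <- data.frame(x = b1$x + 50, y = b1$y)
  p1 <- register_bead_pairs(b1, b2)
  expect_identical(nrow(p1), 40L)
  expect_equal(unique(p1$dx), -50)
  expect_equal(unique(p1$dy), 0)

  # 10% spurious beads in channel 2 stay unmatched; matching equals the
  # exhaustive mutual-NN oracle
  spur <- data.frame(x = runif(4, 0, 20000), y = runif(4, 0, 20000))
  b2s <- rbind(b2, spur)
  p2 <- register_bead_pairs(b1, b2s)
  oracle <- oracle_mutual_nn(b1, b2s, cutoff = 300)
  expect_identical(nrow(p2), nrow(oracle))
  expect_equal(cbind(p2$x1, p2$y1),
               unname(as.matrix(b1[oracle[, 1], ])))

  expect_error(register_bead_pairs(b1, data.frame(x = 1e6, y = 1e6)),
               "no mutual")
})

test_that("polynomial calibration represents exact fields exactly", {
  set.seed(5)
  b1 <- data.frame(x = runif(30, 0, 25000), y = runif(30, 0, 25000))
  b2 <- data.frame(x = b1$x + 40, y = b1$y - 15)
  cal <- fit_calibration(register_bead_pairs(b1, b2, cutoff = 300))
  expect_lt(cal$rms_residual, 1e-9)
  pred <- predict(cal, c(0, 12000), c(0, 25000))
  expect_equal(unname(pred[, 1]), c(-40, -40), tolerance = 1e-9)
  expect_equal(unname(pred[, 2]), c(15, 15), tolerance = 1e-9)
})

test_that("a known quadratic field is recovered everywhere the beads span", {
  quad <- distortion_model(max_magnitude = 100)
  beads <- simulate_bead_pairs(quad, n_beads = 50, precision = 0, seed = 3)
  pairs <- register_bead_pairs(beads$ch1, beads$ch2)
  cal <- fit_calibration(pairs, degree = 2)
  set.seed(4)
  qx <- runif(200, min(beads$ch1$x), max(beads$ch1$x))
  qy <- runif(200, min(beads$ch1$y), max(beads$ch1$y))
  truth <- eval_distortion(quad, qx, qy)
  pred <- predict(cal, qx + truth[, 1], qy + truth[, 2])
  resid <- sqrt((pred[, 1] + truth[, 1])^2 + (pred[, 2] + truth[, 2])^2)
  # the field is polynomial in the undistorted coordinates while the
  # calibration is parameterized on the distorted ones, so recovery is
  # exact only to second order: |D| * |grad D| ~ 0.1 nm across this field
  expect_lt(max(resid), 0.1)
})

test_that("an interpolating fit with as many beads as coefficients has zero residual", {
  set.seed(6)
  b1 <- data.frame(x = runif(6, 0, 10000), y = runif(6, 0, 10000))
  b2 <- data.frame(x = b1$x + rnorm(6, 20, 10), y = b1$y + rnorm(6, 0, 10))
  pairs <- data.frame(x2 = b2$x, y2 = b2$y, dx = b1$x - b2$x,
                      dy = b1$y - b2$y)
  cal <- fit_calibration(pairs, degree = 2)
  expect_lt(cal$rms_residual, 1e-6)
})

test_that("collinear beads produce a rank-deficiency error at degree 2", {
  b <- data.frame(x2 = seq(0, 10000, length.out = 20), y2 = rep(100, 20),
                  dx = rnorm(20), dy = rnorm(20))
  expect_error(fit_calibration(b, degree = 2), "lower degree")
})

test_that("applying a calibration displaces positions and nothing else", {
  tab <- loc_table(c(1020, 5020), c(300, 700), intensity = c(1, 2))
  ident <- fit_calibration(data.frame(x2 = c(0, 5000, 0, 5000, 2500),
                                      y2 = c(0, 0, 5000, 5000, 2500),
                                      dx = 0, dy = 0), degree = 1)
  expect_equal(as.data.frame(apply_calibration(tab, ident)),
               as.data.frame(tab))

  shift <- fit_calibration(data.frame(x2 = c(0, 5000, 0, 5000, 2500),
                                      y2 = c(0, 0, 5000, 5000, 2500),
                                      dx = -20, dy = 0), degree = 1)
  shifted <- loc_table(c(1020, 5020) + 20, c(300, 700), intensity = c(1, 2))
  back <- apply_calibration(shifted, shift)
  expect_equal(back$x, c(1020, 5020))
  expect_equal(back$intensity, c(1, 2))
  expect_warning(apply_calibration(loc_table(9e5, 9e5), shift),
                 "extrapolation")
})

test_that("round-trip on distorted synapse data leaves RMS misalignment below 15 nm", {
  quad <- distortion_model(max_magnitude = 100)
  beads <- simulate_bead_pairs(quad, n_beads = 100, precision = 5, seed = 11)
  cal <- fit_calibration(register_bead_pairs(beads$ch1, beads$ch2))
  # fitting never worsens alignment on the fit set
  expect_lte(cal$rms_residual,
             sqrt(mean((beads$ch1$x - beads$ch2$x)^2 +
                         (beads$ch1$y - beads$ch2$y)^2)))

  model <- synapse_model(scaffold_center = c(12000, 12000))
  distorted <- simulate_synapse(model, noise_model(), seed = 12,
                                distortion = quad)
  clean <- simulate_synapse(model, noise_model(), seed = 12)
  aligned <- apply_calibration(distorted$ch2, cal)
  resid <- sqrt((aligned$x - clean$ch2$x)^2 + (aligned$y - clean$ch2$y)^2)
  expect_lt(sqrt(mean(resid^2)), 15)
})

test_that("locally weighted averaging agrees with the polynomial path on polynomial fields", {
  quad <- distortion_model(max_magnitude = 100)
  beads <- simulate_bead_pairs(quad, n_beads = 120, precision = 2, seed = 13)
  pairs <- register_bead_pairs(beads$ch1, beads$ch2)
  pol <- fit_calibration(pairs, method = "polynomial")
  lwa <- fit_calibration(pairs, method = "lwa")
  set.seed(14)
  qx <- runif(100, 2000, 23000); qy <- runif(100, 2000, 23000)
  dp <- predict(pol, qx, qy); dl <- predict(lwa, qx, qy)
  # agreement within the scale of the bead precision
  expect_lt(sqrt(mean((dp - dl)^2)), 3 * 2)
})

test_that("calibration models round-trip through JSON", {
  quad <- distortion_model(max_magnitude = 80)
  beads <- simulate_bead_pairs(quad, n_beads = 40, precision = 3, seed = 15)
  cal <- fit_calibration(register_bead_pairs(beads$ch1, beads$ch2))
  f <- tempfile(fileext = ".json")
  write_calibration(cal, f)
  cal2 <- read_calibration(f)
  expect_equal(predict(cal2, c(1000, 20000), c(500, 12000)),
               predict(cal, c(1000, 20000), c(500, 12000)), tolerance = 1e-9)
})
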