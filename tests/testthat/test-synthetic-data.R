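test_that("degenerate zero-noise synapse puts every localization at the nanodomain center", {
  m <- synapse_model(n_nanodomains = 1,
                     nanodomain_centers = matrix(c(1000, 1000), 1),
                     nanodomain_sigma = 1e-9, locs_per_nanodomain = 50,
                     background_locs = 0)
  nm <- noise_model(precision_mean = 1e-9, precision_spread = 0)
  sim <- simulate_synapse(m, nm, seed = 1)
  expect_gt(nrow(sim$ch1), 0)
  expect_true(all(abs(sim$ch1$x - 1000) < 1e-6))
  expect_true(all(abs(sim$ch1$y - 1000) < 1e-6))
})

test_that("identical seed and parameters give bitwise-identical tables", {
  m <- synapse_model()
  nm <- noise_model()
  s1 <- simulate_synapse(m, nm, seed = 42)
  s2 <- simulate_synapse(m, nm, seed = 42)
  expect_identical(s1$ch1, s2$ch1)
  expect_identical(s1$ch2, s2$ch2)
  s3 <- simulate_synapse(m, nm, seed = 43)
  expect_false(identical(s1$ch1, s3$ch1))
})

test_that("nanodomain localization counts are Poisson around the expectation", {
  # oracle: Poisson law; mean over replicates within 3 standard errors
  m <- synapse_model(n_nanodomains = 1, locs_per_nanodomain = 200,
                     background_locs = 0)
  counts <- vapply(1:100, function(i) {
    sim <- simulate_synapse(m, noise_model(), seed = 9000 + i)
    sum(sim$truth$locs$nanodomain[sim$truth$locs$channel == "ch1"] == 1)
  }, numeric(1))
  se <- sd(counts) / sqrt(length(counts))
  expect_lt(abs(mean(counts) - 200), 3 * se)
})

test_that("localization counts equal recorded blink events and emitters stay in the scaffold", {
  for (seed in 1:5) {
    sim <- simulate_synapse(synapse_model(n_nanodomains = 3,
                                          scaffold_radius = 200),
                            noise_model(), seed = seed)
    for (ch in c("ch1", "ch2")) {
      tab <- sim[[ch]]
      em <- sim$truth$emitters[sim$truth$emitters$channel == ch, ]
      expect_identical(nrow(tab), sum(em$blinks))
      expect_identical(nrow(tab),
                       sum(sim$truth$locs$channel == ch))
      nd <- em[em$nanodomain > 0, ]
      d <- sqrt((nd$x - 1000)^2 + (nd$y - 1000)^2)
      expect_true(all(d <= 200 + 1e-9))
    }
  }
})

test_that("bead pairs reproduce the distortion field", {
  ident <- distortion_model(coef_x = 0, coef_y = 0, max_magnitude = NULL)
  b0 <- simulate_bead_pairs(ident, n_beads = 20, precision = 0, seed = 1)
  expect_equal(b0$ch1, b0$ch2, tolerance = 1e-12)

  shift <- distortion_model(coef_x = 20, coef_y = 0, max_magnitude = NULL)
  b1 <- simulate_bead_pairs(shift, n_beads = 20, precision = 0, seed = 1)
  expect_equal(b1$ch2$x - b1$ch1$x, rep(20, 20), tolerance = 1e-12)
  expect_equal(b1$ch2$y - b1$ch1$y, rep(0, 20), tolerance = 1e-12)

  quad <- distortion_model(max_magnitude = 100)
  b2 <- simulate_bead_pairs(quad, n_beads = 50, precision = 0, seed = 2)
  disp <- sqrt((b2$ch2$x - b2$ch1$x)^2 + (b2$ch2$y - b2$ch1$y)^2)
  expect_lte(max(disp), 100 + 1e-9)
  # oracle: direct evaluation of the stated polynomial at the true positions
  d <- eval_distortion(quad, b2$truth$x, b2$truth$y)
  expect_equal(b2$ch2$x - b2$ch1$x, d[, 1], tolerance = 1e-9)
})

test_that("too few beads for the later fit triggers a warning", {
  expect_warning(simulate_bead_pairs(distortion_model(), n_beads = 3,
                                     precision = 0, seed = 1),
                 "under-determined")
})

test_that("frame stacks follow the camera model", {
  cam <- camera_model(offset = 0)
  empty <- simulate_frame_stack(data.frame(frame = integer(0), x = numeric(0),
                                           y = numeric(0),
                                           photons = numeric(0)),
                                cam, dims = c(8, 8), n_frames = 3, seed = 1)
  expect_true(all(empty == 0))

  # immobile emitter at a pixel center: brightest pixel there in every frame
  ev <- data.frame(frame = 1:5, x = 1550, y = 1050, photons = 5000,
                   psf_sigma = 120)
  st <- simulate_frame_stack(ev, camera_model(), dims = c(32, 32), seed = NULL)
  for (f in 1:5) {
    pk <- which(st[, , f] == max(st[, , f]), arr.ind = TRUE)
    expect_equal(unname(pk[1, ]), c(11, 16))
  }

  # Poisson sum law: mean summed background-subtracted intensity ~ N * gain
  cam2 <- camera_model(offset = 50)
  ev <- data.frame(frame = 1:60, x = 1600, y = 1600, photons = 1000,
                   psf_sigma = 120)
  st <- simulate_frame_stack(ev, cam2, dims = c(32, 32), seed = 7)
  sums <- vapply(1:60, function(f) sum(st[, , f] - cam2$offset), numeric(1))
  expect_lt(abs(mean(sums) / cam2$adu_per_photon - 1000),
            3 * sqrt(1000 / 60))
})

test_that("events outside the field are excluded with a message", {
  ev <- data.frame(frame = 1L, x = -500, y = 100, photons = 100,
                   psf_sigma = 120)
  expect_message(st <- simulate_frame_stack(ev, camera_model(offset = 0),
                                            dims = c(8, 8), seed = NULL),
                 "outside the field")
  expect_true(all(st == 0))
})

test_that("label volumes match analytic sphere geometry", {
  # 2% voxel-count accuracy needs fine voxels relative to the radius
  vs <- simulate_label_volume(n_compartments = 1, ssd_counts = 1,
                              ssd_radius = 25, compartment_radius = 30,
                              voxel_size = c(1, 1, 1),
                              channel_offset = c(5, 0, 0), seed = 1)
  st <- compartment_stats(vs$vol_a)
  expect_equal(st$ssds$volume, vs$truth$volume[1], tolerance = 0.02)

  expect_identical(simulate_label_volume(seed = 4)$vol_a$ssd,
                   simulate_label_volume(seed = 4)$vol_a$ssd)

  empty <- simulate_label_volume(n_compartments = 0, seed = 1)
  expect_true(all(empty$vol_a$ssd == 0L))
  expect_equal(nrow(empty$truth), 0L)
})

test_that("SSD radius larger than its compartment is rejected", {
  expect_error(simulate_label_volume(ssd_radius = 300,
                                     compartment_radius = 250, seed = 1),
               "exceeds")
})
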