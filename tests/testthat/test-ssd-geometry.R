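make_cube_volume <- function() {
  dims <- c(20L, 20L, 20L)
  ssd <- array(0L, dims); comp <- array(0L, dims)
  comp[3:16, 3:16, 3:16] <- 1L
  ssd[5:14, 5:14, 5:14] <- 1L   # 10x10x10 voxels
  label_volume(ssd, comp, voxel_size = c(40, 40, 120))
}

test_that("compartment stats follow voxel arithmetic", {
  vol <- make_cube_volume()
  st <- compartment_stats(vol)
  expect_equal(st$ssds$volume, 1000 * 40 * 40 * 120)   # 1.92e8 nm^3
  expect_equal(st$ssds$n_voxels, 1000L)
  expect_identical(st$compartments$n_ssds, 1L)
  # unweighted centroid of voxels 5..14 at voxel centers
  expect_equal(st$ssds$x, (mean(5:14) - 0.5) * 40)
  expect_equal(st$ssds$z, (mean(5:14) - 0.5) * 120)
  # SSD volume cannot exceed its compartment volume
  expect_lte(st$ssds$volume, st$compartments$volume)
})

test_that("spherical SSD volumes match the analytic value within 2%", {
  vs <- simulate_label_volume(n_compartments = 2, ssd_counts = 1,
                              ssd_radius = 25, compartment_radius = 30,
                              voxel_size = c(1, 1, 1),
                              channel_offset = c(5, 0, 0), seed = 2)
  st <- compartment_stats(vs$vol_a)
  expect_equal(st$ssds$volume, vs$truth$volume, tolerance = 0.02)
})

test_that("empty volumes give empty stats", {
  empty <- simulate_label_volume(n_compartments = 0, seed = 1)
  st <- compartment_stats(empty$vol_a)
  expect_identical(nrow(st$ssds), 0L)
  expect_identical(nrow(st$compartments), 0L)
})

test_that("SSD voxels outside every compartment are rejected", {
  dims <- c(8L, 8L, 8L)
  ssd <- array(0L, dims); comp <- array(0L, dims)
  ssd[1:2, 1:2, 1:2] <- 1L
  expect_error(label_volume(ssd, comp, c(40, 40, 120)), "label 1")
})

test_that("voxel overlap fractions cover identity, disjoint and half-offset cases", {
  vol <- make_cube_volume()
  same <- ssd_overlap(vol, vol)
  expect_true(all(same$fractions$overlap_fraction == 1))
  expect_equal(same$percent_overlapping, 100)

  # relabeling invariance
  relab <- vol
  relab$ssd[relab$ssd == 1L] <- 7L
  relab$parent <- c("7" = 1L)
  expect_equal(ssd_overlap(vol, relab)$fractions$overlap_fraction, 1)

  disjoint <- vol
  disjoint$ssd <- array(0L, dim(vol$ssd))
  disjoint$ssd[2:3, 2:3, 2:3] <- 1L
  disjoint$comp <- array(1L, dim(vol$ssd))
  expect_equal(ssd_overlap(vol, disjoint)$fractions$overlap_fraction, 0)
  expect_equal(ssd_overlap(vol, disjoint)$percent_overlapping, 0)

  # half-offset cube: shift by 5 of 10 voxels along x
  half <- vol
  half$ssd <- array(0L, dim(vol$ssd))
  half$ssd[10:19, 5:14, 5:14] <- 1L
  half$comp <- array(1L, dim(vol$ssd))
  expect_equal(ssd_overlap(vol, half)$fractions$overlap_fraction, 0.5)

  mism <- simulate_label_volume(n_compartments = 1, seed = 1)
  expect_error(ssd_overlap(vol, mism$vol_a), "mismatch")
})

test_that("nearest-neighbour centroid distances match brute force", {
  vs <- simulate_label_volume(n_compartments = 4, ssd_counts = 2,
                              seed = 5)
  sa <- compartment_stats(vs$vol_a)
  sb <- compartment_stats(vs$vol_b)
  nn <- nn_distances(sa, sb)
  expect_identical(nrow(nn), nrow(sa$ssds))
  for (i in seq_len(nrow(sa$ssds))) {
    d <- sqrt((sb$ssds$x - sa$ssds$x[i])^2 +
                (sb$ssds$y - sa$ssds$y[i])^2 +
                (sb$ssds$z - sa$ssds$z[i])^2)
    expect_equal(nn$distance[i], min(d))
  }
  # empty partner: flagged as NA
  empty <- compartment_stats(simulate_label_volume(0, seed = 1)$vol_a)
  nn2 <- nn_distances(sa, empty)
  expect_true(all(is.na(nn2$distance)))
})

test_that("a single constructed pair reports its exact distance, ties once", {
  mk_stats <- function(xyz) {
    list(ssds = data.frame(label = seq_len(nrow(xyz)), x = xyz[, 1],
                           y = xyz[, 2], z = xyz[, 3]))
  }
  a <- mk_stats(cbind(0, 0, 0))
  b <- mk_stats(cbind(100, 0, 0))
  expect_equal(nn_distances(a, b)$distance, 100)
  # equidistant partners: reported once, as the minimum
  b2 <- mk_stats(rbind(c(100, 0, 0), c(-100, 0, 0)))
  nn <- nn_distances(a, b2)
  expect_identical(nrow(nn), 1L)
  expect_equal(nn$distance, 100)
})

test_that("count/volume grouping handles constant, monotone and single-row batches", {
  const <- data.frame(n_ssds_own = 2L, n_ssds_partner = 2L,
                      volume_partner = c(1e7, 2e7, 3e7, 4e7))
  cv <- count_volume_correlations(const)
  expect_true(all(cv$by_count$mean_partner == 2))
  expect_true(all(cv$by_volume$mean_own == 2))

  set.seed(71)
  vols <- runif(60, 1e7, 9e7)
  batch <- data.frame(n_ssds_own = 1L + rpois(60, vols / 2e7),
                      n_ssds_partner = 2L,
                      volume_partner = vols)
  cv2 <- count_volume_correlations(batch,
                                   volume_breaks = c(1e7, 3e7, 5e7, 7e7, 9e7))
  expect_true(all(diff(cv2$by_volume$mean_own) >= 0))

  single <- batch[1, ]
  cv3 <- count_volume_correlations(single)
  expect_identical(nrow(cv3$by_count), 1L)
  expect_equal(cv3$by_count$mean_partner, 2)
})

test_that("label volumes round-trip through TIFF + sidecar", {
  vs <- simulate_label_volume(n_compartments = 2, ssd_counts = 2, seed = 9)
  base <- tempfile()
  write_label_volume(vs$vol_a, base)
  back <- read_label_volume(base)
  expect_identical(back$ssd, vs$vol_a$ssd)
  expect_identical(back$comp, vs$vol_a$comp)
  expect_equal(back$voxel_size, vs$vol_a$voxel_size)
})
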