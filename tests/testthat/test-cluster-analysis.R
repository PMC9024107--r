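# deterministic 2-nanodomain fixture reused across blocks
two_domain_region <- function(seed = 55) {
  m <- synapse_model(n_nanodomains = 2,
                     nanodomain_centers = rbind(c(900, 1000), c(1100, 1000)),
                     nanodomain_sigma = 25, locs_per_nanodomain = 150,
                     background_locs = 100, scaffold_radius = 160)
  sim <- simulate_synapse(m, noise_model(), seed = seed)
  tab <- sim$ch1
  pts <- cbind(tab$x, tab$y)
  dens <- local_density(pts)
  regions <- segment_scaffold(pts, dens)
  list(sim = sim, tab = tab, pts = pts, dens = dens, regions = regions)
}

test_that("local density counts neighbours within the radius, self excluded", {
  expect_identical(local_density(cbind(0, 0)), 0L)

  # 20 nm square lattice at radius 25: interior points see exactly their
  # four axial neighbours (diagonals at 28.3 nm are outside)
  g <- expand.grid(x = seq(0, 200, by = 20), y = seq(0, 200, by = 20))
  d <- local_density(as.matrix(g), density_params(neighbor_radius = 25))
  interior <- g$x > 0 & g$x < 200 & g$y > 0 & g$y < 200
  expect_true(all(d[interior] == 4L))
})

test_that("mean local density of a uniform disc matches the Poisson expectation", {
  set.seed(61)
  n <- 1000; R <- 1000; r <- 25
  th <- runif(n, 0, 2 * pi); rr <- R * sqrt(runif(n))
  pts <- cbind(rr * cos(th), rr * sin(th))
  d <- local_density(pts, density_params(neighbor_radius = r))
  lambda <- n / (pi * R^2)
  se <- sd(d) / sqrt(n)
  expect_lt(abs(mean(d) - lambda * pi * r^2), 3 * se)
})

test_that("scaffold segmentation retains the dense disc and rejects background", {
  # dense disc over sparse uniform background at 10x density contrast
  set.seed(62)
  n_disc <- 600; R <- 150
  th <- runif(n_disc, 0, 2 * pi); rr <- R * sqrt(runif(n_disc))
  disc <- cbind(1000 + rr * cos(th), 1000 + rr * sin(th))
  disc_density <- n_disc / (pi * R^2)
  box <- 1200
  n_bg <- round(disc_density / 10 * box^2)
  bg <- cbind(runif(n_bg, 400, 400 + box), runif(n_bg, 400, 400 + box))
  pts <- rbind(disc, bg)
  dens <- local_density(pts)
  regions <- segment_scaffold(pts, dens)
  expect_gte(length(regions), 1L)
  main <- regions[[which.max(vapply(regions, `[[`, numeric(1), "area"))]]
  in_main <- seq_len(nrow(pts)) %in% main$member_idx
  expect_gte(mean(in_main[seq_len(n_disc)]), 0.95)
  expect_lte(mean(in_main[-seq_len(n_disc)]), 0.10)
})

test_that("uniform-density point sets are fully retained (zero range)", {
  g <- as.matrix(expand.grid(x = seq(0, 400, by = 20),
                             y = seq(0, 400, by = 20)))
  # constant densities: threshold equals the minimum, everything kept
  dens <- rep(5L, nrow(g))
  regions <- segment_scaffold(g, dens)
  expect_identical(sort(unique(unlist(lapply(regions, `[[`, "member_idx")))),
                   seq_len(nrow(g)))
})

test_that("two scaffolds far apart segment into two regions", {
  set.seed(63)
  mk <- function(cx) {
    th <- runif(400, 0, 2 * pi); rr <- 150 * sqrt(runif(400))
    cbind(cx + rr * cos(th), 1000 + rr * sin(th))
  }
  pts <- rbind(mk(1000), mk(3000))
  regions <- segment_scaffold(pts, local_density(pts))
  expect_identical(length(regions), 2L)
})

test_that("regions below the minimum area are dropped", {
  set.seed(64)
  tight <- cbind(rnorm(30, 0, 8), rnorm(30, 0, 8))     # ~ a few hundred nm^2
  regions <- segment_scaffold(tight, local_density(tight),
                              scaffold_params(min_area = 1500))
  expect_identical(length(regions), 0L)
  expect_match(paste(attr(regions, "dropped"), collapse = " "), "min_area")
})

test_that("HDR detection recovers two seeded nanodomains with their members", {
  # region with two sigma-25 nanodomains (150 localizations each) over 100
  # uniform background localizations; membership checked against truth
  set.seed(55)
  d1 <- cbind(rnorm(150, 900, 25), rnorm(150, 1000, 25))
  d2 <- cbind(rnorm(150, 1100, 25), rnorm(150, 1000, 25))
  th <- runif(100, 0, 2 * pi); rr <- 160 * sqrt(runif(100))
  bg <- cbind(1000 + 1.4 * rr * cos(th), 1000 + rr * sin(th))
  pts <- rbind(d1, d2, bg)
  nd_of <- rep(c(1L, 2L, 0L), c(150, 150, 100))

  sh <- alpha_shape(pts, 100)
  k <- which.max(sh$component_areas)
  tr <- sh$triangles[sh$component == k, , drop = FALSE]
  vert <- sort(unique(as.vector(tr)))
  region <- list(channel = "a", points = pts[vert, , drop = FALSE],
                 member_idx = vert,
                 triangles = matrix(match(tr, vert), ncol = 3))
  hdrs <- detect_hdrs(region, hdr_params(seed = 5))
  expect_identical(length(hdrs), 2L)
  for (h in hdrs) {
    glob <- region$member_idx[h$region_idx]
    cx <- mean(pts[glob, 1])
    nd <- if (abs(cx - 900) < abs(cx - 1100)) 1L else 2L
    expect_gte(sum(nd_of[glob] == nd) / 150, 0.70)   # capture
    expect_gte(mean(nd_of[glob] == nd), 0.90)        # purity
    expect_lte(h$area, sh$component_areas[k])
  }
})

test_that("the full segmentation chain finds both nanodomains of a simulated synapse", {
  fx <- two_domain_region()
  expect_identical(length(fx$regions), 1L)
  hdrs <- detect_hdrs(fx$regions[[1]], hdr_params(seed = 5))
  expect_identical(length(hdrs), 2L)
  cx <- sort(vapply(hdrs, function(h) mean(h$points[, 1]), numeric(1)))
  expect_lt(abs(cx[1] - 900), 30)
  expect_lt(abs(cx[2] - 1100), 30)
})

test_that("empty and undersized regions yield no HDRs", {
  expect_identical(length(detect_hdrs(list(points = NULL))), 0L)
  tiny <- list(points = cbind(1:3, 1:3), triangles = matrix(1:3, 1),
               channel = "a")
  expect_identical(length(detect_hdrs(tiny, hdr_params(min_points = 10))), 0L)
})

test_that("raising the SD multiplier never increases HDR points", {
  fx <- two_domain_region()
  region <- fx$regions[[1]]
  n_hot <- vapply(c(1, 2, 3, 4), function(k) {
    hdrs <- detect_hdrs(region, hdr_params(sd_multiplier = k, seed = 9))
    sum(vapply(hdrs, function(h) nrow(h$points), integer(1)))
  }, numeric(1))
  expect_true(all(diff(n_hot) <= 0))
})

test_that("HDR detection is invariant under translation and rotation", {
  fx <- two_domain_region()
  region <- fx$regions[[1]]
  base <- detect_hdrs(region, hdr_params(seed = 3))

  transform <- function(pts, theta, shift) {
    ctr <- colMeans(pts)
    rot <- matrix(c(cos(theta), sin(theta), -sin(theta), cos(theta)), 2)
    sweep(sweep(pts, 2, ctr) %*% rot, 2, -(ctr + shift))
  }
  for (theta in c(0, 0.7)) {
    shift <- c(5000, -3000)
    region2 <- region
    region2$points <- transform(region$points, theta, shift)
    moved <- detect_hdrs(region2, hdr_params(seed = 3))
    expect_identical(length(moved), length(base))
    base_sets <- lapply(base, function(h) sort(h$region_idx))
    moved_sets <- lapply(moved, function(h) sort(h$region_idx))
    expect_setequal(vapply(base_sets, paste, character(1), collapse = ","),
                    vapply(moved_sets, paste, character(1), collapse = ","))
  }
})

test_that("overlap classification follows the 0.23 area-fraction rule", {
  # channel-B scaffold: dense uniform square [0,400]^2
  set.seed(65)
  sq <- cbind(runif(800, 0, 400), runif(800, 0, 400))
  regions_b <- segment_scaffold(sq, local_density(sq), channel = "b")
  expect_identical(length(regions_b), 1L)

  mk_hdr <- function(cx, cy) {
    pts <- cbind(runif(120, cx - 40, cx + 40), runif(120, cy - 40, cy + 40))
    shape <- alpha_shape(pts, 20)
    structure(list(channel = "a", member_idx = seq_len(nrow(pts)),
                   region_idx = seq_len(nrow(pts)), points = pts,
                   shape = shape, area = shape$area,
                   boundary = unlist(shape$boundaries, recursive = FALSE),
                   peak_density = 10,
                   overlap_fraction_scaffold = NA_real_,
                   overlap_fraction_hdr = NA_real_, synaptic = NA),
              class = "hdr")
  }
  inside <- mk_hdr(200, 200)     # fully inside the scaffold
  outside <- mk_hdr(2000, 2000)  # disjoint
  res <- classify_overlap(list(inside, outside), regions_b)
  expect_equal(res$table$overlap_fraction_scaffold[1], 1, tolerance = 0.02)
  expect_true(res$table$synaptic[1])
  expect_equal(res$table$overlap_fraction_scaffold[2], 0)
  expect_false(res$table$synaptic[2])
  expect_true(all(res$table$overlap_fraction_scaffold >= 0 &
                    res$table$overlap_fraction_scaffold <= 1))

  # fraction just above / below the 0.23 threshold via a straddling HDR
  straddle <- mk_hdr(390, 200)   # roughly half inside
  res2 <- classify_overlap(list(straddle), regions_b,
                           op = overlap_params(synaptic_threshold = 0.23))
  f <- res2$table$overlap_fraction_scaffold
  expect_identical(res2$table$synaptic, f >= 0.23)
  # threshold 0 marks every intersecting HDR synaptic; threshold 1 only
  # fully contained ones
  expect_true(classify_overlap(list(straddle), regions_b,
                               op = overlap_params(0))$table$synaptic)
  expect_false(classify_overlap(list(straddle), regions_b,
                                op = overlap_params(1))$table$synaptic)
})

test_that("batch summaries report counts and recover a seeded area-count relation", {
  sims <- simulate_synapse_batch(16, counts = 1:4, seed = 21)
  analyses <- lapply(seq_along(sims), function(i)
    analyze_synapse(sims[[i]]$ch1, sims[[i]]$ch2,
                    hp = hdr_params(seed = 100 + i)))
  sm <- summarize_synapses(analyses)
  expect_identical(nrow(sm$rois), 16L)
  expect_true(all(c("n_hdrs_a", "n_hdrs_b", "scaffold_area_a") %in%
                    names(sm$rois)))
  cc <- sm$correlations$area_b_vs_nhdr_b
  expect_gt(cc$r, 0.5)

  empty <- summarize_synapses(list())
  expect_identical(nrow(empty$rois), 0L)
})
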