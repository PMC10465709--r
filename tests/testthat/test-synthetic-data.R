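test_that("unperturbed domain mask is a disk with the expected area", {
  g <- grid_spec(64, 64, dx = 10)
  m <- gen_domain_mask(g, mean_radius = 200, boundary_roughness = 0, seed = 1)
  # center-of-pixel rasterization of a disk: area within one perimeter of pi R^2
  area <- sum(m$mask) * g$dx^2
  expect_lt(abs(area - pi * 200^2), 2 * pi * 200 * g$dx)
  # radially symmetric: no pixel farther than R + half a diagonal
  idx <- which(m$mask, arr.ind = TRUE)
  rr <- sqrt(((idx[, 1] - 0.5 - 32) * 10)^2 + ((idx[, 2] - 0.5 - 32) * 10)^2)
  expect_lte(max(rr), 200)
})

test_that("domain masks are reproducible and seed-sensitive", {
  g <- grid_spec(64, 64, dx = 10)
  m1 <- gen_domain_mask(g, 200, 0.3, n_modes = 8, seed = 7)
  m2 <- gen_domain_mask(g, 200, 0.3, n_modes = 8, seed = 7)
  m3 <- gen_domain_mask(g, 200, 0.3, n_modes = 8, seed = 8)
  expect_identical(m1$mask, m2$mask)
  expect_identical(m1$psi, m2$psi)
  expect_false(identical(m1$mask, m3$mask))
})

test_that("perturbed mask area stays within the analytic annulus bounds", {
  g <- grid_spec(96, 96, dx = 10)
  r0 <- 250
  m <- gen_domain_mask(g, r0, boundary_roughness = 0.3, n_modes = 8, seed = 1)
  area <- sum(m$mask) * g$dx^2
  expect_gte(area, pi * (r0 * 0.7)^2 * 0.98)  # 2% slack for pixelization
  expect_lte(area, pi * (r0 * 1.3)^2 * 1.02)
})

test_that("masks are single 4-connected components away from the border", {
  g <- grid_spec(48, 48, dx = 10)
  for (seed in 1:4) {
    m <- gen_domain_mask(g, 150, 0.25, seed = seed)
    expect_equal(count_components_4(m$mask), 1L)
    expect_false(any(m$mask[1, ] | m$mask[48, ] | m$mask[, 1] | m$mask[, 48]))
  }
})

test_that("domains that cannot fit raise an error", {
  g <- grid_spec(32, 32, dx = 10)
  expect_error(gen_domain_mask(g, 160, 0.2, seed = 1), "does not fit")
  expect_error(domain_mask(matrix(TRUE, 32, 32), g), "border")
})

test_that("mask PNG round-trips with its scale sidecar", {
  g <- grid_spec(48, 48, dx = 12.5)
  m <- gen_domain_mask(g, 150, 0.2, seed = 3)
  path <- withr::local_tempfile(fileext = ".png")
  write_mask(m, path)
  m2 <- read_mask(path)
  expect_identical(m2$mask, m$mask)
  expect_equal(m2$grid$dx, 12.5)
})

test_that("perfect hexagonal lattice has six-coordinated interior", {
  lat <- gen_hex_lattice(spacing = 60, extent = 7 * 60, jitter_sd = 0, seed = 1)
  expect_true(all(lat$truth$neighbor_count[lat$truth$interior] == 6L))
  # interior nearest-neighbor distances all equal the spacing
  pts <- as.matrix(lat$points)
  d <- as.matrix(dist(pts))
  diag(d) <- Inf
  nn <- unname(apply(d[lat$truth$interior, ], 1, min))
  expect_equal(nn, rep(60, sum(lat$truth$interior)), tolerance = 1e-5)
})

test_that("small jitter keeps the neighbor-count mode at six", {
  lat <- gen_hex_lattice(60, 7 * 60, jitter_sd = 0.05 * 60, seed = 5)
  counts <- lat$truth$neighbor_count[lat$truth$interior]
  tab <- table(counts)
  expect_equal(as.integer(names(which.max(tab))), 6L)
})

test_that("lattice generation is deterministic in the seed", {
  a <- gen_hex_lattice(60, 300, jitter_sd = 4, seed = 9)
  b <- gen_hex_lattice(60, 300, jitter_sd = 4, seed = 9)
  expect_identical(a$points, b$points)
  expect_identical(a$truth, b$truth)
})

test_that("plant_defects with nothing to plant is the identity", {
  lat <- gen_hex_lattice(60, 300, seed = 1)
  out <- plant_defects(lat, 0, 0, 0, seed = 1)
  expect_equal(out$points, lat$points)
  expect_equal(out$truth, lat$truth)
})

test_that("an interstitial at a cell center creates defects on re-analysis", {
  lat <- gen_hex_lattice(60, 7 * 60, seed = 1)
  out <- plant_defects(lat, interstitials = 1, seed = 2)
  expect_equal(nrow(out$points), nrow(lat$points) + 1L)
  d <- mean(out$truth$neighbor_count[out$truth$interior] != 6L)
  expect_gt(d, 0)
})

test_that("vacancies reduce the point count and perturb coordination", {
  lat <- gen_hex_lattice(60, 8 * 60, seed = 1)
  out <- plant_defects(lat, vacancies = 2, seed = 3)
  expect_equal(nrow(out$points), nrow(lat$points) - 2L)
  expect_gt(mean(out$truth$neighbor_count[out$truth$interior] != 6L), 0)
  expect_error(plant_defects(lat, vacancies = 10000), "fewer")
})

test_that("a void leaves no pruned edge crossing its center", {
  lat <- gen_hex_lattice(60, 10 * 60, seed = 1)
  out <- plant_defects(lat, void_radius = 120, seed = 4)
  ctr <- out$defects[out$defects$type == "void", ]
  ref <- reference_triangulation(out$points)
  # distance from the void center to every surviving edge segment
  p <- as.matrix(out$points)
  seg_dist <- vapply(seq_len(nrow(ref$edges)), function(k) {
    a <- p[ref$edges$i[k], ]; b <- p[ref$edges$j[k], ]
    ab <- b - a
    t <- max(0, min(1, sum((c(ctr$x_nm, ctr$y_nm) - a) * ab) / sum(ab^2)))
    sqrt(sum((a + t * ab - c(ctr$x_nm, ctr$y_nm))^2))
  }, 0)
  expect_gt(min(seg_dist), 60)
  # and pruning really enforced the length cutoff
  expect_lte(max(ref$edges$length_nm), 2 * median(ref$edges$length_nm))
})

test_that("noiseless flat abundance tables normalize to all-zero fold changes", {
  tab <- gen_abundance_table(10, trend = "flat", noise_cv = 0, missing_rate = 0,
                             seed = 1)
  fc <- log2_fold_change(filter_complete(tab))
  expect_true(all(as.matrix(fc[c("E12.5", "E13.0", "E13.5", "E14.0", "E14.5")]) == 0))
})

test_that("fully missing tables survive the pipeline as empty results", {
  tab <- gen_abundance_table(10, missing_rate = 1, seed = 1)
  expect_equal(nrow(filter_complete(tab)), 0L)
})

test_that("noiseless peak-trend proteins peak at E13.5", {
  tab <- gen_abundance_table(50, trend = "peak", noise_cv = 0, missing_rate = 0,
                             seed = 2)
  pk <- peak_timepoint(log2_fold_change(tab))
  expect_true(all(pk$peak == "E13.5"))
})

test_that("abundance generation is reproducible and positive", {
  a <- gen_abundance_table(30, noise_cv = 0.3, missing_rate = 0.2, seed = 4)
  b <- gen_abundance_table(30, noise_cv = 0.3, missing_rate = 0.2, seed = 4)
  expect_identical(a, b)
  vals <- as.matrix(a[c("E12.5", "E13.0", "E13.5", "E14.0", "E14.5")])
  expect_true(all(vals > 0, na.rm = TRUE))
})
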