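test_that("sphere silhouettes are identical disks of the right radius", {
  rs <- render_silhouettes(shape_spec("sphere", 0.25), pixel_size_um = 10,
                           angles = seq(0, 350, 45))
  areas <- vapply(rs$stack$masks, sum, numeric(1))
  expect_equal(areas, rep(pi * 25^2, length(areas)), tolerance = 0.02)
  expect_true(all(vapply(rs$stack$masks, identical, logical(1),
                         rs$stack$masks[[1]])))
})

test_that("generator truth matches closed-form geometry", {
  tr <- render_silhouettes(shape_spec("ellipsoid", c(0.25, 0.155, 0.135)),
                           pixel_size_um = 20, angles = c(0, 90))$truth
  expect_equal(tr$volume_nl, 4 / 3 * pi * 0.25 * 0.155 * 0.135 * 1e3,
               tolerance = 1e-8)
  expect_equal(tr$length_mm, 0.5)
  expect_equal(tr$width_mm, 0.31)
  expect_equal(tr$height_mm, 0.27)

  sp <- shape_truth(shape_spec("sphere", 0.25))
  expect_equal(sp$surface_area_mm2, 4 * pi * 0.25^2, tolerance = 1e-8)
  expect_equal(sp$sphericity_pct, 100, tolerance = 1e-6)

  ## superellipsoid: volume between its inscribed ellipsoid and bounding box
  se <- shape_truth(shape_spec("superellipsoid", c(0.2, 0.15, 0.12),
                               exponent = 4))
  expect_gt(se$volume_nl, 4 / 3 * pi * 0.2 * 0.15 * 0.12 * 1e3)
  expect_lt(se$volume_nl, 8 * 0.2 * 0.15 * 0.12 * 1e3)
  expect_lt(se$sphericity_pct, 100)
})

test_that("occluded stacks are truncated above one common row", {
  rs <- render_silhouettes(shape_spec("sphere", 0.2, occluded_fraction = 0.2),
                           pixel_size_um = 5, angles = seq(0, 350, 30))
  row <- rs$stack$occlusion_row
  expect_true(is.numeric(row) && row > 1)
  for (m in rs$stack$masks) {
    expect_false(any(m[seq_len(row - 1), ]))
    expect_true(any(m[row, ])) # silhouette reaches the cut
  }
})

test_that("tray generation is reproducible and blob sizes are exact", {
  p <- tibble::tibble(col = 4, row = 1, n_px = 10)
  t1 <- make_tray_image(jitter_mm = 2, plants = p, rng_seed = 6)
  t2 <- make_tray_image(jitter_mm = 2, plants = p, rng_seed = 6)
  expect_identical(t1$image, t2$image)
  expect_identical(t1$truth$lattice, t2$truth$lattice)

  gm <- grid_from_lattice(t1$truth$lattice, c(5, 4))
  crops <- crop_pots(t1$image, gm, "T")
  i <- which(crops$x_index == 4 & crops$y_index == 1)
  expect_equal(green_area(crops$image[[i]])$green_pixels, 10)

  expect_error(make_tray_image(jitter_mm = 10), class = "seedtrack_error_domain")
})

test_that("growth curves are continuous, clipped and round-trippable", {
  gc <- make_growth_curve(noise_sd_mm2 = 0, rng_seed = 1)
  expect_true(all(gc$series$area_mm2[gc$series$time_d <= 3.77] == 0))
  fit <- fit_linear_segment(gc$series)
  expect_equal(fit$germination_time_d, 3.77, tolerance = 0.01)
  expect_equal(fit$growth_rate_mm2_d, 1.02, tolerance = 0.01)

  late <- make_growth_curve(germination_time_d = 20, switch_time_d = 24,
                            times_d = 1:14)
  expect_true(all(late$series$green_pixels == 0))

  a <- make_growth_curve(rng_seed = 1)
  b <- make_growth_curve(rng_seed = 2)
  expect_false(identical(a$series$area_mm2, b$series$area_mm2))
  expect_identical(a$truth, b$truth)

  expect_error(make_growth_curve(germination_time_d = 5, switch_time_d = 4),
               class = "seedtrack_error_domain")
})

test_that("seed batches hit their moments and correlation targets", {
  b <- make_seed_batch(1e4, rng_seed = 12)
  expect_equal(mean(b$mass_ug), 22.1, tolerance = 0.1 / 22.1)
  expect_equal(sd(b$mass_ug), 2.92, tolerance = 0.05)
  expect_equal(cor(b$mass_ug, b$volume_nl), 0.98, tolerance = 0.011)

  one <- make_seed_batch(1, rng_seed = 3)
  expect_equal(nrow(one), 1)

  bad <- matrix(c(1, 2, 2, 1), 2, 2,
                dimnames = list(c("mass", "volume"), c("mass", "volume")))
  expect_error(make_seed_batch(10, correlation = bad),
               class = "seedtrack_error_domain")

  ## default correlation structure is a valid correlation matrix
  R <- default_trait_correlation()
  expect_equal(diag(R), setNames(rep(1, 9), rownames(R)))
  ev <- eigen(R, symmetric = TRUE, only.values = TRUE)$values
  expect_true(all(ev > 0))
})

test_that("seeded generators are bit-reproducible", {
  expect_identical(make_seed_batch(50, rng_seed = 9),
                   make_seed_batch(50, rng_seed = 9))
  expect_identical(make_growth_curve(rng_seed = 9)$series,
                   make_growth_curve(rng_seed = 9)$series)
})
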