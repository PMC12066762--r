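test_that("crossings on an undisplaced tray are found at the lattice", {
  tr <- make_tray_image(jitter_mm = 0, rng_seed = 3)
  cx <- detect_crossings(tr$image)
  expect_equal(nrow(cx), 12)
  errs <- crossing_errors(cx, tr$truth$inner_crossings)
  expect_lt(max(errs), 1)
})

test_that("crossings on displaced trays stay within 2 px of truth", {
  for (seed in c(7, 21)) {
    tr <- make_tray_image(jitter_mm = 3, rng_seed = seed)
    cx <- detect_crossings(tr$image)
    errs <- crossing_errors(cx, tr$truth$inner_crossings)
    expect_lt(max(errs), 2)
  }
})

test_that("localization error stays bounded across jitter amplitudes", {
  errs <- vapply(c(0, 1.5, 3), function(j) {
    tr <- make_tray_image(jitter_mm = j, rng_seed = 13)
    max(crossing_errors(detect_crossings(tr$image), tr$truth$inner_crossings))
  }, numeric(1))
  expect_true(all(errs < 2))
})

test_that("a featureless image fails crossing detection", {
  flat <- array(0.4, c(320, 400, 3))
  expect_error(detect_crossings(flat), class = "seedtrack_error_detection")
})

test_that("a perfect lattice extrapolates exactly and equivariantly", {
  tr <- make_tray_image(jitter_mm = 0, rng_seed = 1)
  gm <- fit_and_extrapolate(tr$truth$inner_crossings)
  expect_equal(dim(gm$lattice), c(5, 6, 2))
  expect_equal(gm$lattice, tr$truth$lattice, tolerance = 1e-6)

  shifted <- tr$truth$inner_crossings
  shifted$x <- shifted$x + 7.5
  shifted$y <- shifted$y - 3.25
  gm2 <- fit_and_extrapolate(shifted)
  expect_equal(gm2$lattice[, , 1], gm$lattice[, , 1] + 7.5, tolerance = 1e-6)
  expect_equal(gm2$lattice[, , 2], gm$lattice[, , 2] - 3.25, tolerance = 1e-6)
})

test_that("jittered lattice extrapolation stays within 3 px of generator truth", {
  tr <- make_tray_image(jitter_mm = 3, rng_seed = 11)
  gm <- fit_and_extrapolate(detect_crossings(tr$image))
  err <- sqrt((gm$lattice[, , 1] - tr$truth$lattice[, , 1])^2 +
                (gm$lattice[, , 2] - tr$truth$lattice[, , 2])^2)
  expect_lt(max(err), 3)
})

test_that("degenerate crossing sets are rejected", {
  collinear <- data.frame(x = seq_len(12), y = rep(5, 12))
  expect_error(fit_and_extrapolate(collinear), class = "seedtrack_error_fit")
  expect_error(fit_and_extrapolate(data.frame(x = 1:5, y = 1:5)),
               class = "seedtrack_error_domain")
})

test_that("cropping partitions the tray and keeps blobs in their pots", {
  tr <- make_tray_image(
    jitter_mm = 2, rng_seed = 5,
    plants = tibble::tibble(col = 2, row = 3, n_px = 40)
  )
  gm <- fit_and_extrapolate(detect_crossings(tr$image))
  crops <- crop_pots(tr$image, gm, "T1")
  expect_equal(nrow(crops), 20)

  ## partition: crop pixel counts sum to the fitted tray quadrilateral area
  lat <- gm$lattice
  corners <- rbind(lat[1, 1, ], lat[1, 6, ], lat[5, 6, ], lat[5, 1, ])
  quad_area <- abs(sum(corners[, 1] * corners[c(2:4, 1), 2] -
                         corners[c(2:4, 1), 1] * corners[, 2])) / 2
  expect_equal(sum(crops$n_pixels), quad_area, tolerance = 0.02)

  ## the blob's pixels all land in crop (2, 3) and nowhere else
  counts <- vapply(seq_len(nrow(crops)), function(i) {
    if (is.null(crops$image[[i]])) return(0L)
    green_area(crops$image[[i]])$green_pixels
  }, integer(1))
  hit <- which(counts > 0)
  expect_equal(crops$x_index[hit], 2)
  expect_equal(crops$y_index[hit], 3)
  expect_equal(counts[hit], 40L)
})

test_that("a blob on a pot wall is split between exactly two crops", {
  tr <- make_tray_image(
    jitter_mm = 1, rng_seed = 9,
    plants = tibble::tibble(col = 3, row = 2, n_px = 60, offset = 1)
  )
  gm <- fit_and_extrapolate(detect_crossings(tr$image))
  crops <- crop_pots(tr$image, gm, "T1")
  counts <- vapply(seq_len(nrow(crops)), function(i) {
    if (is.null(crops$image[[i]])) return(0L)
    green_area(crops$image[[i]])$green_pixels
  }, integer(1))
  expect_equal(sum(counts), 60L)
  expect_equal(sum(counts > 0), 2)
})

test_that("a whole-image 1x1 grid crops to the input image", {
  img <- array(runif(40 * 30 * 3), c(30, 40, 3))
  lat <- array(0, c(2, 2, 2))
  lat[, , 1] <- matrix(c(0.5, 40.5, 0.5, 40.5), 2, 2, byrow = TRUE)
  lat[, , 2] <- matrix(c(0.5, 0.5, 30.5, 30.5), 2, 2, byrow = TRUE)
  crops <- crop_pots(img, grid_from_lattice(lat, c(1, 1)), "T1")
  expect_equal(nrow(crops), 1)
  expect_equal(crops$image[[1]], img)
})

test_that("adaptive cropping loses no plant pixels where a fixed grid does", {
  tr <- make_tray_image(
    jitter_mm = 3, rng_seed = 13,
    plants = tibble::tibble(col = 2, row = 2, n_px = 50, offset = 0.85)
  )
  blob <- tr$truth$plant_pixels[[1]]
  in_cell <- function(grid) {
    crops <- crop_pots(tr$image, grid, "T1")
    i <- which(crops$x_index == 2 & crops$y_index == 2)
    if (is.null(crops$mask[[i]])) return(0L)
    Ht <- dim(tr$image)[1]
    cell <- matrix(FALSE, Ht, dim(tr$image)[2])
    rows <- crops$offset_row[i] - 1 + seq_len(nrow(crops$mask[[i]]))
    cols <- crops$offset_col[i] - 1 + seq_len(ncol(crops$mask[[i]]))
    cell[rows, cols] <- crops$mask[[i]]
    sum(cell[blob])
  }
  adaptive <- fit_and_extrapolate(detect_crossings(tr$image))
  fixed <- grid_from_lattice(tr$truth$nominal_lattice, c(5, 4))
  kept_adaptive <- in_cell(adaptive)
  kept_fixed <- in_cell(fixed)
  expect_equal(kept_adaptive, 50L) # zero pixels lost
  expect_lt(kept_fixed, 50L)       # the fixed grid clips the plant
})
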