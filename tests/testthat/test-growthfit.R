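series_from_areas <- function(times, areas) {
  tibble::tibble(time_d = times, green_pixels = round(areas / 0.0013),
                 area_mm2 = areas)
}

test_that("green pixel counting converts exactly at the calibration", {
  soil <- array(0, c(20, 20, 3))
  soil[, , 1] <- 0.38; soil[, , 2] <- 0.30; soil[, , 3] <- 0.22
  expect_equal(green_area(soil)$green_pixels, 0)
  expect_equal(green_area(soil)$area_mm2, 0)

  blob <- soil
  for (k in 1:10) blob[3, k, ] <- c(0.2, 0.55, 0.15)
  g <- green_area(blob)
  expect_equal(g$green_pixels, 10)
  expect_equal(g$area_mm2, 0.013)

  blob100 <- soil
  idx <- cbind(rep(5:14, each = 10), rep(5:14, times = 10))
  for (ch in 1:3) {
    layer <- blob100[, , ch]
    layer[idx] <- c(0.2, 0.55, 0.15)[ch]
    blob100[, , ch] <- layer
  }
  expect_equal(green_area(blob100)$area_mm2, 0.13)
})

test_that("emergence is the first crossing of the 10-pixel threshold", {
  s <- leaf_area_series(1:5, c(0, 0, 9, 10, 40))
  expect_equal(detect_emergence(s), 4)
  expect_true(is.na(detect_emergence(leaf_area_series(1:5, rep(0, 5)))))
  expect_equal(detect_emergence(leaf_area_series(1:3, c(12, 20, 30))), 1)
})

test_that("a noiseless line is recovered exactly", {
  t <- 4:8
  s <- series_from_areas(t, 0.8 * (t - 3.5))
  fit <- suppressWarnings(fit_linear_segment(s)) # noiseless: lm warns on perfect fit
  expect_equal(fit$status, "fitted")
  expect_equal(fit$growth_rate_mm2_d, 0.8, tolerance = 1e-6)
  expect_equal(fit$germination_time_d, 3.5, tolerance = 1e-6)
  expect_equal(fit$adj_r2, 1, tolerance = 1e-6)
  expect_equal(glance(fit)$n_linear, 5)
})

test_that("leading zeros are dropped and short series yield no-linear-fit", {
  t <- 1:10
  a <- c(0, 0, 0, 0.5, 1.5, 2.5, 3.5, 4.5, 5.5, 6.5)
  fit <- suppressWarnings(fit_linear_segment(series_from_areas(t, a)))
  expect_equal(fit$status, "fitted")
  expect_equal(fit$linear_segment[1], 4)

  short <- series_from_areas(1:3, c(0.5, 1.5, 2.5))
  expect_equal(fit_linear_segment(short)$status, "no-linear-fit")
  allzero <- series_from_areas(1:6, rep(0, 6))
  expect_equal(fit_linear_segment(allzero)$status, "no-emergence")
})

test_that("each linear-fit acceptance criterion is individually necessary", {
  t <- 1:8
  good <- 1.0 * (t - 0.5) # qualifies easily
  expect_equal(suppressWarnings(fit_linear_segment(series_from_areas(t, good)))$status,
               "fitted")

  ## adjusted R^2 alone: weak slope, structured wiggle, small residuals
  wig <- rep(c(0.2, -0.2), 4)
  weak <- 0.6 + 0.18 * t + wig
  f_r2 <- fit_linear_segment(series_from_areas(t, weak))
  expect_equal(f_r2$status, "no-linear-fit")

  ## slope significance alone: flat positive series
  flat <- 2 + 0.005 * t + rep(c(0.05, -0.05), 4)
  expect_equal(fit_linear_segment(series_from_areas(t, flat))$status,
               "no-linear-fit")

  ## intercept significance alone: line through the origin
  origin <- 1.0 * t + rep(c(0.01, -0.01), 4)
  expect_equal(fit_linear_segment(series_from_areas(t, origin))$status,
               "no-linear-fit")

  ## deviance alone: steep line with large residuals
  noisy <- 5 * (t - 0.5) + rep(c(0.8, -0.8), 4)
  f_dev <- fit_linear_segment(series_from_areas(t, noisy))
  expect_equal(f_dev$status, "no-linear-fit")
})

test_that("a purely exponential series never passes as linear from the top", {
  t <- 1:12
  a <- 0.05 * exp(0.6 * t)
  fit <- fit_linear_segment(series_from_areas(t, a))
  expect_true(fit$status %in% c("fitted", "no-linear-fit"))
  if (fit$status == "fitted") {
    ## whatever was accepted is a trimmed early prefix, not the whole curve
    expect_lt(fit$linear_segment[2], length(t))
  }
})

test_that("growth-rate bias vanishes as observation noise vanishes", {
  bias <- vapply(c(0.3, 0.1, 0.02), function(ns) {
    rates <- vapply(1:60, function(i) {
      gc <- make_growth_curve(noise_sd_mm2 = ns, switch_time_d = 99,
                              times_d = seq(1, 10), rng_seed = 1000 + i)
      g <- glance(fit_linear_segment(gc$series))
      if (g$status == "fitted") g$growth_rate_mm2_d else NA_real_
    }, numeric(1))
    abs(mean(rates, na.rm = TRUE) - 1.02)
  }, numeric(1))
  expect_lt(bias[3], 0.01)
  expect_lt(bias[3], bias[1] + 1e-9)
})

test_that("germination time never exceeds the linear segment start", {
  for (i in 1:10) {
    gc <- make_growth_curve(rng_seed = i)
    fit <- fit_linear_segment(gc$series)
    if (fit$status == "fitted") {
      expect_lte(fit$germination_time_d,
                 gc$series$time_d[fit$linear_segment[1]])
    }
  }
})

test_that("negative x-intercepts are clamped to sowing time", {
  t <- 1:6
  s <- series_from_areas(t, 1 + 0.5 * t)
  fit <- suppressWarnings(fit_linear_segment(s))
  expect_equal(fit$status, "fitted")
  expect_equal(fit$germination_time_d, 0)
  expect_true("negative-intercept-clamped" %in% fit$flags)
})

test_that("exponential fits recover exact and noisy parameters", {
  t <- 1:10
  s <- series_from_areas(t, 0.1 * exp(0.5 * t))
  par <- fit_exponential(s)
  expect_equal(unname(par["A0"]), 0.1, tolerance = 0.01)
  expect_equal(unname(par["r"]), 0.5, tolerance = 0.01)

  set.seed(77)
  rs <- vapply(1:100, function(i) {
    a <- 0.1 * exp(0.5 * t) * exp(rnorm(length(t), 0, 0.05))
    fit_exponential(series_from_areas(t, a))["r"]
  }, numeric(1))
  expect_equal(mean(rs), 0.5, tolerance = 0.1)

  const <- series_from_areas(1:6, rep(2, 6))
  expect_lt(abs(fit_exponential(const)["r"]), 1e-6)
  expect_error(fit_exponential(series_from_areas(1:6, rep(0, 6))),
               class = "seedtrack_error_domain")
})

test_that("growth_traits maps over a long per-pot table", {
  d <- dplyr::bind_rows(lapply(1:3, function(i) {
    gc <- make_growth_curve(rng_seed = i)
    tibble::tibble(seed_id = sprintf("C-%04d", i),
                   time_d = gc$series$time_d,
                   green_pixels = gc$series$green_pixels)
  }))
  out <- growth_traits(d)
  expect_equal(nrow(out), 3)
  expect_true(all(out$status == "fitted"))
  expect_true(all(out$emergence_d >= 4))
})
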