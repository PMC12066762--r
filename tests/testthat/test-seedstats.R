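test_that("pneumatic release kinematics follow a = pi r^2 p / m", {
  k <- release_kinematics(3000, 75e-6, 2e-8, 5e-3)
  expect_equal(k$acceleration_m_s2, pi * (75e-6)^2 * 3000 / 2e-8)
  expect_equal(k$release_speed_m_s, sqrt(2 * k$acceleration_m_s2 * 5e-3))
  expect_equal(k$seed_speed_after_collision_m_s, 2 * k$hammer_speed_m_s)

  k0 <- release_kinematics(0, 75e-6, 2e-8, 5e-3)
  expect_equal(k0$acceleration_m_s2, 0)
  expect_equal(k0$release_speed_m_s, 0)
  expect_error(release_kinematics(3000, -1, 2e-8, 5e-3),
               class = "seedtrack_error_domain")
})

test_that("balance-noise simulation obeys variance additivity", {
  expect_identical(simulate_old_balance(c(10, 20), rel_sd = 0, draws_per_value = 3),
                   rep(c(10, 20), each = 3))

  x <- simulate_old_balance(20, rel_sd = 0.15, draws_per_value = 1e5, rng_seed = 4)
  expect_equal(sd(x), 3.0, tolerance = 0.02)

  base <- batch_quantile_sample(22.1, 2.92, 98)
  infl <- simulate_old_balance(base, rel_sd = 0.15, draws_per_value = 2000,
                               rng_seed = 8)
  expect_equal(sd(infl), sqrt(2.92^2 + (0.15 * 22.1)^2), tolerance = 0.05)
  expect_error(simulate_old_balance(numeric(0)), class = "seedtrack_error_domain")
})

test_that("minimal n grows monotonically with measurement noise", {
  s <- seed_trait_summaries()
  mass <- s[s$trait == "mass", ]
  ns <- vapply(c(0, 0.08, 0.15), function(rs) {
    sd_c <- sqrt(mass$sd_C^2 + (rs * mass$mean_C)^2)
    sd_t <- sqrt(mass$sd_T^2 + (rs * mass$mean_T)^2)
    minimal_n(list(mean = mass$mean_C, sd = sd_c),
              list(mean = mass$mean_T, sd = sd_t))
  }, numeric(1))
  expect_true(all(diff(ns) >= 0))
  expect_warning(res <- minimal_n(list(mean = 5, sd = 1), list(mean = 5, sd = 2)),
                 "equal means")
  expect_identical(res, Inf)
})

test_that("sigma CI width shrinks with n and vanishes asymptotically", {
  w <- sd_confidence_width(c(10, 20, 50, 100, 200, 1000, 10000))
  expect_true(all(diff(w$width_pct) < 0))
  expect_lt(w$width_pct[7], 3)
  expect_true(all(w$lower_frac < 1 & w$upper_frac > 1))
  expect_error(sd_confidence_width(1), class = "seedtrack_error_domain")
})

test_that("Welch test from summaries matches published magnitudes and the null", {
  s <- seed_trait_summaries()
  mass <- s[s$trait == "mass", ]
  wt <- welch_ttest(list(mean = mass$mean_C, sd = mass$sd_C, n = mass$n_C),
                    list(mean = mass$mean_T, sd = mass$sd_T, n = mass$n_T))
  expect_gt(wt$p, 1.6e-07 / 2)
  expect_lt(wt$p, 1.6e-07 * 2)

  same <- list(mean = 10, sd = 2, n = 50)
  expect_equal(welch_ttest(same, same)$p, 1)
  expect_error(welch_ttest(list(mean = 1, sd = 1, n = 1), same),
               class = "seedtrack_error_domain")
})

test_that("Welch test holds its type-I error rate under the null", {
  set.seed(99)
  reject <- vapply(1:1000, function(i) {
    a <- rnorm(20, 10, 2)
    b <- rnorm(20, 10, 2)
    welch_ttest(list(mean = mean(a), sd = sd(a), n = 20),
                list(mean = mean(b), sd = sd(b), n = 20))$p < 0.05
  }, logical(1))
  expect_equal(mean(reject), 0.05, tolerance = 0.4) # 0.03-0.07 band
})

test_that("density in ug/nl is g/cm^3 and flags implausible seeds", {
  d <- density_check(22.1, 20.5)
  expect_equal(d$density_g_cm3, 22.1 / 20.5)
  expect_true(d$valid)
  d2 <- density_check(44, 20) # double pick-up
  expect_equal(d2$density_g_cm3, 2.2)
  expect_false(d2$valid)
  expect_error(density_check(20, 0), class = "seedtrack_error_domain")
})

test_that("correlation matrix is symmetric with unit diagonal and stars", {
  b <- make_seed_batch(200, rng_seed = 31)
  cm <- correlation_matrix(b, c("mass_ug", "volume_nl", "brightness_pct",
                                "germination_time_d"))
  expect_equal(diag(cm$r), rep(1, 4), ignore_attr = TRUE)
  expect_equal(cm$r, t(cm$r))
  expect_equal(cm$r["mass_ug", "volume_nl"], 0.98, tolerance = 0.021)
  expect_equal(cm$stars["mass_ug", "volume_nl"], "***")
  td <- tidy(cm)
  expect_equal(nrow(td), 16)

  ## independent traits stay near zero
  set.seed(5)
  ind <- tibble::tibble(a = rnorm(200), b = rnorm(200))
  cmi <- correlation_matrix(ind)
  expect_lt(abs(cmi$r["a", "b"]), 0.2)

  ## constant trait: correlation undefined
  cc <- correlation_matrix(tibble::tibble(a = rnorm(10), k = rep(1, 10)))
  expect_true(is.na(cc$r["a", "k"]))
})
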