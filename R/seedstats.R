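## Batch-level statistics: release kinematics of the seed handling tool,
## measurement-noise simulation, sample-size calculations, sigma
## confidence intervals, Welch tests, density validation and trait
## correlation matrices.

#' Reference trait summaries for Col-0 seed batches
#'
#' Published per-trait means, standard deviations and sample sizes for an
#' Arabidopsis Col-0 control batch (`C`) and a batch from two generations
#' of elevated temperature during flowering (`T`). These summaries are
#' the standard inputs for sample-size calculations and for
#' parameterizing the synthetic seed-batch generator.
#'
#' @return Tibble with columns `trait`, `unit`, `mean_C`, `mean_T`,
#'   `sd_C`, `sd_T`, `n_C`, `n_T`.
#' @export
seed_trait_summaries <- function() {
  tibble::tribble(
    ~trait,              ~unit,     ~mean_C, ~mean_T, ~sd_C, ~sd_T, ~n_C, ~n_T,
    "mass",              "ug",      22.1,    24.8,    2.92,  3.95,  98L,  98L,
    "volume",            "nl",      20.5,    23.0,    2.69,  3.46,  99L,  96L,
    "length",            "mm",      0.49,    0.51,    0.04,  0.05,  99L,  96L,
    "width",             "mm",      0.31,    0.33,    0.02,  0.02,  99L,  96L,
    "height",            "mm",      0.27,    0.27,    0.02,  0.02,  99L,  96L,
    "sphericity",        "%",       94.5,    92.9,    1.64,  1.95,  99L,  96L,
    "brightness",        "%",       38.4,    34.2,    3.01,  3.66,  94L,  97L,
    "germination_time",  "d",       3.77,    4.62,    1.50,  2.33,  60L,  56L,
    "growth_rate",       "mm2/d",   1.02,    1.09,    0.23,  0.19,  49L,  40L
  )
}

#' Kinematics of pneumatic and hammer-based seed release
#'
#' For pneumatic release, a seed at the nozzle receives an initial
#' acceleration `a = pi r^2 p / m` from the overpressure acting on the
#' nozzle cross-section and reaches `v = sqrt(2 a d)` over the distance
#' `d` of sustained acceleration. For the mechanical alternative, a
#' "hammer" of much larger mass falls a small height `h` inside the
#' nozzle, reaching `sqrt(2 g h)`; an elastic collision with a much
#' lighter seed caps the seed speed at twice the hammer speed.
#'
#' @param overpressure_pa Release overpressure in Pa (>= 0).
#' @param nozzle_radius_m Inner nozzle radius in m.
#' @param seed_mass_kg Seed mass in kg.
#' @param distance_m Acceleration distance in m.
#' @param hammer_drop_m Hammer fall height in m (default 1 mm).
#' @param hammer_mass_kg Hammer mass in kg (default 7.2 mg).
#' @return One-row tibble: `acceleration_m_s2`, `release_speed_m_s`,
#'   `hammer_speed_m_s`, `seed_speed_after_collision_m_s`.
#' @export
release_kinematics <- function(overpressure_pa, nozzle_radius_m, seed_mass_kg,
                               distance_m, hammer_drop_m = 1e-3,
                               hammer_mass_kg = 7.2e-6) {
  if (overpressure_pa < 0 || nozzle_radius_m <= 0 || seed_mass_kg <= 0 ||
      distance_m <= 0 || hammer_drop_m < 0 || hammer_mass_kg <= 0) {
    abort("kinematic inputs must be positive (overpressure and hammer drop may be 0)",
          class = "seedtrack_error_domain")
  }
  g <- 9.80665
  a <- pi * nozzle_radius_m^2 * overpressure_pa / seed_mass_kg
  v <- sqrt(2 * a * distance_m)
  vh <- sqrt(2 * g * hammer_drop_m)
  tibble(
    acceleration_m_s2 = a,
    release_speed_m_s = v,
    hammer_speed_m_s = vh,
    seed_speed_after_collision_m_s = 2 * vh
  )
}

#' Simulate the noise of a low-resolution balance
#'
#' Around each true mass a normal distribution with a relative standard
#' deviation `rel_sd` (default 15%, the repeatability of the older 1 ug
#' balance) is built, and `draws_per_value` values are drawn from each,
#' producing the inflated total distribution of the batch. As the number
#' of draws grows, the sample SD converges to
#' `sqrt(sd(values)^2 + (rel_sd * mean(values))^2)`.
#'
#' @param values Measured values (e.g. seed masses in ug).
#' @param rel_sd Relative SD of the simulated measurement noise.
#' @param draws_per_value Draws per source value.
#' @param rng_seed Optional integer seed for reproducibility.
#' @return Numeric vector of `length(values) * draws_per_value` draws.
#' @export
simulate_old_balance <- function(values, rel_sd = 0.15, draws_per_value = 100,
                                 rng_seed = NULL) {
  if (length(values) == 0) abort("values must be non-empty",
                                 class = "seedtrack_error_domain")
  if (rel_sd < 0) abort("rel_sd must be >= 0", class = "seedtrack_error_domain")
  if (!is.null(rng_seed)) set.seed(rng_seed)
  rnorm(length(values) * draws_per_value,
        mean = rep(values, each = draws_per_value),
        sd = rep(abs(values) * rel_sd, each = draws_per_value))
}

#' Deterministic normal batch sample with exact moments
#'
#' Normal quantiles at plotting positions, affinely rescaled to hit the
#' requested mean and SD exactly. Useful as a fixed stand-in for a batch
#' only known through its summary statistics.
#'
#' @param mean,sd Target moments.
#' @param n Sample size.
#' @return Numeric vector of length `n`.
#' @export
batch_quantile_sample <- function(mean, sd, n) {
  q <- qnorm(ppoints(n))
  mean + sd * (q - base::mean(q)) / stats::sd(q)
}

## Welch t statistic, df and two-sided p from summary statistics.
welch_from_summaries <- function(m1, s1, n1, m2, s2, n2) {
  se2 <- s1^2 / n1 + s2^2 / n2
  t <- (m1 - m2) / sqrt(se2)
  df <- se2^2 / ((s1^2 / n1)^2 / (n1 - 1) + (s2^2 / n2)^2 / (n2 - 1))
  c(t = t, df = df, p = 2 * pt(-abs(t), df))
}

#' Minimal sample size separating two batch distributions
#'
#' Smallest equal per-batch `n` at which the two-sample t statistic,
#' computed from the batch distributions at sample size `n`, exceeds the
#' critical t value at level `alpha` (two-sided, unequal variances).
#'
#' @param batch_a,batch_b Either numeric sample vectors or lists/one-row
#'   data frames with elements `mean` and `sd`.
#' @param alpha Significance level (default 0.05, i.e. 95% significance).
#' @param n_max Upper end of the search range.
#' @return The minimal `n`, or `Inf` (with a warning) if the means are
#'   equal or `n_max` is insufficient.
#' @export
minimal_n <- function(batch_a, batch_b, alpha = 0.05, n_max = 10000) {
  a <- as_summary(batch_a)
  b <- as_summary(batch_b)
  if (a$mean == b$mean) {
    warn("equal means: no finite n separates the batches")
    return(Inf)
  }
  for (n in 2:n_max) {
    wt <- welch_from_summaries(a$mean, a$sd, n, b$mean, b$sd, n)
    if (abs(wt[["t"]]) > qt(1 - alpha / 2, wt[["df"]])) return(n)
  }
  warn(sprintf("no n <= %d reaches significance", n_max))
  Inf
}

as_summary <- function(x) {
  if (is.numeric(x) && length(x) > 1) {
    list(mean = mean(x), sd = sd(x))
  } else if (is.list(x) && all(c("mean", "sd") %in% names(x))) {
    list(mean = as.numeric(x$mean[1]), sd = as.numeric(x$sd[1]))
  } else {
    abort("batch must be a sample vector or a list with mean and sd",
          class = "seedtrack_error_domain")
  }
}

#' Resampled minimal-n procedure
#'
#' The simulation counterpart of [minimal_n()]: fixed base batches (given
#' as value vectors) are inflated with relative normal measurement noise
#' via [simulate_old_balance()], the minimal `n` is computed from each
#' inflated distribution, and the procedure is repeated `reps` times.
#' With `rel_sd = 0` every repetition reproduces the analytic result.
#'
#' @param values_a,values_b Base batch values.
#' @param rel_sd Relative measurement noise (0 = none).
#' @param draws_per_value Draws per value per repetition.
#' @param reps Number of repetitions.
#' @param alpha Significance level.
#' @param rng_seed Integer seed.
#' @return List with `ns` (per-repetition minimal n), `mean`, and
#'   `majority` (the modal minimal n).
#' @export
minimal_n_resampled <- function(values_a, values_b, rel_sd = 0.15,
                                draws_per_value = 100, reps = 1000,
                                alpha = 0.05, rng_seed = 1) {
  set.seed(rng_seed)
  ns <- vapply(seq_len(reps), function(i) {
    da <- if (rel_sd > 0) simulate_old_balance(values_a, rel_sd, draws_per_value)
          else values_a
    db <- if (rel_sd > 0) simulate_old_balance(values_b, rel_sd, draws_per_value)
          else values_b
    minimal_n(da, db, alpha = alpha)
  }, numeric(1))
  tab <- table(ns)
  list(ns = ns, mean = mean(ns),
       majority = as.numeric(names(tab)[which.max(tab)]))
}

#' Confidence interval width for a standard deviation
#'
#' Single-sample chi-square interval for sigma estimated from `n`
#' observations: the bounds, as fractions of sigma, are
#' `sqrt((n-1) / qchisq(1 -/+ alpha/2, n-1))`. The width is reported in
#' percent of sigma.
#'
#' @param n Sample size (>= 2), vectorized.
#' @param conf Confidence level (default 0.95).
#' @return Tibble: `n`, `lower_frac`, `upper_frac`, `width_pct`
#'   (unrounded) and `width_pct_int` (integer-rounded).
#' @export
sd_confidence_width <- function(n, conf = 0.95) {
  if (any(n < 2)) abort("n must be >= 2", class = "seedtrack_error_domain")
  alpha <- 1 - conf
  lower <- sqrt((n - 1) / qchisq(1 - alpha / 2, n - 1))
  upper <- sqrt((n - 1) / qchisq(alpha / 2, n - 1))
  width <- (upper - lower) * 100
  tibble(n = n, lower_frac = lower, upper_frac = upper,
         width_pct = width, width_pct_int = as.integer(round(width)))
}

#' Welch two-sample t-test from summary statistics
#'
#' Two-sided unequal-variance t-test computed from per-batch means, SDs
#' and sample sizes (Welch-Satterthwaite degrees of freedom).
#'
#' @param summary_a,summary_b Lists or one-row data frames with `mean`,
#'   `sd`, `n`.
#' @return One-row tibble: `t`, `df`, `p`.
#' @export
welch_ttest <- function(summary_a, summary_b) {
  need <- function(x) {
    if (!all(c("mean", "sd", "n") %in% names(x))) {
      abort("summaries need mean, sd and n", class = "seedtrack_error_domain")
    }
    lapply(x[c("mean", "sd", "n")], function(v) as.numeric(v[1]))
  }
  a <- need(summary_a); b <- need(summary_b)
  if (a$n < 2 || b$n < 2) abort("n must be >= 2", class = "seedtrack_error_domain")
  wt <- welch_from_summaries(a$mean, a$sd, a$n, b$mean, b$sd, b$n)
  tibble(t = wt[["t"]], df = wt[["df"]], p = wt[["p"]])
}

#' Seed density sanity check
#'
#' Density in g/cm^3 equals mass in ug divided by volume in nl (the two
#' unit systems coincide numerically). Densities outside `bounds` flag a
#' likely invalid mass or volume estimate, e.g. a double pick-up, a
#' broken seed, or carving failure.
#'
#' @param mass_ug Seed mass in ug (vectorized).
#' @param volume_nl Seed volume in nl (vectorized).
#' @param bounds Valid density interval in g/cm^3.
#' @return Tibble: `density_g_cm3`, `valid`.
#' @export
density_check <- function(mass_ug, volume_nl, bounds = c(0.8, 1.4)) {
  if (any(volume_nl <= 0)) abort("volume must be > 0",
                                 class = "seedtrack_error_domain")
  d <- mass_ug / volume_nl
  tibble(density_g_cm3 = d, valid = d >= bounds[1] & d <= bounds[2])
}

#' Pairwise Pearson correlation matrix with significance stars
#'
#' Pearson correlations between all pairs of the selected trait columns,
#' using pairwise-complete observations, with p values from [cor.test()]
#' and the conventional three-level stars (`*` p < 0.05, `**` p < 0.01,
#' `***` p < 0.001). Constant traits yield `NA` correlations.
#'
#' @param records Data frame of per-seed records.
#' @param traits Character vector of trait column names (default: all
#'   numeric columns).
#' @return Object of class `trait_cor`: list of matrices `r`, `p`, `n`,
#'   `stars`. Has [tidy()] and [autoplot()] methods.
#' @export
correlation_matrix <- function(records, traits = NULL) {
  if (is.null(traits)) {
    traits <- names(records)[vapply(records, is.numeric, logical(1))]
  }
  m <- as.matrix(records[traits])
  k <- length(traits)
  r <- p <- n <- matrix(NA_real_, k, k, dimnames = list(traits, traits))
  for (i in seq_len(k)) {
    for (j in seq_len(k)) {
      ok <- complete.cases(m[, i], m[, j])
      n[i, j] <- sum(ok)
      if (i == j) {
        if (n[i, j] >= 1 && sd_or_zero(m[ok, i]) >= 0) r[i, j] <- 1
        next
      }
      if (n[i, j] < 3 || sd_or_zero(m[ok, i]) == 0 || sd_or_zero(m[ok, j]) == 0) next
      ct <- suppressWarnings(cor.test(m[ok, i], m[ok, j]))
      r[i, j] <- unname(ct$estimate)
      p[i, j] <- ct$p.value
    }
  }
  stars <- matrix("", k, k, dimnames = list(traits, traits))
  stars[!is.na(p) & p < 0.05] <- "*"
  stars[!is.na(p) & p < 0.01] <- "**"
  stars[!is.na(p) & p < 0.001] <- "***"
  structure(list(r = r, p = p, n = n, stars = stars, traits = traits),
            class = "trait_cor")
}

#' @export
print.trait_cor <- function(x, ...) {
  cat(sprintf("<trait_cor> %d traits\n", length(x$traits)))
  print(round(x$r, 2))
  invisible(x)
}

#' @rdname correlation_matrix
#' @param x,object A `trait_cor`.
#' @param ... Unused.
#' @export
tidy.trait_cor <- function(x, ...) {
  out <- expand.grid(trait_a = x$traits, trait_b = x$traits,
                     stringsAsFactors = FALSE)
  out$r <- as.vector(x$r)
  out$p <- as.vector(x$p)
  out$n <- as.vector(x$n)
  out$stars <- as.vector(x$stars)
  as_tibble(out)
}

#' @rdname correlation_matrix
#' @export
autoplot.trait_cor <- function(object, ...) {
  df <- tidy(object)
  df$label <- ifelse(is.na(df$r), "", sprintf("%.2f%s", df$r, df$stars))
  ggplot2::ggplot(df, ggplot2::aes(.data$trait_a, .data$trait_b, fill = .data$r)) +
    ggplot2::geom_tile() +
    ggplot2::geom_text(ggplot2::aes(label = .data$label), size = 3) +
    ggplot2::scale_fill_gradient2(limits = c(-1, 1), low = "steelblue",
                                  high = "firebrick", mid = "white",
                                  na.value = "grey90") +
    ggplot2::labs(x = NULL, y = NULL, fill = "Pearson r") +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45, hjust = 1))
}
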