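## Leaf-area time series and the germination / early-growth model.
##
## Emergence is defined operationally: a seedling has germinated once its
## top-view image contains at least 10 green pixels (0.013 mm^2 at the
## default calibration of 0.0013 mm^2/px). Early growth (cotyledon
## expansion) is linear in time; exponential growth starts with the first
## true leaves. The early growth rate is the slope of the linear phase
## and germination time is that line's x-axis intercept.

#' Default Growscreen pixel area (mm^2 per pixel)
#'
#' 10 green pixels correspond to 0.013 mm^2 of projected leaf area.
#' @export
GROWSCREEN_PIXEL_AREA <- 0.0013

#' Build a leaf-area time series
#'
#' @param times Days after sowing, strictly increasing.
#' @param green_pixels Integer green-pixel counts per time point.
#' @param pixel_area Projected area of one pixel in mm^2.
#' @return Tibble with columns `time_d`, `green_pixels`, `area_mm2` and
#'   attribute `pixel_area`.
#' @export
leaf_area_series <- function(times, green_pixels,
                             pixel_area = GROWSCREEN_PIXEL_AREA) {
  stopifnot(length(times) == length(green_pixels), pixel_area > 0)
  if (any(diff(times) <= 0)) {
    abort("times must be strictly increasing", class = "seedtrack_error_domain")
  }
  out <- tibble(time_d = as.numeric(times),
                green_pixels = as.integer(round(green_pixels)))
  out$area_mm2 <- out$green_pixels * pixel_area
  attr(out, "pixel_area") <- pixel_area
  out
}

#' Count green pixels in a pot image
#'
#' Pixels are classified green by HSV gates (defaults: hue 60-180 deg,
#' saturation > 0.25, value > 0.15), which separates seedling tissue from
#' soil and pot walls in top-view images.
#'
#' @param image RGB array in `[0, 1]`.
#' @param pixel_area mm^2 per pixel.
#' @param hue_range,min_saturation,min_value Classification gates.
#' @return One-row tibble: `green_pixels`, `area_mm2`.
#' @export
green_area <- function(image, pixel_area = GROWSCREEN_PIXEL_AREA,
                       hue_range = c(60, 180), min_saturation = 0.25,
                       min_value = 0.15) {
  stopifnot(length(dim(image)) == 3)
  hsv <- image_hsv(image)
  green <- hsv$h >= hue_range[1] & hsv$h <= hue_range[2] &
    hsv$s > min_saturation & hsv$v > min_value
  n <- sum(green)
  tibble(green_pixels = n, area_mm2 = n * pixel_area)
}

#' Detect seedling emergence
#'
#' Earliest time point at which the green-pixel count reaches the
#' emergence threshold (default 10 px).
#'
#' @param series Leaf-area series, see [leaf_area_series()].
#' @param threshold_px Emergence threshold in green pixels.
#' @return The emergence time in days, or `NA_real_` if never reached.
#' @export
detect_emergence <- function(series, threshold_px = 10) {
  hit <- which(series$green_pixels >= threshold_px)
  if (length(hit) == 0) return(NA_real_)
  series$time_d[hit[1]]
}

#' Fit the linear early-growth phase by backward elimination
#'
#' Starting from the full post-emergence series, one data point is
#' removed from the *end* at a time until the remaining prefix passes all
#' acceptance criteria for a linear fit: adjusted R^2 > 0.9, slope and
#' intercept both significantly different from 0 (two-sided t-test,
#' `alpha`), and deviance (residual sum of squares of the Gaussian
#' linear model) divided by the number of observations below 0.1.
#' The longest qualifying prefix wins. The slope of the accepted fit is
#' the early growth rate; its x-axis intercept is the germination time.
#'
#' @param series Leaf-area series; leading all-zero observations are
#'   dropped automatically.
#' @param min_points Smallest admissible segment length (default 4, which
#'   leaves 2 residual degrees of freedom).
#' @param alpha Significance level for the slope/intercept t-tests.
#' @param adj_r2_min,deviance_per_n_max Fit-acceptance gates.
#' @return Object of class `growth_fit` with `status` one of `"fitted"`,
#'   `"no-emergence"`, `"no-linear-fit"`; when fitted it carries
#'   `germination_time_d`, `growth_rate_mm2_d`, the linear-segment index
#'   range (relative to the input series), fit diagnostics and the
#'   exponential-phase parameters. Has [tidy()], [glance()] and
#'   [autoplot()] methods.
#' @export
fit_linear_segment <- function(series, min_points = 4, alpha = 0.05,
                               adj_r2_min = 0.9, deviance_per_n_max = 0.1) {
  stopifnot(is.data.frame(series), all(c("time_d", "area_mm2") %in% names(series)))
  first_pos <- which(series$area_mm2 > 0)
  base <- list(series = as_tibble(series), exp_params = c(A0 = NA_real_, r = NA_real_),
               flags = character())
  if (length(first_pos) == 0) {
    return(structure(c(base, list(status = "no-emergence")), class = "growth_fit"))
  }
  start <- first_pos[1]
  t_all <- series$time_d[start:nrow(series)]
  a_all <- series$area_mm2[start:nrow(series)]
  n_all <- length(t_all)
  if (n_all < min_points) {
    return(structure(c(base, list(status = "no-linear-fit")), class = "growth_fit"))
  }

  accepted <- NULL
  for (end in n_all:min_points) {
    tt <- t_all[1:end]; aa <- a_all[1:end]
    fit <- lm(aa ~ tt)
    sm <- summary(fit)
    crit <- linear_fit_criteria(sm, n = end, alpha = alpha,
                                adj_r2_min = adj_r2_min,
                                deviance_per_n_max = deviance_per_n_max)
    if (all(unlist(crit$pass)) && coef(fit)[2] > 0) {
      accepted <- list(fit = fit, sm = sm, end = end, crit = crit)
      break
    }
  }
  if (is.null(accepted)) {
    return(structure(c(base, list(status = "no-linear-fit")), class = "growth_fit"))
  }

  slope <- unname(coef(accepted$fit)[2])
  intercept <- unname(coef(accepted$fit)[1])
  gt <- -intercept / slope
  flags <- character()
  if (gt < 0) {
    flags <- "negative-intercept-clamped"
    gt <- 0
  }
  exp_par <- tryCatch(
    fit_exponential(series),
    error = function(e) c(A0 = NA_real_, r = NA_real_)
  )
  structure(
    list(
      status = "fitted",
      germination_time_d = gt,
      growth_rate_mm2_d = slope,
      slope = slope,
      intercept = intercept,
      linear_segment = c(start, start + accepted$end - 1),
      adj_r2 = accepted$crit$adj_r2,
      deviance_per_n = accepted$crit$deviance_per_n,
      slope_p = accepted$crit$slope_p,
      intercept_p = accepted$crit$intercept_p,
      exp_params = exp_par,
      flags = flags,
      series = as_tibble(series)
    ),
    class = "growth_fit"
  )
}

## The conjunctive acceptance criteria for one candidate linear fit.
linear_fit_criteria <- function(sm, n, alpha, adj_r2_min, deviance_per_n_max) {
  dev_per_n <- sum(sm$residuals^2) / n
  slope_p <- sm$coefficients[2, 4]
  intercept_p <- sm$coefficients[1, 4]
  list(
    adj_r2 = sm$adj.r.squared,
    deviance_per_n = dev_per_n,
    slope_p = slope_p,
    intercept_p = intercept_p,
    pass = list(
      adj_r2 = is.finite(sm$adj.r.squared) && sm$adj.r.squared > adj_r2_min,
      deviance = dev_per_n < deviance_per_n_max,
      slope = is.finite(slope_p) && slope_p < alpha,
      intercept = is.finite(intercept_p) && intercept_p < alpha
    )
  )
}

#' Fit the exponential growth phase
#'
#' Least-squares fit of `area = A0 * exp(r * t)` over all positive-area
#' points from emergence onward, started from the log-linear solution and
#' refined with Levenberg-Marquardt.
#'
#' @param series Leaf-area series.
#' @return Named numeric `c(A0 = , r = )`.
#' @export
fit_exponential <- function(series) {
  pos <- series$area_mm2 > 0
  if (sum(pos) < 3) {
    abort("need at least 3 positive-area points", class = "seedtrack_error_domain")
  }
  tt <- series$time_d[pos]
  aa <- series$area_mm2[pos]
  lf <- lm(log(aa) ~ tt)
  start <- list(A0 = exp(unname(coef(lf)[1])), r = unname(coef(lf)[2]))
  fit <- tryCatch(
    minpack.lm::nlsLM(aa ~ A0 * exp(r * tt), start = start,
                      control = minpack.lm::nls.lm.control(maxiter = 200)),
    error = function(e) NULL
  )
  if (is.null(fit)) {
    c(A0 = start$A0, r = start$r)
  } else {
    c(A0 = unname(coef(fit)["A0"]), r = unname(coef(fit)["r"]))
  }
}

#' @export
print.growth_fit <- function(x, ...) {
  if (x$status != "fitted") {
    cat(sprintf("<growth_fit> status: %s\n", x$status))
  } else {
    cat(sprintf(
      "<growth_fit> germination %.2f d, growth rate %.3f mm^2/d (segment %d..%d, adj R^2 %.3f)\n",
      x$germination_time_d, x$growth_rate_mm2_d,
      x$linear_segment[1], x$linear_segment[2], x$adj_r2))
  }
  invisible(x)
}

#' @rdname fit_linear_segment
#' @param x,object A `growth_fit`.
#' @param ... Unused.
#' @export
tidy.growth_fit <- function(x, ...) {
  if (x$status != "fitted") {
    return(tibble(term = character(), estimate = numeric(), p.value = numeric()))
  }
  tibble(
    term = c("intercept", "slope", "exp_A0", "exp_r"),
    estimate = c(x$intercept, x$slope, x$exp_params[["A0"]], x$exp_params[["r"]]),
    p.value = c(x$intercept_p, x$slope_p, NA_real_, NA_real_)
  )
}

#' @rdname fit_linear_segment
#' @export
glance.growth_fit <- function(x, ...) {
  tibble(
    status = x$status,
    germination_time_d = if (x$status == "fitted") x$germination_time_d else NA_real_,
    growth_rate_mm2_d = if (x$status == "fitted") x$growth_rate_mm2_d else NA_real_,
    adj_r2 = if (x$status == "fitted") x$adj_r2 else NA_real_,
    deviance_per_n = if (x$status == "fitted") x$deviance_per_n else NA_real_,
    n_linear = if (x$status == "fitted") diff(x$linear_segment) + 1L else NA_integer_,
    exp_r = x$exp_params[["r"]],
    flags = paste(x$flags, collapse = ";")
  )
}

#' @rdname fit_linear_segment
#' @export
autoplot.growth_fit <- function(object, ...) {
  df <- object$series
  p <- ggplot2::ggplot(df, ggplot2::aes(.data$time_d, .data$area_mm2)) +
    ggplot2::geom_point() +
    ggplot2::labs(x = "days after sowing", y = "projected leaf area [mm²]")
  if (object$status == "fitted") {
    seg <- df[object$linear_segment[1]:object$linear_segment[2], ]
    p <- p +
      ggplot2::geom_point(data = seg, colour = "darkgreen") +
      ggplot2::geom_abline(slope = object$slope, intercept = object$intercept,
                           colour = "darkgreen")
    if (is.finite(object$exp_params[["r"]])) {
      grid <- tibble(time_d = seq(min(seg$time_d), max(df$time_d), length.out = 100))
      grid$area_mm2 <- object$exp_params[["A0"]] *
        exp(object$exp_params[["r"]] * grid$time_d)
      p <- p + ggplot2::geom_line(data = grid, colour = "orange")
    }
  }
  p
}

#' Germination and growth traits for many pots at once
#'
#' Maps [detect_emergence()] and [fit_linear_segment()] over a long table
#' of per-pot observations.
#'
#' @param data Long tibble with columns `seed_id`, `time_d` and
#'   `green_pixels`.
#' @param pixel_area mm^2 per pixel.
#' @param threshold_px Emergence threshold.
#' @param ... Passed to [fit_linear_segment()].
#' @return One row per seed: emergence time, fit status, germination
#'   time, growth rate and diagnostics.
#' @export
growth_traits <- function(data, pixel_area = GROWSCREEN_PIXEL_AREA,
                          threshold_px = 10, ...) {
  stopifnot(all(c("seed_id", "time_d", "green_pixels") %in% names(data)))
  data |>
    dplyr::group_by(.data$seed_id) |>
    dplyr::arrange(.data$time_d, .by_group = TRUE) |>
    dplyr::group_modify(function(d, key) {
      s <- leaf_area_series(d$time_d, d$green_pixels, pixel_area)
      emer <- detect_emergence(s, threshold_px)
      g <- glance(fit_linear_segment(s, ...))
      g$emergence_d <- emer
      g
    }) |>
    dplyr::ungroup()
}
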