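#' Simulate a seedling leaf-area growth curve
#'
#' Projected leaf area is zero before germination, grows linearly during
#' cotyledon expansion, and switches to exponential growth (first true
#' leaves) at `switch_time`, matched in value at the switch so the curve
#' is continuous. Additive Gaussian noise emulates segmentation noise;
#' negative areas are clipped to zero and areas are quantized to whole
#' green pixels, as the imaging system reports them.
#'
#' @param germination_time_d Germination time in days after sowing.
#' @param linear_rate_mm2_d Early growth rate (slope of the linear
#'   phase), mm^2/day.
#' @param switch_time_d Onset of the exponential phase (> germination).
#' @param exp_rate_d Relative growth rate of the exponential phase, 1/day.
#' @param noise_sd_mm2 SD of the additive observation noise.
#' @param times_d Sampling times (default daily, day 1 to 14).
#' @param pixel_area mm^2 per green pixel.
#' @param rng_seed Optional integer seed.
#' @return List: `series` (a [leaf_area_series()]) and `truth` (tibble of
#'   the generating parameters).
#' @export
make_growth_curve <- function(germination_time_d = 3.77,
                              linear_rate_mm2_d = 1.02,
                              switch_time_d = 8,
                              exp_rate_d = 0.5,
                              noise_sd_mm2 = 0.05,
                              times_d = seq(1, 14),
                              pixel_area = GROWSCREEN_PIXEL_AREA,
                              rng_seed = NULL) {
  if (switch_time_d <= germination_time_d) {
    abort("switch_time_d must exceed germination_time_d",
          class = "seedtrack_error_domain")
  }
  if (!is.null(rng_seed)) set.seed(rng_seed)
  a_switch <- linear_rate_mm2_d * (switch_time_d - germination_time_d)
  area <- ifelse(
    times_d <= germination_time_d, 0,
    ifelse(times_d <= switch_time_d,
           linear_rate_mm2_d * (times_d - germination_time_d),
           a_switch * exp(exp_rate_d * (times_d - switch_time_d)))
  )
  noisy <- area + ifelse(area > 0, rnorm(length(area), 0, noise_sd_mm2), 0)
  noisy[noisy < 0] <- 0
  green <- round(noisy / pixel_area)
  list(
    series = leaf_area_series(times_d, green, pixel_area),
    truth = tibble(
      germination_time_d = germination_time_d,
      linear_rate_mm2_d = linear_rate_mm2_d,
      switch_time_d = switch_time_d,
      exp_rate_d = exp_rate_d,
      noise_sd_mm2 = noise_sd_mm2
    )
  )
}
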