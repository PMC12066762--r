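#' Segment a single seed in a top-view RGB image
#'
#' At the 2D imaging station a single seed lies on a bright glass plate.
#' The seed is segmented by thresholding the HSV value channel (Otsu by
#' default), keeping the largest connected component and filling holes.
#' A plausibility flag (not a rejection) marks areas outside the typical
#' Arabidopsis range of 0.05-0.5 mm^2.
#'
#' @param image RGB array in `[0, 1]`.
#' @param pixel_size Pixel size in um/px.
#' @param threshold Optional value-channel threshold; darker is seed.
#' @return Logical matrix with attributes `pixel_size`, `area_px`,
#'   `area_mm2` and `plausible`.
#' @export
segment_seed_2d <- function(image, pixel_size, threshold = NULL) {
  stopifnot(length(dim(image)) == 3)
  v <- image_hsv(image)$v
  thr <- threshold %||% otsu_threshold(v)
  mask <- v < thr
  ## a seed occupies a minority of the frame; a majority "foreground"
  ## means the frame is blank or the lighting is unusable
  if (mean(mask) > 0.5) mask[] <- FALSE
  n_big <- n_large_components(mask, frac = 0.25)
  if (n_big != 1) {
    abort(sprintf("expected exactly 1 seed, found %d", n_big),
          class = "seedtrack_error_count_mismatch", n_components = n_big)
  }
  out <- largest_component(mask)
  area_mm2 <- sum(out) * (pixel_size / 1000)^2
  attr(out, "pixel_size") <- pixel_size
  attr(out, "area_px") <- sum(out)
  attr(out, "area_mm2") <- area_mm2
  attr(out, "plausible") <- area_mm2 >= 0.05 && area_mm2 <= 0.5
  if (!attr(out, "plausible")) {
    warn(sprintf("segmented area %.3g mm^2 is outside the plausible seed range",
                 area_mm2))
  }
  out
}

#' Colour and area traits of a segmented seed
#'
#' Seed brightness is the mean of the HSV value channel over a small
#' patch (default 5 x 5 px) centred on the mask centroid; using a central
#' cut-out rather than the whole mask retains surface brightness
#' variation while excluding the darker pixels at the seed edge. The
#' standard deviation over the same patch, mean hue and mean saturation
#' (patch-wise) and the projected area of the mask are reported alongside.
#'
#' @param image RGB array in `[0, 1]`.
#' @param mask Logical seed mask, e.g. from [segment_seed_2d()].
#' @param pixel_size Pixel size in um/px.
#' @param patch Patch edge length in pixels (odd; default 5).
#' @return One-row tibble: `projected_area_mm2`, `brightness_mean_pct`,
#'   `brightness_sd_pct`, `hue_mean_deg`, `saturation_mean_pct`,
#'   `edge_flag` (`TRUE` when the patch had to be shrunk or leaves the
#'   mask).
#' @export
color_traits <- function(image, mask, pixel_size, patch = 5) {
  stopifnot(length(dim(image)) == 3, is.logical(mask))
  if (!any(mask)) abort("empty mask", class = "seedtrack_error_count_mismatch")
  hsv <- image_hsv(image)
  idx <- which(mask, arr.ind = TRUE)
  cr <- round(mean(idx[, 1]))
  cc <- round(mean(idx[, 2]))

  half <- (patch - 1) / 2
  edge_flag <- FALSE
  ## distance from centroid to the mask boundary along rows/cols
  repeat {
    rows <- (cr - half):(cr + half)
    cols <- (cc - half):(cc + half)
    ok <- all(rows >= 1) && all(rows <= nrow(mask)) &&
      all(cols >= 1) && all(cols <= ncol(mask)) && all(mask[rows, cols])
    if (ok || half == 0) break
    half <- half - 1
    edge_flag <- TRUE
  }
  if (!all(mask[rows, cols])) edge_flag <- TRUE
  if (edge_flag) warn("centre patch shrunk or extends beyond the seed mask")

  v <- hsv$v[rows, cols]
  tibble(
    projected_area_mm2 = sum(mask) * (pixel_size / 1000)^2,
    brightness_mean_pct = mean(v) * 100,
    brightness_sd_pct = sd_or_zero(as.vector(v)) * 100,
    hue_mean_deg = mean(hsv$h[rows, cols]),
    saturation_mean_pct = mean(hsv$s[rows, cols]) * 100,
    edge_flag = edge_flag
  )
}

sd_or_zero <- function(x) if (length(x) < 2) 0 else sd(x)

#' Fit the mass-from-projected-area power model
#'
#' Projected seed area is a 2D quantity, so mass is modelled as
#' `mass = a * area^(3/2)`: the 3/2 exponent restores the missing third
#' dimension under geometric similarity. The single coefficient `a` is
#' fitted by least squares; per-seed relative deviations quantify how
#' poor a mass proxy the projected area remains for individual seeds.
#'
#' @param data Data frame with the area and mass columns, or `NULL` when
#'   `areas`/`masses` vectors are given directly.
#' @param areas,masses Column names (tidy-selected, when `data` is given)
#'   or numeric vectors: projected areas (mm^2) and masses (ug).
#' @return Object of class `mass_area_fit`: list with `a`, `fitted`,
#'   `rel_dev`, `max_rel_dev`, `n`, `data`. Has [tidy()], [glance()] and
#'   [autoplot()] methods.
#' @export
fit_mass_area_model <- function(data = NULL, areas = "projected_area_mm2",
                                masses = "mass_ug") {
  if (is.data.frame(data)) {
    A <- data[[areas]]
    y <- data[[masses]]
  } else {
    A <- areas
    y <- masses
  }
  if (length(A) < 3 || length(A) != length(y)) {
    abort("need at least 3 paired observations", class = "seedtrack_error_domain")
  }
  if (any(!is.finite(A)) || any(!is.finite(y)) || any(A <= 0) || any(y <= 0)) {
    abort("areas and masses must be positive and finite",
          class = "seedtrack_error_domain")
  }
  x <- A^1.5
  a <- sum(x * y) / sum(x^2)
  fitted <- a * x
  rel_dev <- abs(fitted - y) / y
  structure(
    list(a = a, fitted = fitted, rel_dev = rel_dev,
         max_rel_dev = max(rel_dev), n = length(y),
         data = tibble(area_mm2 = A, mass_ug = y)),
    class = "mass_area_fit"
  )
}

#' @export
print.mass_area_fit <- function(x, ...) {
  cat(sprintf("<mass_area_fit> mass = %.4g * area^(3/2), n = %d, max rel. deviation %.1f%%\n",
              x$a, x$n, 100 * x$max_rel_dev))
  invisible(x)
}

#' @rdname fit_mass_area_model
#' @param x,object A `mass_area_fit`.
#' @param ... Unused.
#' @export
tidy.mass_area_fit <- function(x, ...) {
  tibble(term = "a", estimate = x$a)
}

#' @rdname fit_mass_area_model
#' @export
glance.mass_area_fit <- function(x, ...) {
  tibble(a = x$a, n = x$n, max_rel_dev = x$max_rel_dev,
         mean_rel_dev = mean(x$rel_dev))
}

#' @rdname fit_mass_area_model
#' @export
autoplot.mass_area_fit <- function(object, ...) {
  grid <- tibble(
    area_mm2 = seq(min(object$data$area_mm2), max(object$data$area_mm2),
                   length.out = 100)
  )
  grid$mass_ug <- object$a * grid$area_mm2^1.5
  ggplot2::ggplot(object$data, ggplot2::aes(.data$area_mm2, .data$mass_ug)) +
    ggplot2::geom_point(alpha = 0.6) +
    ggplot2::geom_line(data = grid, colour = "red") +
    ggplot2::labs(x = "projected area [mm²]", y = "seed mass [µg]",
                  title = sprintf("mass = %.3g · area^(3/2)", object$a))
}
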