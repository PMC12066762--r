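#' Render a synthetic top-view seed image
#'
#' A brown elliptical seed on a bright background, as seen at the 2D
#' imaging station. The seed's HSV value channel is uniform over an inner
#' core (so the central 5 x 5 px brightness patch has a known mean) and
#' darkens toward the rim, mimicking the edge shading of real seed
#' images.
#'
#' @param semi_axes_mm In-plane semi-axes (a, b) of the seed outline, mm.
#' @param brightness_pct HSV value of the seed core, percent.
#' @param pixel_size_um Pixel size in um/px (default 16, i.e. a 5 x 5
#'   patch covers about 80 x 80 um).
#' @param frame_px Square frame size (default fits the seed with margin).
#' @param hue_deg,saturation Seed colour (testa brown by default).
#' @param background Background value-channel level.
#' @param angle_deg In-plane rotation of the outline.
#' @return List: `image` (H x W x 3 array), `truth` (tibble with the
#'   rendered area in px and mm^2 and the core brightness).
#' @export
make_seed_image <- function(semi_axes_mm = c(0.25, 0.155),
                            brightness_pct = 38.4,
                            pixel_size_um = 16, frame_px = NULL,
                            hue_deg = 30, saturation = 0.75,
                            background = 0.95, angle_deg = 0) {
  semi_px <- semi_axes_mm * 1000 / pixel_size_um
  if (is.null(frame_px)) frame_px <- 2 * ceiling(max(semi_px)) + 12
  H <- W <- frame_px
  cr <- (H + 1) / 2; cc <- (W + 1) / 2
  rows <- matrix(seq_len(H), H, W)
  cols <- matrix(seq_len(W), H, W, byrow = TRUE)
  th <- angle_deg * pi / 180
  xr <- (cols - cc) * cos(th) + (rows - cr) * sin(th)
  yr <- -(cols - cc) * sin(th) + (rows - cr) * cos(th)
  rho2 <- (xr / semi_px[1])^2 + (yr / semi_px[2])^2
  inside <- rho2 <= 1

  v <- matrix(background, H, W)
  core_v <- brightness_pct / 100
  ## uniform core, linear darkening over the outer 30% of the radius
  rim <- sqrt(pmax(rho2, 0))
  shade <- pmax(0, (rim - 0.7) / 0.3)
  v[inside] <- core_v * (1 - 0.5 * shade[inside])
  s <- matrix(0.02, H, W)
  s[inside] <- saturation
  h <- matrix(hue_deg, H, W)

  img <- array(0, c(H, W, 3))
  rgb <- grDevices::hsv(h / 360, s, pmin(pmax(v, 0), 1))
  rgbm <- grDevices::col2rgb(rgb) / 255
  img[, , 1] <- matrix(rgbm[1, ], H, W)
  img[, , 2] <- matrix(rgbm[2, ], H, W)
  img[, , 3] <- matrix(rgbm[3, ], H, W)

  list(
    image = img,
    truth = tibble(
      area_px = sum(inside),
      area_mm2 = sum(inside) * (pixel_size_um / 1000)^2,
      brightness_pct = brightness_pct,
      analytic_area_mm2 = pi * prod(semi_axes_mm)
    )
  )
}
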