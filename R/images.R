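## Shared raster helpers. Images are plain R arrays indexed [row, col] or
## [row, col, channel], values in [0, 1]; row 1 is the top of the frame.

#' Read and write RGB/greyscale images
#'
#' Thin wrappers around [png::readPNG()] / [png::writePNG()] that keep the
#' package's array convention: `[row, col]` for greyscale, `[row, col, 3]`
#' for RGB, values in `[0, 1]`.
#'
#' @param path File path of a PNG image.
#' @param image Numeric array in `[0, 1]`.
#' @return `read_image()` returns a numeric array; `write_image()` returns
#'   `path` invisibly.
#' @export
read_image <- function(path) {
  img <- png::readPNG(path)
  if (length(dim(img)) == 3 && dim(img)[3] == 4) img <- img[, , 1:3] # drop alpha
  img
}

#' @rdname read_image
#' @export
write_image <- function(image, path) {
  image[image < 0] <- 0
  image[image > 1] <- 1
  png::writePNG(image, path)
  invisible(path)
}

## Greyscale view of an image (luminance for RGB input).
as_grey <- function(image) {
  if (length(dim(image)) == 2) return(image)
  0.299 * image[, , 1] + 0.587 * image[, , 2] + 0.114 * image[, , 3]
}

## Per-pixel HSV channels of an RGB array.
## Returns list(h, s, v): h in degrees [0, 360), s and v in [0, 1].
image_hsv <- function(image) {
  stopifnot(length(dim(image)) == 3)
  d <- dim(image)
  hsv <- grDevices::rgb2hsv(
    r = as.vector(image[, , 1]),
    g = as.vector(image[, , 2]),
    b = as.vector(image[, , 3]),
    maxColorValue = 1
  )
  list(
    h = matrix(hsv[1, ] * 360, d[1], d[2]),
    s = matrix(hsv[2, ], d[1], d[2]),
    v = matrix(hsv[3, ], d[1], d[2])
  )
}

## Connected-component bookkeeping on a logical mask.
## Returns list(labels = integer matrix, sizes = named sizes sorted desc).
label_components <- function(mask) {
  labels <- EBImage::bwlabel(mask * 1)
  lab <- as.integer(labels)
  lab <- lab[lab > 0]
  sizes <- if (length(lab)) tabulate(lab) else integer(0)
  list(labels = labels, sizes = sizes)
}

## Keep the largest connected component of a logical mask and fill holes.
largest_component <- function(mask, fill_holes = TRUE) {
  cc <- label_components(mask)
  if (length(cc$sizes) == 0) return(mask & FALSE)
  keep <- which.max(cc$sizes)
  out <- cc$labels == keep
  if (fill_holes) out <- EBImage::fillHull(out * 1) > 0
  out
}

## Count components at least `frac` the size of the largest one.
n_large_components <- function(mask, frac = 0.05) {
  cc <- label_components(mask)
  if (length(cc$sizes) == 0) return(0L)
  sum(cc$sizes >= frac * max(cc$sizes))
}

## Otsu threshold of a grey matrix in [0, 1].
otsu_threshold <- function(grey) {
  EBImage::otsu(grey, range = c(0, 1))
}

## Separable mean filter (box) over a matrix, edge-padded.
box_filter <- function(m, width) {
  width <- max(1L, as.integer(width))
  if (width %% 2 == 0) width <- width + 1L
  k <- rep(1 / width, width)
  run <- function(x) {
    out <- stats::filter(x, k, sides = 2)
    out[is.na(out)] <- 0
    as.numeric(out)
  }
  m2 <- apply(m, 2, run)
  t(apply(t(m2), 2, run))
}
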