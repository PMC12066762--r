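#' Build a calibrated silhouette stack
#'
#' A silhouette stack holds the binary seed masks of one rotation series at
#' the 3D imaging station, together with the calibration needed to carve
#' them into a voxel hull: the per-view rotation angle, the physical pixel
#' size, the image column of the (vertical) rotation axis, and optionally
#' the image row above which the seed is hidden inside the pick-up nozzle.
#'
#' The physical frame used throughout the 3D module is: `z` (vertical,
#' in micrometres) increases upward, with `z = (nrow - row + 0.5) *
#' pixel_size` for image row `row`; the in-view horizontal coordinate `u`
#' is measured from the rotation-axis column, `u = (col - rotation_axis) *
#' pixel_size`.
#'
#' @param masks List of logical matrices (seed = `TRUE`), all the same size.
#' @param angles Numeric vector of rotation angles in degrees, strictly
#'   increasing, within `[0, 360)`. One per mask.
#' @param pixel_size Physical pixel size in micrometres per pixel.
#' @param rotation_axis Image column of the rotation axis. Defaults to the
#'   median silhouette centroid column across views, which is unbiased for
#'   a full rotation series.
#' @param occlusion_row Optional image row; rows strictly above it carry no
#'   silhouette information because the seed is hidden by the nozzle.
#' @return An object of class `silhouette_stack`.
#' @export
silhouette_stack <- function(masks, angles, pixel_size,
                             rotation_axis = NULL, occlusion_row = NULL) {
  if (!is.list(masks) || length(masks) < 2) {
    abort("a silhouette stack needs at least 2 views", class = "seedtrack_error_stack")
  }
  dims <- vapply(masks, dim, integer(2))
  if (any(dims[1, ] != dims[1, 1]) || any(dims[2, ] != dims[2, 1])) {
    abort("all masks must have identical dimensions", class = "seedtrack_error_stack")
  }
  if (length(angles) != length(masks)) {
    abort("one angle per mask is required", class = "seedtrack_error_stack")
  }
  if (any(diff(angles) <= 0) || any(angles < 0) || any(angles >= 360)) {
    abort("angles must be strictly increasing within [0, 360)",
          class = "seedtrack_error_stack")
  }
  if (!is.numeric(pixel_size) || pixel_size <= 0) {
    abort("pixel_size must be a positive number of um/px",
          class = "seedtrack_error_stack")
  }
  masks <- lapply(masks, function(m) {
    storage.mode(m) <- "logical"
    m
  })
  if (is.null(rotation_axis)) {
    cents <- vapply(masks, function(m) {
      cs <- colSums(m)
      if (sum(cs) == 0) return(NA_real_)
      sum(cs * seq_along(cs)) / sum(cs)
    }, numeric(1))
    rotation_axis <- median(cents, na.rm = TRUE)
  }
  structure(
    list(masks = masks, angles = as.numeric(angles), pixel_size = pixel_size,
         rotation_axis = rotation_axis, occlusion_row = occlusion_row),
    class = "silhouette_stack"
  )
}

#' @export
print.silhouette_stack <- function(x, ...) {
  d <- dim(x$masks[[1]])
  cat(sprintf(
    "<silhouette_stack> %d views of %d x %d px at %.3g um/px, axis col %.1f%s\n",
    length(x$masks), d[1], d[2], x$pixel_size, x$rotation_axis,
    if (is.null(x$occlusion_row)) "" else sprintf(", occluded above row %d",
                                                  x$occlusion_row)
  ))
  invisible(x)
}

## z (um) of image row centres, and the inverse.
row_to_z <- function(row, n_row, pixel_size) (n_row - row + 0.5) * pixel_size
z_to_row <- function(z, n_row, pixel_size) n_row - z / pixel_size + 0.5

#' Segment a backlit seed silhouette
#'
#' At the 3D station the seed hangs in front of a bright backlight, so the
#' seed is the dark object in the frame. Thresholding (Otsu on the grey
#' image unless an explicit threshold is given) is followed by keeping the
#' single connected foreground component and filling holes.
#'
#' @param image Greyscale matrix or RGB array in `[0, 1]`.
#' @param pixel_size Pixel size in um/px (kept with the returned mask).
#' @param threshold Optional grey threshold; pixels strictly darker are
#'   foreground. Default: Otsu.
#' @return Logical matrix (seed = `TRUE`) with attributes `pixel_size` and
#'   `area_px`.
#' @export
segment_silhouette <- function(image, pixel_size, threshold = NULL) {
  grey <- as_grey(image)
  thr <- threshold %||% otsu_threshold(grey)
  mask <- grey < thr
  ## a near-uniform frame has no meaningful threshold: foreground must be
  ## a minority of a backlit view
  if (mean(mask) > 0.5) mask[] <- FALSE
  n_big <- n_large_components(mask, frac = 0.25)
  if (n_big == 0) {
    abort("empty view: no foreground component found",
          class = "seedtrack_error_empty_view")
  }
  if (n_big > 1) {
    abort(sprintf("ambiguous view: %d large foreground components", n_big),
          class = "seedtrack_error_ambiguous", n_components = n_big)
  }
  out <- largest_component(mask)
  attr(out, "pixel_size") <- pixel_size
  attr(out, "area_px") <- sum(out)
  out
}

#' Read and write silhouette stacks on disk
#'
#' A stack directory holds one PNG per view (`view_001.png`, ...) plus a
#' `stack.json` sidecar with `angles`, `pixel_size`, `rotation_axis` and
#' optionally `occlusion_row`.
#'
#' @param stack A `silhouette_stack`.
#' @param dir Directory to write to / read from.
#' @return `read_silhouette_stack()` returns a `silhouette_stack`;
#'   `write_silhouette_stack()` returns `dir` invisibly.
#' @export
write_silhouette_stack <- function(stack, dir) {
  stopifnot(inherits(stack, "silhouette_stack"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  for (i in seq_along(stack$masks)) {
    write_image(stack$masks[[i]] * 1, file.path(dir, sprintf("view_%03d.png", i)))
  }
  meta <- list(angles = stack$angles, pixel_size = stack$pixel_size,
               rotation_axis = stack$rotation_axis)
  if (!is.null(stack$occlusion_row)) meta$occlusion_row <- stack$occlusion_row
  jsonlite::write_json(meta, file.path(dir, "stack.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}

#' @rdname write_silhouette_stack
#' @export
read_silhouette_stack <- function(dir) {
  meta <- jsonlite::read_json(file.path(dir, "stack.json"), simplifyVector = TRUE)
  files <- sort(list.files(dir, pattern = "^view_\\d+\\.png$", full.names = TRUE))
  masks <- lapply(files, function(f) as_grey(read_image(f)) > 0.5)
  silhouette_stack(masks, meta$angles, meta$pixel_size,
                   rotation_axis = meta$rotation_axis,
                   occlusion_row = meta$occlusion_row)
}
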