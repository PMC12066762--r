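#' Voxel hull container
#'
#' A `voxel_hull` is a 3D logical occupancy grid with a physical voxel
#' size (um) and the physical coordinates (um) of the centre of voxel
#' `[1, 1, 1]`. Axis 1 is x, axis 2 is y, axis 3 is z (vertical, upward).
#'
#' @param occupancy Logical 3D array.
#' @param voxel_size Edge length of one voxel in micrometres.
#' @param origin Numeric length-3: physical (x, y, z) of the first voxel
#'   centre, in micrometres.
#' @return An object of class `voxel_hull`.
#' @export
voxel_hull <- function(occupancy, voxel_size, origin = c(0, 0, 0)) {
  stopifnot(is.array(occupancy), length(dim(occupancy)) == 3, voxel_size > 0)
  storage.mode(occupancy) <- "logical"
  structure(list(occupancy = occupancy, voxel_size = voxel_size,
                 origin = as.numeric(origin)),
            class = "voxel_hull")
}

#' @export
print.voxel_hull <- function(x, ...) {
  d <- dim(x$occupancy)
  cat(sprintf("<voxel_hull> %d x %d x %d grid at %.3g um, %d occupied (%.3g nl)\n",
              d[1], d[2], d[3], x$voxel_size, sum(x$occupancy), hull_volume(x)))
  invisible(x)
}

## Physical voxel-centre coordinates along each axis, in um.
hull_axes <- function(hull) {
  d <- dim(hull$occupancy)
  list(x = hull$origin[1] + (seq_len(d[1]) - 1) * hull$voxel_size,
       y = hull$origin[2] + (seq_len(d[2]) - 1) * hull$voxel_size,
       z = hull$origin[3] + (seq_len(d[3]) - 1) * hull$voxel_size)
}

#' Hull volume in nanolitres
#'
#' Occupied voxel count times voxel volume. 1 nl = 1e6 um^3.
#'
#' @param hull A `voxel_hull`.
#' @return Volume in nl.
#' @export
hull_volume <- function(hull) {
  sum(hull$occupancy) * hull$voxel_size^3 / 1e6
}

#' Carve a voxel hull from a silhouette stack
#'
#' Space carving under an orthographic projection model: a voxel stays
#' occupied iff its centre projects inside the silhouette in *every* view.
#' The result is (a voxelization of) the visual hull, the largest shape
#' consistent with all silhouettes; it always contains the imaged object,
#' so the carved volume is an upper estimate that tightens as the angular
#' sampling and voxel resolution increase.
#'
#' The projection of a point `(x, y, z)` into the view at angle `theta` is
#' `u = x cos(theta) + y sin(theta)` (horizontal, um from the rotation
#' axis) at height `z`.
#'
#' @param stack A [silhouette_stack()].
#' @param voxel_size Voxel edge in um (default 5).
#' @return A [voxel_hull()] whose `origin` is expressed in the stack's
#'   physical frame (x and y measured from the rotation axis, z from the
#'   bottom edge of the frame).
#' @export
carve_hull <- function(stack, voxel_size = 5) {
  stopifnot(inherits(stack, "silhouette_stack"))
  H <- nrow(stack$masks[[1]]); W <- ncol(stack$masks[[1]])
  px <- stack$pixel_size

  any_mask <- Reduce(`|`, stack$masks)
  if (!any(any_mask)) {
    abort("carve failure: all views are empty", class = "seedtrack_error_carve")
  }
  rows_used <- which(rowSums(any_mask) > 0)
  cols_used <- which(colSums(any_mask) > 0)
  u_max <- max(abs((cols_used - stack$rotation_axis) * px)) + 2 * voxel_size
  z_lo <- row_to_z(max(rows_used), H, px) - 2 * voxel_size
  z_hi <- row_to_z(min(rows_used), H, px) + 2 * voxel_size

  xs <- seq(-u_max, u_max, by = voxel_size)
  zs <- seq(z_lo, z_hi, by = voxel_size)
  nx <- length(xs); nz <- length(zs)

  short_axis_px <- min(length(rows_used), length(cols_used)) * px
  if (short_axis_px / voxel_size < 20) {
    warn(sprintf(
      "voxel_size %.3g um spans the seed's short axis with < 20 voxels; consider a finer grid",
      voxel_size))
  }

  xy <- cbind(rep(xs, times = nx), rep(xs, each = nx)) # (x, y) pairs, x fastest
  occ <- matrix(TRUE, nx * nx, nz)
  rows_of_z <- round(z_to_row(zs, H, px))
  z_ok <- rows_of_z >= 1 & rows_of_z <= H
  occ[, !z_ok] <- FALSE

  for (i in seq_along(stack$angles)) {
    th <- stack$angles[i] * pi / 180
    u <- xy[, 1] * cos(th) + xy[, 2] * sin(th)
    col_i <- round(stack$rotation_axis + u / px)
    in_frame <- col_i >= 1 & col_i <= W
    m <- stack$masks[[i]]
    for (k in which(z_ok)) {
      if (!any(occ[, k])) next
      v <- logical(nx * nx)
      v[in_frame] <- m[rows_of_z[k] + (col_i[in_frame] - 1) * H]
      occ[, k] <- occ[, k] & v
    }
  }

  if (!any(occ)) {
    abort("carve failure: silhouettes have an empty intersection",
          class = "seedtrack_error_carve")
  }
  hull <- voxel_hull(array(occ, c(nx, nx, nz)), voxel_size,
                     origin = c(xs[1], xs[1], zs[1]))
  hull$pixel_size <- px
  hull$frame_dim <- c(H, W)
  hull$rotation_axis <- stack$rotation_axis
  if (!is.null(stack$occlusion_row)) {
    ## plane sits at the top edge of the first visible row
    hull$occlusion_z <- row_to_z(stack$occlusion_row, H, px) + px / 2
  }
  hull
}

#' Project a voxel hull back into a view
#'
#' Orthographic re-projection of all occupied voxel centres into the image
#' frame of a silhouette stack at one view angle. By construction of
#' [carve_hull()] the returned mask is a subset of that view's silhouette;
#' this is the re-projection containment property of the visual hull.
#'
#' @param hull A `voxel_hull` produced by [carve_hull()].
#' @param angle View angle in degrees.
#' @return Logical matrix with the dimensions of the stack's frames.
#' @export
project_hull <- function(hull, angle) {
  if (is.null(hull$frame_dim)) {
    abort("hull carries no camera frame; carve it from a silhouette_stack first")
  }
  H <- hull$frame_dim[1]; W <- hull$frame_dim[2]
  ax <- hull_axes(hull)
  idx <- which(hull$occupancy, arr.ind = TRUE)
  x <- ax$x[idx[, 1]]; y <- ax$y[idx[, 2]]; z <- ax$z[idx[, 3]]
  th <- angle * pi / 180
  u <- x * cos(th) + y * sin(th)
  col_i <- round(hull$rotation_axis + u / hull$pixel_size)
  row_i <- round(z_to_row(z, H, hull$pixel_size))
  keep <- col_i >= 1 & col_i <= W & row_i >= 1 & row_i <= H
  out <- matrix(FALSE, H, W)
  out[cbind(row_i[keep], col_i[keep])] <- TRUE
  out
}

## Logical array of occupied voxels having at least one empty 6-neighbour
## (or lying on the grid boundary).
surface_voxels <- function(occ) {
  d <- dim(occ)
  shift <- function(a, s, dim) {
    idx <- lapply(d, seq_len)
    idx[[dim]] <- pmin(pmax(idx[[dim]] + s, 1L), d[dim])
    out <- a[idx[[1]], idx[[2]], idx[[3]], drop = FALSE]
    ## grid boundary counts as empty neighbourhood
    if (s == 1) {
      switch(dim, out[d[1], , ] <- FALSE, out[, d[2], ] <- FALSE, out[, , d[3]] <- FALSE)
    } else {
      switch(dim, out[1, , ] <- FALSE, out[, 1, ] <- FALSE, out[, , 1] <- FALSE)
    }
    out
  }
  interior <- shift(occ, 1L, 1L) & shift(occ, -1L, 1L) &
    shift(occ, 1L, 2L) & shift(occ, -1L, 2L) &
    shift(occ, 1L, 3L) & shift(occ, -1L, 3L)
  occ & !interior
}

#' Export a hull surface as an ASCII PLY point cloud
#'
#' Writes the surface voxel centres (in mm) as PLY vertices, readable by
#' standard mesh viewers.
#'
#' @param hull A [voxel_hull()].
#' @param path Output `.ply` path.
#' @return `path`, invisibly.
#' @export
write_hull_ply <- function(hull, path) {
  P <- surface_points(hull) / 1000
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("ply", "format ascii 1.0",
               sprintf("element vertex %d", nrow(P)),
               "property float x", "property float y", "property float z",
               "end_header"), con)
  writeLines(sprintf("%.6f %.6f %.6f", P[, 1], P[, 2], P[, 3]), con)
  invisible(path)
}

## Physical coordinates (um) of surface voxel centres, one row per voxel.
surface_points <- function(hull) {
  ax <- hull_axes(hull)
  idx <- which(surface_voxels(hull$occupancy), arr.ind = TRUE)
  cbind(x = ax$x[idx[, 1]], y = ax$y[idx[, 2]], z = ax$z[idx[, 3]])
}
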