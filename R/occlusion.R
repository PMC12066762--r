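#' Extrapolate the seed cap hidden inside the nozzle
#'
#' During 3D imaging the seed hangs from a vacuum nozzle, so its top is
#' occluded in every view and the carved hull is cut off by a horizontal
#' plane, biasing the volume low. This routine reduces that
#' underestimation by fitting a general ellipsoid (a bounded quadric) by
#' least squares to the hull surface below the occlusion plane and adding
#' the fitted ellipsoid's voxels above the plane.
#'
#' Surface voxels within `band_voxels` of the plane are excluded from the
#' fit because they trace the artificial flat cut, not the seed surface.
#' Added voxels are clipped to the xy-footprint of the contact
#' cross-section (dilated by one voxel), which for any convex seed bounds
#' the true cap and guarantees the added volume never exceeds the cylinder
#' spanned by the contact cross-section.
#'
#' @param hull A [voxel_hull()] truncated from above, e.g. carved from a
#'   stack with `occlusion_row` set.
#' @param occlusion_z Physical z (um) of the occlusion plane. Defaults to
#'   the value recorded by [carve_hull()]; when neither is available the
#'   hull is treated as complete and returned unchanged.
#' @param band_voxels Surface layers below the plane excluded from the fit.
#' @return A [voxel_hull()] containing the input hull plus the
#'   extrapolated cap; attribute `cap_nl` records the added volume. If the
#'   hull shows no occupied voxels near the plane the input is returned
#'   unchanged with a warning.
#' @export
extrapolate_occluded_cap <- function(hull, occlusion_z = NULL, band_voxels = 3) {
  stopifnot(inherits(hull, "voxel_hull"))
  vx <- hull$voxel_size
  ax <- hull_axes(hull)
  occlusion_z <- occlusion_z %||% hull$occlusion_z
  if (is.null(occlusion_z)) {
    ## nothing was occluded: the hull is already complete
    out <- hull
    attr(out, "cap_nl") <- 0
    return(out)
  }

  z_top_occ <- max(ax$z[apply(hull$occupancy, 3, any)])
  if (z_top_occ > occlusion_z + vx / 2) {
    abort("hull has occupied voxels above the stated occlusion plane",
          class = "seedtrack_error_occlusion")
  }
  near <- z_top_occ >= occlusion_z - band_voxels * vx
  if (!near) {
    warn("no occupied voxels near the occlusion plane; nothing to extrapolate")
    out <- hull
    attr(out, "cap_nl") <- 0
    return(out)
  }

  P <- surface_points(hull)
  fitp <- P[P[, 3] < occlusion_z - band_voxels * vx, , drop = FALSE]
  if (nrow(fitp) < 20) {
    warn("too few surface points below the occlusion plane; nothing to extrapolate")
    out <- hull
    attr(out, "cap_nl") <- 0
    return(out)
  }

  ## algebraic least-squares quadric; coordinates centred on the point
  ## cloud and expressed in mm for conditioning
  mu <- colMeans(fitp)
  Pm <- sweep(fitp, 2, mu) / 1000
  X <- cbind(Pm[, 1]^2, Pm[, 2]^2, Pm[, 3]^2,
             Pm[, 1] * Pm[, 2], Pm[, 1] * Pm[, 3], Pm[, 2] * Pm[, 3],
             Pm[, 1], Pm[, 2], Pm[, 3])
  b <- tryCatch(qr.solve(X, rep(1, nrow(X))), error = function(e) NULL)
  A <- if (is.null(b)) NULL else
    matrix(c(b[1], b[4] / 2, b[5] / 2,
             b[4] / 2, b[2], b[6] / 2,
             b[5] / 2, b[6] / 2, b[3]), 3, 3)
  if (is.null(b) || any(eigen(A, symmetric = TRUE, only.values = TRUE)$values <= 0)) {
    warn("quadric fit is not a bounded ellipsoid; cap not extrapolated")
    out <- hull
    attr(out, "cap_nl") <- 0
    return(out)
  }

  ## extend the grid upward far enough to hold any plausible cap
  height <- occlusion_z - min(ax$z[apply(hull$occupancy, 3, any)])
  n_extra <- ceiling((height + 2 * vx) / vx)
  d <- dim(hull$occupancy)
  occ_new <- array(FALSE, d + c(0, 0, n_extra))
  occ_new[, , seq_len(d[3])] <- hull$occupancy
  zs_new <- hull$origin[3] + (seq_len(d[3] + n_extra) - 1) * vx

  ## xy footprint of the contact cross-section, dilated by one voxel
  top_layers <- which(zs_new <= occlusion_z & zs_new > occlusion_z - (band_voxels + 1) * vx)
  top_layers <- top_layers[top_layers <= d[3]]
  fp <- apply(hull$occupancy[, , top_layers, drop = FALSE], c(1, 2), any)
  fp_d <- fp
  fp_d[-1, ] <- fp_d[-1, ] | fp[-nrow(fp), ]
  fp_d[-nrow(fp), ] <- fp_d[-nrow(fp), ] | fp[-1, ]
  fp_d[, -1] <- fp_d[, -1] | fp[, -ncol(fp)]
  fp_d[, -ncol(fp)] <- fp_d[, -ncol(fp)] | fp[, -1]

  above <- which(zs_new > occlusion_z - vx / 2)
  q_of <- function(x, y, z) {
    b[1] * x^2 + b[2] * y^2 + b[3] * z^2 + b[4] * x * y + b[5] * x * z +
      b[6] * y * z + b[7] * x + b[8] * y + b[9] * z
  }
  xg <- matrix((ax$x - mu[1]) / 1000, d[1], d[2])
  yg <- matrix((ax$y - mu[2]) / 1000, d[1], d[2], byrow = TRUE)
  added <- 0L
  for (k in above) {
    zmm <- (zs_new[k] - mu[3]) / 1000
    inside <- q_of(xg, yg, zmm) <= 1 & fp_d & !occ_new[, , k]
    occ_new[, , k] <- occ_new[, , k] | inside
    added <- added + sum(inside)
  }

  out <- voxel_hull(occ_new, vx, hull$origin)
  out$pixel_size <- hull$pixel_size
  out$frame_dim <- hull$frame_dim
  out$rotation_axis <- hull$rotation_axis
  attr(out, "cap_nl") <- added * vx^3 / 1e6
  out
}
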