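## Synthetic seed-like solids with analytic ground truth, rendered into
## rotation-series silhouettes. These are the oracles for the carving and
## morphometrics code: every generated stack is returned together with
## the exact volume, surface area, length/width/height and sphericity of
## the generating solid.

#' Specify a synthetic seed-like solid
#'
#' Supported solids are the sphere, the triaxial ellipsoid and the
#' superellipsoid `|x/a|^n + |y/b|^n + |z/c|^n <= 1` (n > 2 gives
#' blockier, more seed-like shapes). The solid can be rotated and a top
#' fraction of its height can be marked as occluded by the pick-up
#' nozzle.
#'
#' @param kind `"sphere"`, `"ellipsoid"` or `"superellipsoid"`.
#' @param semi_axes_mm Semi-axes (a, b, c) in mm; a single number for a
#'   sphere.
#' @param orientation Either a 3x3 rotation matrix or yaw/pitch/roll
#'   angles in degrees (intrinsic z-y-x).
#' @param occluded_fraction Fraction of the solid's height hidden by the
#'   nozzle, in `[0, 0.5]`.
#' @param exponent Superellipsoid exponent `n` (ignored otherwise).
#' @return Object of class `shape_spec`.
#' @export
shape_spec <- function(kind = c("sphere", "ellipsoid", "superellipsoid"),
                       semi_axes_mm, orientation = c(0, 0, 0),
                       occluded_fraction = 0, exponent = 4) {
  kind <- match.arg(kind)
  if (kind == "sphere") semi_axes_mm <- rep(semi_axes_mm[1], 3)
  if (length(semi_axes_mm) != 3 || any(semi_axes_mm <= 0)) {
    abort("semi_axes_mm must be 3 positive numbers", class = "seedtrack_error_domain")
  }
  if (occluded_fraction < 0 || occluded_fraction > 0.5) {
    abort("occluded_fraction must be in [0, 0.5]", class = "seedtrack_error_domain")
  }
  R <- if (is.matrix(orientation)) orientation else rotation_matrix(orientation)
  n <- if (kind == "superellipsoid") exponent else 2
  structure(list(kind = kind, semi_axes_mm = semi_axes_mm, rotation = R,
                 occluded_fraction = occluded_fraction, exponent = n),
            class = "shape_spec")
}

## Intrinsic z-y-x rotation from yaw/pitch/roll in degrees.
rotation_matrix <- function(ypr) {
  a <- ypr * pi / 180
  Rz <- matrix(c(cos(a[1]), -sin(a[1]), 0, sin(a[1]), cos(a[1]), 0, 0, 0, 1),
               3, 3, byrow = TRUE)
  Ry <- matrix(c(cos(a[2]), 0, sin(a[2]), 0, 1, 0, -sin(a[2]), 0, cos(a[2])),
               3, 3, byrow = TRUE)
  Rx <- matrix(c(1, 0, 0, 0, cos(a[3]), -sin(a[3]), 0, sin(a[3]), cos(a[3])),
               3, 3, byrow = TRUE)
  Rz %*% Ry %*% Rx
}

#' Analytic morphometrics of a shape specification
#'
#' Volume is closed-form for all supported solids (for the
#' superellipsoid via gamma functions). Surface area is closed-form for
#' the sphere and computed by numerical quadrature of the parametric
#' surface otherwise. Length/width/height are orientation-independent:
#' `2(a, b, c)` sorted decreasingly for spheres and ellipsoids (the
#' longest chord of an ellipsoid is its major diameter and the shadow
#' orthogonal to it is spanned by the other two axes), and measured from
#' dense surface samples for superellipsoids.
#'
#' @param spec A [shape_spec()].
#' @return One-row tibble matching [measure_morphometrics()] columns.
#' @export
shape_truth <- function(spec) {
  s <- spec$semi_axes_mm
  n <- spec$exponent
  if (spec$kind %in% c("sphere", "ellipsoid")) {
    vol_mm3 <- 4 / 3 * pi * prod(s)
    area <- if (spec$kind == "sphere") 4 * pi * s[1]^2 else ellipsoid_area(s)
    lwh <- sort(2 * s, decreasing = TRUE)
  } else {
    vol_mm3 <- 8 * prod(s) * gamma(1 + 1 / n)^3 / gamma(1 + 3 / n)
    area <- superellipsoid_area(s, n)
    P <- superellipsoid_samples(s, n)
    lwh <- point_cloud_lwh(P)
  }
  tibble(
    volume_nl = vol_mm3 * 1e3,
    surface_area_mm2 = area,
    length_mm = lwh[1], width_mm = lwh[2], height_mm = lwh[3],
    sphericity_pct = 100 * pi^(1 / 3) * (6 * vol_mm3)^(2 / 3) / area
  )
}

## Parametric surface-area quadrature for the superellipsoid family
## (exponent 2 = ellipsoid). Midpoint rule on a fine (theta, phi) grid.
superellipsoid_area <- function(s, n, grid = 720) {
  e <- 2 / n
  spow <- function(x, p) sign(x) * abs(x)^p
  th <- seq(-pi / 2, pi / 2, length.out = grid + 1)
  ph <- seq(-pi, pi, length.out = 2 * grid + 1)
  thm <- (th[-1] + th[-length(th)]) / 2
  phm <- (ph[-1] + ph[-length(ph)]) / 2
  dth <- diff(th)[1]; dph <- diff(ph)[1]
  TH <- matrix(thm, length(thm), length(phm))
  PH <- matrix(phm, length(thm), length(phm), byrow = TRUE)
  X <- function(TH, PH) {
    list(x = s[1] * spow(cos(TH), e) * spow(cos(PH), e),
         y = s[2] * spow(cos(TH), e) * spow(sin(PH), e),
         z = s[3] * spow(sin(TH), e))
  }
  h <- 1e-5
  p0 <- X(TH, PH)
  pt <- X(TH + h, PH)
  pp <- X(TH, PH + h)
  du <- lapply(seq_along(p0), function(i) (pt[[i]] - p0[[i]]) / h)
  dv <- lapply(seq_along(p0), function(i) (pp[[i]] - p0[[i]]) / h)
  cx <- du[[2]] * dv[[3]] - du[[3]] * dv[[2]]
  cy <- du[[3]] * dv[[1]] - du[[1]] * dv[[3]]
  cz <- du[[1]] * dv[[2]] - du[[2]] * dv[[1]]
  sum(sqrt(cx^2 + cy^2 + cz^2)) * dth * dph
}

ellipsoid_area <- function(s) superellipsoid_area(s, 2)

## Dense body-frame surface samples of a superellipsoid.
superellipsoid_samples <- function(s, n, grid = 180) {
  e <- 2 / n
  spow <- function(x, p) sign(x) * abs(x)^p
  th <- seq(-pi / 2, pi / 2, length.out = grid)
  ph <- seq(-pi, pi, length.out = 2 * grid)
  TH <- rep(th, times = length(ph))
  PH <- rep(ph, each = length(th))
  cbind(s[1] * spow(cos(TH), e) * spow(cos(PH), e),
        s[2] * spow(cos(TH), e) * spow(sin(PH), e),
        s[3] * spow(sin(TH), e))
}

## Length/width/height of a dense point cloud (same definition as
## hull_lwh, but on exact surface samples; no voxel correction).
point_cloud_lwh <- function(P, n_dirs = 600) {
  D <- fibonacci_directions(n_dirs)
  proj <- P %*% t(D)
  ext <- unique(c(apply(proj, 2, which.max), apply(proj, 2, which.min)))
  Q <- P[ext, , drop = FALSE]
  dm <- as.matrix(stats::dist(Q))
  ij <- which(dm == max(dm), arr.ind = TRUE)[1, ]
  len <- max(dm)
  axis <- Q[ij[2], ] - Q[ij[1], ]
  axis <- axis / sqrt(sum(axis^2))
  b1 <- if (abs(axis[1]) < 0.9) c(1, 0, 0) else c(0, 1, 0)
  b1 <- b1 - sum(b1 * axis) * axis
  b1 <- b1 / sqrt(sum(b1^2))
  b2 <- c(axis[2] * b1[3] - axis[3] * b1[2],
          axis[3] * b1[1] - axis[1] * b1[3],
          axis[1] * b1[2] - axis[2] * b1[1])
  P2 <- cbind(P %*% b1, P %*% b2)
  hc <- grDevices::chull(P2)
  Q2 <- P2[hc, , drop = FALSE]
  dm2 <- as.matrix(stats::dist(Q2))
  ij2 <- which(dm2 == max(dm2), arr.ind = TRUE)[1, ]
  w1 <- max(dm2)
  waxis <- Q2[ij2[2], ] - Q2[ij2[1], ]
  waxis <- waxis / sqrt(sum(waxis^2))
  w2 <- diff(range(P2 %*% c(-waxis[2], waxis[1])))
  c(len, max(w1, w2), min(w1, w2))
}

#' Render the rotation-series silhouettes of a synthetic solid
#'
#' Orthographic binary projections of the solid at each turntable angle,
#' on the same geometry the carver assumes: vertical rotation axis at the
#' frame's centre column, `z` upward. A pixel is foreground iff its
#' centre lies inside the solid's projection (for spheres and ellipsoids
#' via the closed-form projected conic; for superellipsoids by ray
#' marching). With `occluded_fraction > 0` all masks are truncated above
#' the same image row, exactly as a nozzle-held seed would be.
#'
#' @param spec A [shape_spec()].
#' @param angles View angles in degrees (default 36 views at 10 deg).
#' @param pixel_size_um Pixel size in um/px.
#' @param frame_px Optional square frame size (default: fits the solid
#'   with a margin).
#' @return List with elements `stack` (a [silhouette_stack()]) and
#'   `truth` (from [shape_truth()], plus `occlusion_z_um` when occluded).
#' @export
render_silhouettes <- function(spec, angles = seq(0, 350, by = 10),
                               pixel_size_um = 5, frame_px = NULL) {
  stopifnot(inherits(spec, "shape_spec"))
  semi_um <- spec$semi_axes_mm * 1000
  r_max <- sqrt(sum(semi_um^2))
  if (is.null(frame_px)) frame_px <- 2 * ceiling(r_max / pixel_size_um) + 16
  H <- W <- frame_px
  if (2 * max(semi_um) / pixel_size_um > frame_px - 2) {
    abort("shape does not fit in the frame", class = "seedtrack_error_frame")
  }
  axis_col <- (W + 1) / 2
  z_centre <- H / 2 * pixel_size_um

  cols <- seq_len(W); rows <- seq_len(H)
  u <- (cols - axis_col) * pixel_size_um
  z <- row_to_z(rows, H, pixel_size_um) - z_centre
  U <- matrix(u, H, W, byrow = TRUE)
  Z <- matrix(z, H, W)

  masks <- lapply(angles, function(ang) {
    th <- ang * pi / 180
    Rz <- matrix(c(cos(th), -sin(th), 0, sin(th), cos(th), 0, 0, 0, 1),
                 3, 3, byrow = TRUE)
    M <- Rz %*% spec$rotation
    if (spec$kind %in% c("sphere", "ellipsoid")) {
      A <- M %*% diag(1 / semi_um^2) %*% t(M)
      disc <- (A[1, 2] * U + A[2, 3] * Z)^2 -
        A[2, 2] * (A[1, 1] * U^2 + 2 * A[1, 3] * U * Z + A[3, 3] * Z^2 - 1)
      disc >= 0
    } else {
      ray_march_superellipsoid(U, Z, M, semi_um, spec$exponent, r_max)
    }
  })

  truth <- shape_truth(spec)
  occlusion_row <- NULL
  if (spec$occluded_fraction > 0) {
    zext <- solid_z_extent(spec, semi_um)
    z_cut <- z_centre + zext[2] - spec$occluded_fraction * diff(zext)
    occlusion_row <- max(1L, floor(z_to_row(z_cut, H, pixel_size_um)))
    masks <- lapply(masks, function(m) {
      m[seq_len(occlusion_row - 1), ] <- FALSE
      m
    })
    truth$occlusion_z_um <- row_to_z(occlusion_row, H, pixel_size_um) + pixel_size_um / 2
  }

  stack <- silhouette_stack(masks, angles, pixel_size_um,
                            rotation_axis = axis_col,
                            occlusion_row = occlusion_row)
  list(stack = stack, truth = truth)
}

## Vertical extent (um, relative to solid centre) of the rotated solid.
solid_z_extent <- function(spec, semi_um) {
  if (spec$kind %in% c("sphere", "ellipsoid")) {
    ## support function of an ellipsoid along +/- z
    h <- sqrt(sum((semi_um * spec$rotation[3, ])^2))
    c(-h, h)
  } else {
    P <- superellipsoid_samples(spec$semi_axes_mm * 1000, spec$exponent, grid = 90)
    range(P %*% spec$rotation[3, ])
  }
}

## Binary silhouette of a rotated superellipsoid by ray marching along
## the (orthographic) viewing direction.
ray_march_superellipsoid <- function(U, Z, M, semi_um, n, r_max, steps = 201) {
  ts <- seq(-r_max, r_max, length.out = steps)
  inside <- matrix(FALSE, nrow(U), ncol(U))
  Minv <- t(M) # rotation: inverse = transpose
  for (t_d in ts) {
    b1 <- (Minv[1, 1] * U + Minv[1, 2] * t_d + Minv[1, 3] * Z) / semi_um[1]
    b2 <- (Minv[2, 1] * U + Minv[2, 2] * t_d + Minv[2, 3] * Z) / semi_um[2]
    b3 <- (Minv[3, 1] * U + Minv[3, 2] * t_d + Minv[3, 3] * Z) / semi_um[3]
    inside <- inside | (abs(b1)^n + abs(b2)^n + abs(b3)^n <= 1)
  }
  inside
}
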