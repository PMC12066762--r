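#' Render a synthetic tray image with ground truth
#'
#' A top view of a tray of `n_cols x n_rows` soil-filled pots separated
#' by brighter pot walls, with optional green seedling blobs of exactly
#' requested pixel counts. Tray misalignment is emulated the way real
#' trays misbehave: a rigid displacement of the whole tray (translation
#' up to `jitter_mm` plus a slight rotation) together with a small
#' independent wobble of every wall crossing (fabrication inaccuracy and
#' tray flex). The true positions of all wall crossings, and the exact
#' pixel set of every blob, are returned alongside the image.
#'
#' @param layout `c(n_cols, n_rows)` pots (default 5 x 4).
#' @param pitch_mm Pot pitch in mm (default 15, i.e. 1.5 cm pots).
#' @param px_per_mm Image scale (default 5 px/mm).
#' @param jitter_mm Maximum tray displacement in mm (0-3).
#' @param plants Optional tibble with columns `col`, `row` (pot indices),
#'   `n_px` (green pixel count) and optionally `offset` (fraction of the
#'   distance from the pot centre toward the midpoint of its right wall;
#'   `offset = 1` centres the blob on the wall, default 0).
#' @param rng_seed Integer seed; identical seeds give identical images.
#' @param wall_width_px Drawn wall thickness.
#' @return List with `image` (H x W x 3), and `truth`: `lattice` (an
#'   `(n_rows+1) x (n_cols+1) x 2` array of crossing x/y pixel positions),
#'   `inner_crossings` (tibble of the `(n_cols-1)(n_rows-1)` wall
#'   crossings between pots), `nominal_lattice` (the undisplaced grid),
#'   `plant_pixels` (list of linear pixel index vectors), `px_per_mm`.
#' @export
make_tray_image <- function(layout = c(5, 4), pitch_mm = 15, px_per_mm = 5,
                            jitter_mm = 0, plants = NULL, rng_seed = 1,
                            wall_width_px = 3) {
  if (jitter_mm < 0) abort("jitter_mm must be >= 0", class = "seedtrack_error_domain")
  nc <- layout[1]; nr <- layout[2]
  pitch <- pitch_mm * px_per_mm
  if (jitter_mm * px_per_mm > pitch / 2 - 2) {
    abort("jitter too large: pots would overlap", class = "seedtrack_error_domain")
  }
  set.seed(rng_seed)
  margin <- ceiling(jitter_mm * px_per_mm) + 12
  Wd <- nc * pitch + 2 * margin
  Ht <- nr * pitch + 2 * margin

  ## nominal lattice: (nr+1) x (nc+1) crossings
  gx <- margin + (0:nc) * pitch
  gy <- margin + (0:nr) * pitch
  nominal <- array(0, c(nr + 1, nc + 1, 2))
  nominal[, , 1] <- matrix(gx, nr + 1, nc + 1, byrow = TRUE)
  nominal[, , 2] <- matrix(gy, nr + 1, nc + 1)

  ## rigid displacement + small per-point wobble
  jpx <- jitter_mm * px_per_mm
  shift <- stats::runif(2, -1, 1) * jpx * 0.9
  ## slight in-plane rotation, scaled with the misalignment amplitude
  ang <- stats::runif(1, -1, 1) * 0.006 * min(1, jitter_mm / 3)
  cx <- Wd / 2; cy <- Ht / 2
  lattice <- nominal
  X <- nominal[, , 1] - cx; Y <- nominal[, , 2] - cy
  lattice[, , 1] <- cx + X * cos(ang) - Y * sin(ang) + shift[1] +
    stats::runif(length(X), -1, 1) * min(0.15 * jpx, 1.5)
  lattice[, , 2] <- cy + X * sin(ang) + Y * cos(ang) + shift[2] +
    stats::runif(length(Y), -1, 1) * min(0.15 * jpx, 1.5)

  ## soil background
  base <- array(0, c(Ht, Wd, 3))
  noise <- matrix(stats::runif(Ht * Wd, -0.05, 0.05), Ht, Wd)
  base[, , 1] <- 0.38 + noise
  base[, , 2] <- 0.30 + noise
  base[, , 3] <- 0.22 + noise

  ## pot walls: straight segments between adjacent lattice points
  wall <- matrix(FALSE, Ht, Wd)
  draw_seg <- function(p1, p2) {
    n <- max(2, ceiling(max(abs(p2 - p1))) * 2)
    xs <- round(seq(p1[1], p2[1], length.out = n))
    ys <- round(seq(p1[2], p2[2], length.out = n))
    half <- floor(wall_width_px / 2)
    for (d in -half:half) {
      wall[cbind(pmin(pmax(ys + d, 1), Ht), pmin(pmax(xs, 1), Wd))] <<- TRUE
      wall[cbind(pmin(pmax(ys, 1), Ht), pmin(pmax(xs + d, 1), Wd))] <<- TRUE
    }
  }
  for (i in 1:(nr + 1)) for (j in 1:nc) {
    draw_seg(lattice[i, j, ], lattice[i, j + 1, ])
  }
  for (i in 1:nr) for (j in 1:(nc + 1)) {
    draw_seg(lattice[i, j, ], lattice[i + 1, j, ])
  }
  wall_shade <- 0.75 + matrix(stats::runif(Ht * Wd, -0.04, 0.04), Ht, Wd)
  for (ch in 1:3) {
    layer <- base[, , ch]
    layer[wall] <- wall_shade[wall]
    base[, , ch] <- layer
  }

  ## green blobs of exactly n_px pixels
  plant_pixels <- list()
  if (!is.null(plants) && nrow(plants) > 0) {
    if (!"offset" %in% names(plants)) plants$offset <- 0
    for (k in seq_len(nrow(plants))) {
      pc <- plants$col[k]; pr <- plants$row[k]
      centre <- (lattice[pr, pc, ] + lattice[pr + 1, pc + 1, ]) / 2
      ## offset moves the blob toward the midpoint of the pot's right wall
      right_mid <- (lattice[pr, pc + 1, ] + lattice[pr + 1, pc + 1, ]) / 2
      centre <- centre + plants$offset[k] * (right_mid - centre)
      n_px <- plants$n_px[k]
      rad <- ceiling(sqrt(n_px / pi)) + 3
      ys <- pmin(pmax(round(centre[2]) + (-rad:rad), 1), Ht)
      xs <- pmin(pmax(round(centre[1]) + (-rad:rad), 1), Wd)
      cand <- expand.grid(y = unique(ys), x = unique(xs))
      d2 <- (cand$x - centre[1])^2 + (cand$y - centre[2])^2
      ord <- order(d2)[seq_len(min(n_px, nrow(cand)))]
      sel <- cand[ord, ]
      idx <- sel$y + (sel$x - 1) * Ht
      base[, , 1][idx] <- 0.20 + stats::runif(length(idx), -0.03, 0.03)
      base[, , 2][idx] <- 0.55 + stats::runif(length(idx), -0.04, 0.04)
      base[, , 3][idx] <- 0.15 + stats::runif(length(idx), -0.03, 0.03)
      plant_pixels[[k]] <- idx
    }
  }
  base[base < 0] <- 0; base[base > 1] <- 1

  inner <- expand.grid(row = 2:nr, col = 2:nc)
  inner$x <- lattice[cbind(inner$row, inner$col, 1)]
  inner$y <- lattice[cbind(inner$row, inner$col, 2)]

  list(
    image = base,
    truth = list(
      lattice = lattice,
      nominal_lattice = nominal,
      inner_crossings = as_tibble(inner[c("col", "row", "x", "y")]),
      plant_pixels = plant_pixels,
      px_per_mm = px_per_mm,
      layout = c(n_cols = nc, n_rows = nr)
    )
  )
}
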