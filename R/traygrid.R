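## Adaptive pot-grid detection and cropping for tray images. Trays
## misalign against any fixed crop grid (fabrication tolerances and tray
## flex of a few mm), so the wall crossings between pots are detected in
## each image, a grid is fitted through them, the outer crossings are
## extrapolated, and pots are cropped along the fitted grid.

#' Detect the inner wall crossings of a pot tray
#'
#' Pot walls are brighter than soil. A matched-filter approach is used:
#' the above-median brightness is averaged along a horizontal and a
#' vertical bar of roughly half a pot pitch; the product of the two bar
#' responses peaks where a horizontal and a vertical wall cross.
#' Non-maximum suppression with a minimum separation of half a pitch
#' yields the candidate crossings, refined to sub-pixel positions by a
#' local response centroid; the `(n_cols-1)(n_rows-1)` strongest
#' candidates are the inner crossings.
#'
#' @param image RGB tray image in `[0, 1]`.
#' @param layout `c(n_cols, n_rows)` pots.
#' @param pitch_px Approximate pot pitch in px.
#' @return Tibble of crossings (`x`, `y`, `response`), ordered row-major
#'   (top-left to bottom-right).
#' @export
detect_crossings <- function(image, layout = c(5, 4), pitch_px = 75) {
  nc <- layout[1]; nr <- layout[2]
  n_needed <- (nc - 1) * (nr - 1)
  grey <- as_grey(image)
  w <- pmax(grey - median(grey), 0)
  bar <- max(5L, round(pitch_px * 0.5))
  resp_h <- t(apply(w, 1, running_mean, width = bar))
  resp_v <- apply(w, 2, running_mean, width = bar)
  resp <- resp_h * resp_v
  resp <- box_filter(resp, 3)

  ## absolute response floor: a wall-crossing needs both bars to average
  ## visibly above the soil level
  floor_resp <- 0.01
  min_sep <- round(pitch_px * 0.45)
  peaks <- non_max_suppression(resp, min_sep, floor_resp)
  ## border walls produce T-junction responses near the image edge; inner
  ## crossings sit at least one pitch inside the tray
  edge <- pitch_px * 0.5
  peaks <- peaks[peaks$x > edge & peaks$x < ncol(resp) - edge &
                   peaks$y > edge & peaks$y < nrow(resp) - edge, ]
  if (nrow(peaks) < n_needed) {
    abort(sprintf("crossing detection failed: found %d of %d required crossings",
                  nrow(peaks), n_needed),
          class = "seedtrack_error_detection", n_found = nrow(peaks))
  }
  peaks <- peaks[order(-peaks$response), ][seq_len(n_needed), ]

  ## sub-pixel refinement: response-weighted centroid in a small window
  half <- 3L
  for (k in seq_len(nrow(peaks))) {
    r0 <- peaks$y[k]; c0 <- peaks$x[k]
    rows <- max(1, r0 - half):min(nrow(resp), r0 + half)
    cols <- max(1, c0 - half):min(ncol(resp), c0 + half)
    win <- resp[rows, cols]
    win <- pmax(win - min(win), 0)
    if (sum(win) > 0) {
      peaks$y[k] <- sum(rows * rowSums(win)) / sum(win)
      peaks$x[k] <- sum(cols * colSums(win)) / sum(win)
    }
  }
  peaks <- peaks[order(peaks$y, peaks$x), ]
  as_tibble(peaks[, c("x", "y", "response")])
}

running_mean <- function(x, width) {
  if (width %% 2 == 0) width <- width + 1L
  out <- stats::filter(x, rep(1 / width, width), sides = 2)
  out[is.na(out)] <- 0
  as.numeric(out)
}

## Local maxima of a response matrix with minimum separation (greedy).
non_max_suppression <- function(resp, min_sep, floor_resp) {
  ord <- order(resp, decreasing = TRUE)
  keep_x <- numeric(0); keep_y <- numeric(0); keep_r <- numeric(0)
  nrw <- nrow(resp)
  for (lin in ord) {
    val <- resp[lin]
    if (val < floor_resp) break
    y <- (lin - 1) %% nrw + 1
    x <- (lin - 1) %/% nrw + 1
    if (length(keep_x) &&
        any(abs(keep_x - x) < min_sep & abs(keep_y - y) < min_sep)) next
    keep_x <- c(keep_x, x); keep_y <- c(keep_y, y); keep_r <- c(keep_r, val)
    if (length(keep_x) >= 200) break
  }
  data.frame(x = keep_x, y = keep_y, response = keep_r)
}

#' Fit grid lines through the inner crossings and extrapolate the border
#'
#' The inner crossings are sorted into `(n_rows-1)` rows and
#' `(n_cols-1)` columns; each grid line is least-squares fitted through
#' its crossings. The outer (border) lines are extrapolated assuming
#' uniform pot pitch, and the full `(n_rows+1) x (n_cols+1)` lattice is
#' returned as the pairwise intersections of the two line families.
#'
#' @param crossings Tibble/data frame with `x`, `y` (from
#'   [detect_crossings()] or ground truth).
#' @param layout `c(n_cols, n_rows)` pots.
#' @return Object of class `grid_model`: `lattice` (array
#'   `(n_rows+1) x (n_cols+1) x 2`), `inner_crossings`, `v_lines` and
#'   `h_lines` (coefficient tibbles), `layout`.
#' @export
fit_and_extrapolate <- function(crossings, layout = c(5, 4)) {
  nc <- layout[1]; nr <- layout[2]
  pts <- as.data.frame(crossings)
  if (nrow(pts) != (nc - 1) * (nr - 1)) {
    abort(sprintf("expected %d crossings, got %d", (nc - 1) * (nr - 1), nrow(pts)),
          class = "seedtrack_error_domain")
  }
  if (stats::sd(pts$x) < 1e-9 || stats::sd(pts$y) < 1e-9) {
    abort("crossings are collinear; cannot fit a grid",
          class = "seedtrack_error_fit")
  }
  ## row-major assignment by sorting
  pts <- pts[order(pts$y), ]
  pts$grid_row <- rep(seq_len(nr - 1), each = nc - 1)
  pts <- pts[order(pts$grid_row, pts$x), ]
  pts$grid_col <- rep(seq_len(nc - 1), times = nr - 1)

  ## vertical lines: x = a + b y; horizontal lines: y = a + b x
  v_lines <- lapply(seq_len(nc - 1), function(j) {
    d <- pts[pts$grid_col == j, ]
    if (nrow(d) >= 2 && stats::sd(d$y) > 1e-9) {
      unname(coef(lm(x ~ y, data = d)))
    } else c(mean(d$x), 0)
  })
  h_lines <- lapply(seq_len(nr - 1), function(i) {
    d <- pts[pts$grid_row == i, ]
    if (nrow(d) >= 2 && stats::sd(d$x) > 1e-9) {
      unname(coef(lm(y ~ x, data = d)))
    } else c(mean(d$y), 0)
  })
  ## uniform-pitch extrapolation of the border lines
  extend <- function(lines, n_inner) {
    a <- vapply(lines, `[`, numeric(1), 1)
    b <- vapply(lines, `[`, numeric(1), 2)
    pitch <- if (n_inner > 1) mean(diff(a)) else NA_real_
    if (!is.finite(pitch)) {
      abort("cannot extrapolate a single grid line without a pitch",
            class = "seedtrack_error_fit")
    }
    slope0 <- if (n_inner > 1) b[1] else b[1]
    c(list(c(a[1] - pitch, slope0)), lines,
      list(c(a[n_inner] + pitch, b[n_inner])))
  }
  v_all <- extend(v_lines, nc - 1)
  h_all <- extend(h_lines, nr - 1)

  lattice <- array(NA_real_, c(nr + 1, nc + 1, 2))
  for (i in seq_len(nr + 1)) {
    for (j in seq_len(nc + 1)) {
      ## intersection of x = av + bv y and y = ah + bh x
      av <- v_all[[j]][1]; bv <- v_all[[j]][2]
      ah <- h_all[[i]][1]; bh <- h_all[[i]][2]
      x <- (av + bv * ah) / (1 - bv * bh)
      y <- ah + bh * x
      lattice[i, j, ] <- c(x, y)
    }
  }
  structure(
    list(lattice = lattice,
         inner_crossings = as_tibble(pts[, c("x", "y", "grid_col", "grid_row")]),
         v_lines = v_all, h_lines = h_all,
         layout = c(n_cols = nc, n_rows = nr)),
    class = "grid_model"
  )
}

#' Build a grid model from known lattice positions
#'
#' Bypasses detection/fitting when the full lattice is already known
#' (e.g. ground truth from [make_tray_image()], or a trivial whole-image
#' 1 x 1 grid).
#'
#' @param lattice `(n_rows+1) x (n_cols+1) x 2` array of x/y positions.
#' @param layout `c(n_cols, n_rows)`.
#' @return A `grid_model`.
#' @export
grid_from_lattice <- function(lattice, layout) {
  stopifnot(length(dim(lattice)) == 3,
            dim(lattice)[1] == layout[2] + 1, dim(lattice)[2] == layout[1] + 1)
  structure(
    list(lattice = lattice, inner_crossings = NULL, v_lines = NULL,
         h_lines = NULL, layout = c(n_cols = layout[1], n_rows = layout[2])),
    class = "grid_model"
  )
}

#' @export
print.grid_model <- function(x, ...) {
  cat(sprintf("<grid_model> %d x %d pots, lattice %d x %d\n",
              x$layout[1], x$layout[2], dim(x$lattice)[1], dim(x$lattice)[2]))
  invisible(x)
}

#' Crop single-pot images along a fitted grid
#'
#' Every pixel of the tray is assigned to exactly one pot cell by
#' locating it between the piecewise-linear boundary curves joining
#' adjacent lattice points (a partition of the tray area: straight
#' segments between lattice points tolerate tray flex better than global
#' straight lines). Each crop is the cell's bounding box together with
#' the exact cell mask and its pot indices, ready for seed-ID linkage.
#'
#' @param image RGB tray image.
#' @param grid A `grid_model` from [fit_and_extrapolate()].
#' @param tray_id Identifier attached to every crop.
#' @return Tibble with columns `tray_id`, `x_index`, `y_index`, `image`
#'   (list of cropped arrays), `mask` (list of logical cell masks within
#'   the crop), `n_pixels`.
#' @export
crop_pots <- function(image, grid, tray_id = "tray") {
  stopifnot(inherits(grid, "grid_model"))
  nc <- grid$layout[1]; nr <- grid$layout[2]
  Ht <- dim(image)[1]; Wd <- dim(image)[2]
  if (any(grid$lattice[, , 1] < 0.5) || any(grid$lattice[, , 1] > Wd + 0.5) ||
      any(grid$lattice[, , 2] < 0.5) || any(grid$lattice[, , 2] > Ht + 0.5)) {
    warn("grid extends beyond the image; crops are clipped at the border")
  }

  ## piecewise-linear boundary x-position of vertical curve j at height y
  px_y <- seq_len(Ht)
  v_curves <- vapply(seq_len(nc + 1), function(j) {
    xs <- grid$lattice[, j, 1]; ys <- grid$lattice[, j, 2]
    stats::approx(ys, xs, xout = px_y, rule = 2)$y
  }, numeric(Ht))
  px_x <- seq_len(Wd)
  h_curves <- vapply(seq_len(nr + 1), function(i) {
    xs <- grid$lattice[i, , 1]; ys <- grid$lattice[i, , 2]
    stats::approx(xs, ys, xout = px_x, rule = 2)$y
  }, numeric(Wd))

  ## cell index per pixel: count boundaries to the left / above
  col_idx <- matrix(0L, Ht, Wd)
  for (j in seq_len(nc + 1)) {
    col_idx <- col_idx + (matrix(px_x, Ht, Wd, byrow = TRUE) >=
                            matrix(v_curves[, j], Ht, Wd))
  }
  row_idx <- matrix(0L, Ht, Wd)
  for (i in seq_len(nr + 1)) {
    row_idx <- row_idx + (matrix(px_y, Ht, Wd) >=
                            matrix(h_curves[, i], Ht, Wd, byrow = TRUE))
  }
  inside <- col_idx >= 1 & col_idx <= nc & row_idx >= 1 & row_idx <= nr

  crops <- vector("list", nc * nr)
  k <- 0
  for (yi in seq_len(nr)) {
    for (xi in seq_len(nc)) {
      cell <- inside & col_idx == xi & row_idx == yi
      if (!any(cell)) {
        k <- k + 1
        crops[[k]] <- tibble(tray_id = tray_id, x_index = xi, y_index = yi,
                             image = list(NULL), mask = list(NULL), n_pixels = 0L)
        next
      }
      rr <- range(which(rowSums(cell) > 0))
      cc <- range(which(colSums(cell) > 0))
      sub <- image[rr[1]:rr[2], cc[1]:cc[2], , drop = FALSE]
      cmask <- cell[rr[1]:rr[2], cc[1]:cc[2]]
      ## zero out pixels belonging to neighbouring cells
      for (ch in seq_len(dim(sub)[3])) {
        layer <- sub[, , ch]
        layer[!cmask] <- 0
        sub[, , ch] <- layer
      }
      k <- k + 1
      crops[[k]] <- tibble(
        tray_id = tray_id, x_index = xi, y_index = yi,
        image = list(sub), mask = list(cmask), n_pixels = sum(cell),
        offset_row = rr[1], offset_col = cc[1]
      )
    }
  }
  dplyr::bind_rows(crops)
}
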