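## Shared synthetic fixtures for the test suite. Everything is generated
## in code; expensive carves are built once per file where needed.

## Greyscale frame with one or more dark disks on a bright background.
disk_image <- function(centres, radius, size = 120, fg = 30 / 255, bg = 220 / 255) {
  img <- matrix(bg, size, size)
  rows <- matrix(seq_len(size), size, size)
  cols <- matrix(seq_len(size), size, size, byrow = TRUE)
  for (i in seq_len(nrow(centres))) {
    d2 <- (rows - centres[i, 1])^2 + (cols - centres[i, 2])^2
    img[d2 <= radius^2] <- fg
  }
  img
}

## RGB image from a grey matrix (equal channels).
grey_rgb <- function(grey) {
  array(rep(grey, 3), c(dim(grey), 3))
}

## Rasterized solid ball occupancy grid (voxel units).
ball_array <- function(r, margin = 4) {
  n <- 2 * r + 2 * margin
  cc <- (n + 1) / 2
  g <- expand.grid(x = seq_len(n), y = seq_len(n), z = seq_len(n))
  array((g$x - cc)^2 + (g$y - cc)^2 + (g$z - cc)^2 <= r^2, c(n, n, n))
}

## Distance from each true crossing to its nearest detected one, after
## checking the match is one-to-one.
crossing_errors <- function(detected, truth) {
  a <- as.data.frame(detected)
  b <- as.data.frame(truth)
  stopifnot(nrow(a) == nrow(b))
  dm <- outer(b$x, a$x, `-`)^2 + outer(b$y, a$y, `-`)^2
  nearest <- apply(dm, 1, which.min)
  stopifnot(!anyDuplicated(nearest)) # bijective assignment
  sqrt(dm[cbind(seq_len(nrow(b)), nearest)])
}
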