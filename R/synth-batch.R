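## Synthetic seed batches: multivariate-normal trait tables with the
## published batch moments and a realistic cross-trait correlation
## structure.

trait_columns <- c(
  mass = "mass_ug", volume = "volume_nl", length = "length_mm",
  width = "width_mm", height = "height_mm", sphericity = "sphericity_pct",
  brightness = "brightness_pct", germination_time = "germination_time_d",
  growth_rate = "growth_rate_mm2_d"
)

#' Default correlation structure for synthetic seed batches
#'
#' Built from a latent factor model, which guarantees a valid (positive
#' definite) correlation matrix: three weakly coupled size factors drive
#' length, width and height; volume loads on all three; mass tracks
#' volume at r = 0.98; sphericity responds negatively to length;
#' germination time follows seed brightness negatively; early growth
#' rate couples positively to mass and negatively to germination time.
#' These choices mirror the qualitative relationships seen in tracked
#' Col-0 batches (e.g. near-perfect mass-volume coupling, no
#' length-width correlation, brighter seeds germinating earlier).
#'
#' @return 9 x 9 correlation matrix over the standard trait set.
#' @export
default_trait_correlation <- function() {
  traits <- names(trait_columns)
  ## loadings over latent factors: l, w, h, e_v, e_m, b, e_g, e_r, e_s
  L <- matrix(0, 9, 9, dimnames = list(traits, NULL))
  L["length", 1] <- 1
  L["width", 2] <- 1
  L["height", 2:3] <- c(0.5, sqrt(0.75))
  v <- (L["length", ] + L["width", ] + L["height", ])
  v[4] <- 0.3
  L["volume", ] <- v / sqrt(sum(v^2) + 2 * 0.0) # latents are orthonormal
  L["volume", ] <- L["volume", ] / sqrt(sum(L["volume", ]^2))
  L["mass", ] <- 0.98 * L["volume", ]
  L["mass", 5] <- sqrt(1 - 0.98^2)
  s <- -0.75 * L["length", ] + 0.3 * L["width", ] + 0.2 * c(0, 0, 1, 0, 0, 0, 0, 0, 0)
  s[9] <- sqrt(max(0, 1 - sum(s^2)))
  L["sphericity", ] <- s
  L["brightness", 6] <- 1
  g <- -0.6 * L["brightness", ]
  g[7] <- sqrt(1 - 0.36)
  L["germination_time", ] <- g
  r <- 0.3 * L["mass", ] - 0.25 * L["germination_time", ]
  r[8] <- sqrt(max(0, 1 - sum(r^2)))
  L["growth_rate", ] <- r
  R <- tcrossprod(L)
  dimnames(R) <- list(traits, traits)
  R
}

#' Generate a synthetic seed batch
#'
#' Draws `n` seeds from a multivariate normal with the requested per-trait
#' means and SDs and the given correlation structure, then truncates
#' physically positive traits at a small positive floor. Sample moments
#' converge to the targets as `n` grows.
#'
#' @param n Number of seeds.
#' @param batch `"C"` (control) or `"T"` (elevated temperature): selects
#'   the default means/SDs from [seed_trait_summaries()].
#' @param means,sds Optional named numeric vectors (names from
#'   `c("mass", "volume", "length", "width", "height", "sphericity",
#'   "brightness", "germination_time", "growth_rate")`) overriding the
#'   batch defaults.
#' @param correlation Correlation matrix over the chosen traits; must be
#'   positive definite. Default [default_trait_correlation()].
#' @param rng_seed Optional integer seed.
#' @return Tibble with one row per seed and the standard trait columns
#'   (`mass_ug`, `volume_nl`, ..., `growth_rate_mm2_d`) plus `batch`.
#' @export
make_seed_batch <- function(n, batch = "C", means = NULL, sds = NULL,
                            correlation = default_trait_correlation(),
                            rng_seed = NULL) {
  stopifnot(n >= 1)
  ref <- seed_trait_summaries()
  mcol <- paste0("mean_", batch); scol <- paste0("sd_", batch)
  base_means <- setNames(ref[[mcol]], ref$trait)
  base_sds <- setNames(ref[[scol]], ref$trait)
  if (!is.null(means)) base_means[names(means)] <- means
  if (!is.null(sds)) base_sds[names(sds)] <- sds

  traits <- rownames(correlation) %||% names(trait_columns)
  if (!all(traits %in% names(base_means))) {
    abort("correlation rows must be named after known traits",
          class = "seedtrack_error_domain")
  }
  ev <- eigen(correlation, symmetric = TRUE, only.values = TRUE)$values
  if (any(ev <= 1e-10)) {
    abort("correlation structure is not positive definite",
          class = "seedtrack_error_domain")
  }
  if (!is.null(rng_seed)) set.seed(rng_seed)
  sigma <- diag(base_sds[traits]) %*% correlation %*% diag(base_sds[traits])
  draws <- MASS::mvrnorm(n, mu = base_means[traits], Sigma = sigma)
  if (n == 1) draws <- matrix(draws, 1, dimnames = list(NULL, traits))
  out <- as_tibble(as.data.frame(draws))
  ## physical traits cannot be negative
  positive <- setdiff(traits, character())
  for (tr in positive) out[[tr]] <- pmax(out[[tr]], base_means[tr] * 0.01)
  names(out) <- trait_columns[traits]
  out$batch <- batch
  out
}
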