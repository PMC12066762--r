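## The tracking data model: batch -> seed -> tray position -> plant.
## Every seed gets a stable ID at pick-up; its tray position links it to
## the pot images, and an emerged plant inherits the linkage. All
## exchange happens through flat one-row-per-seed tables.

#' Create a seed ID registry
#'
#' A registry records which batch IDs have been used so a batch cannot
#' be registered twice. One package-level default registry exists; tests
#' and pipelines can create their own.
#'
#' @return An environment of class `seed_registry`.
#' @export
seed_registry <- function() {
  structure(new.env(parent = emptyenv()), class = "seed_registry")
}

the_registry <- seed_registry()

#' Reset the package-level seed registry
#' @export
reset_registry <- function() {
  rm(list = ls(the_registry), envir = the_registry)
  invisible(NULL)
}

#' Assign seed IDs for a batch
#'
#' IDs embed the batch ID and a zero-padded ordinal
#' (`<batch>-0001`, ...), so they are unique, ordered, and readable.
#'
#' @param batch_id Non-empty batch identifier.
#' @param n_seeds Number of IDs to create (0 allowed).
#' @param registry A [seed_registry()]; defaults to the package registry.
#' @return Character vector of `n_seeds` IDs.
#' @export
assign_ids <- function(batch_id, n_seeds, registry = the_registry) {
  if (!is.character(batch_id) || nchar(batch_id) == 0) {
    abort("batch_id must be a non-empty string", class = "seedtrack_error_domain")
  }
  if (exists(batch_id, envir = registry, inherits = FALSE)) {
    abort(sprintf("batch '%s' is already registered", batch_id),
          class = "seedtrack_error_conflict")
  }
  assign(batch_id, n_seeds, envir = registry)
  if (n_seeds == 0) return(character(0))
  sprintf("%s-%04d", batch_id, seq_len(n_seeds))
}

#' Join seed traits with plant growth traits
#'
#' Left join on `seed_id`: all phenotyped seeds are preserved, growth
#' fields are `NA` for seeds that were not sown or never emerged.
#' Duplicate keys on either side violate the one-row-per-seed contract
#' and raise an integrity error; growth rows without a matching seed are
#' reported in the `unmatched` attribute.
#'
#' @param seed_table Tibble with a `seed_id` column (one row per seed).
#' @param growth_table Tibble with a `seed_id` column.
#' @return The joined tibble, with attribute `unmatched`.
#' @export
join_traits <- function(seed_table, growth_table) {
  if (!"seed_id" %in% names(seed_table) || !"seed_id" %in% names(growth_table)) {
    abort("both tables need a seed_id column", class = "seedtrack_error_integrity")
  }
  if (anyDuplicated(seed_table$seed_id)) {
    abort("duplicate seed_id in seed table", class = "seedtrack_error_integrity")
  }
  if (nrow(growth_table) > 0 && anyDuplicated(growth_table$seed_id)) {
    abort("duplicate seed_id in growth table", class = "seedtrack_error_integrity")
  }
  out <- dplyr::left_join(seed_table, growth_table, by = "seed_id")
  unmatched <- setdiff(growth_table$seed_id, seed_table$seed_id)
  if (length(unmatched)) {
    warn(sprintf("%d growth rows have no matching seed", length(unmatched)))
  }
  attr(out, "unmatched") <- unmatched
  out
}

#' Read and write seed record tables
#'
#' UTF-8 CSV with a header row, one seed per row. Reading restores
#' numeric and character columns so a write/read round trip is lossless.
#'
#' @param records Tibble of seed records.
#' @param path CSV file path.
#' @return `read_seed_records()` returns a tibble;
#'   `write_seed_records()` returns `path` invisibly.
#' @export
write_seed_records <- function(records, path) {
  drop <- vapply(records, is.list, logical(1))
  readr::write_csv(records[!drop], path)
  invisible(path)
}

#' @rdname write_seed_records
#' @export
read_seed_records <- function(path) {
  readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
}

#' Run the full tracking pipeline on synthetic data
#'
#' End-to-end demonstration and integration surface: for each configured
#' batch it generates a synthetic seed batch, renders and carves a 3D
#' silhouette stack per seed (the seed's shape is an ellipsoid with the
#' drawn length/width/height), renders and measures the 2D seed image,
#' simulates the Growscreen time series for the sown seeds and fits
#' germination time and early growth rate, joins everything by seed ID,
#' and closes with the batch statistics (trait correlation matrix and
#' per-trait Welch tests).
#'
#' @param config List: `batches` (named list, each with `n`; names are
#'   batch IDs "C"/"T" selecting generator defaults), `seed` (RNG seed),
#'   `voxel_um` (carving resolution, default 15), `pixel_um_3d` (3D
#'   station pixel size, default 8), `sown_fraction` (default 0.72),
#'   `emergence_fraction` (default 0.85), `days` (sampling days).
#' @return List of class `seedtrack_run`: `records` (the joined trait
#'   table), `correlations` (a `trait_cor`), `tests` (per-trait Welch
#'   results), `log` (character).
#' @export
run_end_to_end <- function(config) {
  if (is.null(config$batches) || length(config$batches) == 0) {
    abort("config must name at least one batch", class = "seedtrack_error_usage")
  }
  seed <- config$seed %||% 1
  voxel_um <- config$voxel_um %||% 15
  px3d <- config$pixel_um_3d %||% 8
  sown_fraction <- config$sown_fraction %||% 0.72
  emergence_fraction <- config$emergence_fraction %||% 0.85
  days <- config$days %||% seq(1, 14)
  registry <- seed_registry()
  log <- character()
  say <- function(...) {
    msg <- sprintf(...)
    log <<- c(log, msg)
    inform(msg)
  }
  set.seed(seed)

  all_seeds <- list()
  all_growth <- list()
  for (bi in seq_along(config$batches)) {
    batch_id <- names(config$batches)[bi]
    n <- config$batches[[bi]]$n
    say("batch %s: generating %d seeds", batch_id, n)
    truth <- make_seed_batch(n, batch = batch_id)
    ids <- assign_ids(batch_id, n, registry)

    say("batch %s: 3D station (carving at %g um voxels)", batch_id, voxel_um)
    m3d <- purrr::map_dfr(seq_len(n), function(i) {
      spec <- shape_spec("ellipsoid",
                         semi_axes_mm = c(truth$length_mm[i] / 2,
                                          truth$width_mm[i] / 2,
                                          truth$height_mm[i] / 2))
      rs <- render_silhouettes(spec, pixel_size_um = px3d)
      measure_morphometrics(carve_hull(rs$stack, voxel_size = voxel_um))
    })

    say("batch %s: 2D station", batch_id)
    m2d <- purrr::map_dfr(seq_len(n), function(i) {
      si <- make_seed_image(
        semi_axes_mm = c(truth$length_mm[i] / 2, truth$width_mm[i] / 2),
        brightness_pct = truth$brightness_pct[i]
      )
      mask <- suppressWarnings(segment_seed_2d(si$image, pixel_size = 16))
      suppressWarnings(color_traits(si$image, mask, pixel_size = 16))
    })

    seeds <- dplyr::bind_cols(
      tibble(batch_id = batch_id, seed_id = ids,
             measured_at = format(Sys.time(), "%Y-%m-%dT%H:%M:%S")),
      tibble(mass_ug = truth$mass_ug),
      m3d, m2d
    )

    n_sown <- round(sown_fraction * n)
    sown_idx <- seq_len(n_sown)
    tray_ids <- sprintf("%s-tray%02d", batch_id, (sown_idx - 1) %/% 20 + 1)
    seeds$tray_id <- NA_character_
    seeds$pos_x <- NA_integer_
    seeds$pos_y <- NA_integer_
    seeds$tray_id[sown_idx] <- tray_ids
    seeds$pos_x[sown_idx] <- as.integer((sown_idx - 1) %% 5 + 1)
    seeds$pos_y[sown_idx] <- as.integer(((sown_idx - 1) %/% 5) %% 4 + 1)

    say("batch %s: Growscreen series for %d sown seeds", batch_id, n_sown)
    emerged <- stats::runif(n_sown) < emergence_fraction
    growth <- purrr::map_dfr(sown_idx, function(i) {
      if (!emerged[i]) {
        return(tibble(seed_id = ids[i], status = "no-emergence",
                      germination_time_d = NA_real_,
                      growth_rate_mm2_d = NA_real_, emergence_d = NA_real_))
      }
      gc <- make_growth_curve(
        germination_time_d = max(0.5, truth$germination_time_d[i]),
        linear_rate_mm2_d = max(0.1, truth$growth_rate_mm2_d[i]),
        switch_time_d = max(0.5, truth$germination_time_d[i]) + 4,
        times_d = days
      )
      fit <- fit_linear_segment(gc$series)
      g <- glance(fit)
      tibble(seed_id = ids[i], status = g$status,
             germination_time_d = g$germination_time_d,
             growth_rate_mm2_d = g$growth_rate_mm2_d,
             emergence_d = detect_emergence(gc$series))
    })
    seeds$plant_id <- NA_character_
    ok <- seeds$seed_id %in% growth$seed_id[growth$status == "fitted"]
    seeds$plant_id[ok] <- sub("^", "P-", seeds$seed_id[ok])

    all_seeds[[batch_id]] <- seeds
    all_growth[[batch_id]] <- growth
  }

  seed_table <- dplyr::bind_rows(all_seeds)
  growth_table <- dplyr::bind_rows(all_growth)
  records <- join_traits(seed_table, growth_table)

  say("statistics: correlation matrix and per-trait tests")
  trait_cols <- c("mass_ug", "volume_nl", "length_mm", "width_mm", "height_mm",
                  "sphericity_pct", "brightness_mean_pct",
                  "germination_time_d", "growth_rate_mm2_d")
  trait_cols <- intersect(trait_cols, names(records))
  correlations <- correlation_matrix(records, trait_cols)

  batches <- unique(records$batch_id)
  tests <- NULL
  if (length(batches) == 2) {
    tests <- purrr::map_dfr(trait_cols, function(tc) {
      s <- lapply(batches, function(b) {
        v <- records[[tc]][records$batch_id == b]
        v <- v[is.finite(v)]
        list(mean = mean(v), sd = sd(v), n = length(v))
      })
      if (s[[1]]$n < 2 || s[[2]]$n < 2) {
        return(tibble(trait = tc, t = NA_real_, df = NA_real_, p = NA_real_))
      }
      dplyr::bind_cols(tibble(trait = tc), welch_ttest(s[[1]], s[[2]]))
    })
  }

  structure(list(records = records, correlations = correlations,
                 tests = tests, log = log),
            class = "seedtrack_run")
}

#' @export
print.seedtrack_run <- function(x, ...) {
  cat(sprintf("<seedtrack_run> %d seeds, %d traits correlated\n",
              nrow(x$records), length(x$correlations$traits)))
  invisible(x)
}
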