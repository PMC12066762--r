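Package: seedtrack
Title: Seed-to-Plant Tracking and Morphometric Phenotyping for Arabidopsis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Computational core of a seed-to-plant tracking pipeline for
    individual Arabidopsis seeds. Reconstructs single-seed 3D shape from
    rotation-series silhouettes by visual-hull voxel carving and derives
    volume, length, width, height, surface area and sphericity; extracts
    2D seed traits (projected area, HSV brightness) and a mass-from-area
    power model; detects pot-grid crossings in tray images and crops
    per-pot images robust to tray misalignment; turns leaf-area time
    series into germination times and early growth rates via a
    backward-eliminated linear fit plus an exponential phase; and provides
    the supporting statistics (release kinematics, balance-noise
    sample-size simulation, chi-square confidence intervals for sigma,
    Welch tests, density validation, trait correlation matrices).
    Includes synthetic-data generators with analytic ground truth for
    every input modality.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    EBImage,
    generics,
    ggplot2,
    jsonlite,
    MASS,
    minpack.lm,
    png,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
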