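---
title: "Methods: seed morphometrics, growth fitting and batch statistics in seedtrack"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: seed morphometrics, growth fitting and batch statistics in seedtrack}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(seedtrack)
```

`seedtrack` implements the computational core of an individual-seed
phenotyping and seed-to-plant tracking pipeline for Arabidopsis. This
vignette documents the models and algorithms, the parameters that matter,
the numerical choices, and what the synthetic-data tests do and do not
demonstrate.

## 1. 3D morphometrics by visual-hull carving

### Model

A seed held on a vertical nozzle is rotated in front of a camera; each of
the 36 views (10° steps) yields a binary silhouette. We assume an
**orthographic projection** with a fixed µm/px scale: the seed (≈ 0.5 mm)
is small relative to the working distance of a macro lens, so perspective
across the seed is negligible, and orthography makes carving separable
per view. The projection of a point $(x, y, z)$ into the view at
turntable angle $\theta$ is $u = x\cos\theta + y\sin\theta$ at height
$z$, with the rotation axis assumed vertical in the image (supplied by
calibration, or estimated as the median silhouette centroid column over
the full rotation, which is unbiased for any shape).

`carve_hull()` keeps a voxel iff its centre projects inside the
silhouette in every view. This voxel-centre test is unbiased (no
systematic inflation or erosion); the result approximates the **visual
hull**, the largest body consistent with all silhouettes. Two properties
follow and are exercised as tests:

* *re-projection containment* — projecting the hull into any view gives a
  mask that is a subset of that view's silhouette (exact at voxel
  resolution, by construction);
* *over-approximation* — the hull contains the true (convex) object, so
  the carved volume is an upper estimate; with 36 views the angular
  excess is ≤ $(1/\cos 5° - 1) \approx 0.4\%$ in radius.

The default voxel size is **5 µm**, giving ≥ 27 voxels across the
shortest semi-axis of a typical Arabidopsis seed (0.135 mm); carving
warns below 20 voxels. Discretization matters at the boundary: the
nearest-pixel silhouette lookup dilates the discrete hull by about half a
pixel. Rendering synthetic oracles at half the voxel pitch (2.5 µm px for
5 µm voxels) keeps all axis-length estimates within one voxel of the
analytic values; at equal pitch the volume criteria still hold but corner
directions of the hull can exceed the one-voxel band.

### Length, width, height

Length is the longest distance inside the object; width the longest
extent orthogonal to the length axis; height the extent orthogonal to
both, with width defined as the larger of the two (a swap enforces
W ≥ H). The farthest pair is found on directional extreme points of the
surface-voxel cloud (600 Fibonacci directions — the endpoints of a
diameter are extreme in their own direction), followed by an exact 2D
convex-hull search in the orthogonal plane. Ties are broken by first
occurrence in scan order. Distances are centre-to-centre: the half-voxel
inset of voxel centres cancels against the half-pixel carving dilation,
so no end-correction is applied.

### Surface area and sphericity

Counting exposed voxel faces overestimates the area of curved surfaces by
up to 1.5× (the axis-aligned staircase), so it is not used. Instead the
binary occupancy is blurred with a small separable Gaussian
(**σ = 0.8 voxel**) and the area is computed as the co-area integral
$\int |\nabla f|\,dV$ of the smoothed indicator — exact for a smoothed
step across a plane, and within 0.7 % of $4\pi r^2$ on rasterized spheres
of radius 20–45 voxels. σ was fixed once by this sphere calibration: more
smoothing suppresses stair-casing noise but rounds sharp edges (a cube
loses ~2 % area at σ = 0.8, ~3.3 % at σ = 1.5). Sphericity is
$100\,\pi^{1/3}(6V)^{2/3}/A$; the sphere attains 100 % and a small
discretization tolerance above 100 is accepted in tests.

### Occluded-cap extrapolation

The nozzle hides the top of the seed in every view, so the carved hull is
cut by a horizontal plane and the volume is biased low (a 10 % height
truncation of a sphere removes ~2.8 % of its volume). We fit a general
quadric by algebraic least squares to the surface voxels more than
3 voxel layers below the plane (the layers at the plane trace the
artificial flat cut), centred on the point cloud and scaled to mm for
conditioning, and require the quadric to be a bounded ellipsoid (positive
definite quadratic form) — otherwise the hull is returned unchanged with
a warning. Voxels of the fitted ellipsoid above the plane are added,
clipped to the xy-footprint of the contact cross-section dilated by one
voxel; for a convex seed the true cap lies inside that footprint, which
also guarantees the added volume never exceeds the cylinder spanned by
the contact cross-section. Synthetic truncation tests recover a
10 %-truncated sphere to within 2 % and a half-truncated ellipsoid to
within 10 %. This module is validated purely by such truncation-recovery
properties, not by equivalence to any particular instrument algorithm.

## 2. 2D seed traits

Seed brightness is the mean HSV value (hexcone model, reported in
percent) of a **5 × 5 px patch centred on the mask centroid** — at the 2D
station's ≈ 16 µm/px this is ≈ 80 × 80 µm. A central cut-out retains
genuine surface brightness variation while excluding the darker rim
pixels; if the patch would leave the mask it is shrunk and an
`edge_flag` is recorded rather than failing. Segmentation thresholds the
value channel (Otsu default), keeps the largest connected component and
fills holes; areas outside 0.05–0.5 mm² are flagged implausible, not
rejected. A frame whose "foreground" would exceed half the image is
treated as having none (blank or unusable lighting).

The mass model $m = a\,A^{3/2}$ restores the dimension missing from a
projected area under geometric similarity; `fit_mass_area_model()`
estimates the single coefficient by least squares and reports per-seed
relative deviations. On real seed data such deviations reach tens of
percent, which is exactly why the pipeline measures volume rather than
inferring mass from area; the package computes hue and saturation but
makes no scientific claims about them.

## 3. Tray grid and pot cropping

Pot walls are brighter than soil. The crossing detector is a matched
filter: above-median brightness is averaged along horizontal and vertical
bars of half a pot pitch, and the product of the two bar responses peaks
where two walls cross. Non-maximum suppression (minimum separation 0.45
pitch, absolute response floor so a featureless image fails loudly),
exclusion of a half-pitch border band (where tray-edge T-junctions live),
and a response-centroid refinement give sub-pixel crossings; the
$(n_\mathrm{cols}-1)(n_\mathrm{rows}-1)$ strongest are the inner
crossings. Grid lines are least-squares fitted per row/column of
crossings; border lines are extrapolated assuming uniform pot pitch, and
the full lattice is the family-pairwise line intersections.

Cropping walks the piecewise-linear boundary curves between adjacent
lattice points (not global straight lines — this tolerates tray flex) and
assigns every pixel to exactly one cell by counting boundary curves to
its left and above: a true partition, so no plant pixel can be lost or
double-counted. On synthetic trays displaced by up to 3 mm, crossings are
localized within 2 px, and adaptive cropping keeps every blob pixel while
a fixed nominal grid demonstrably clips wall-adjacent plants.

## 4. Germination time and early growth rate

Cotyledon growth is expansion-driven and approximately linear in
projected area; exponential growth begins with the first true leaves. The
pipeline therefore models leaf area as linear immediately after
emergence, exponential later, and extracts:

* **emergence** — first time point with ≥ 10 green pixels (0.013 mm² at
  0.0013 mm²/px), HSV gates hue 60–180°, S > 0.25, V > 0.15 (configurable);
* **germination time** — x-axis intercept of the accepted linear fit;
* **early growth rate** — its slope.

`fit_linear_segment()` performs backward elimination: starting from the
full post-emergence series it removes exactly one trailing point per
iteration (never interior points) until the prefix satisfies **all** of:
adjusted R² > 0.9; slope and intercept each significantly different from
0 (two-sided t-tests at α = 0.05 — a conventional default, the
significance level not being otherwise specified); and deviance/n < 0.1,
where the deviance of the Gaussian linear model is the residual sum of
squares in (mm²)². The longest qualifying prefix wins. The minimum
segment length is 4 points (2 residual degrees of freedom; 3 points would
make the t-tests and adjusted R² degenerate). Criteria are conjunctive
and each is individually necessary — unit tests perturb a qualifying
series to violate exactly one criterion and verify the fit is rejected.
Degenerate outcomes are statuses, not errors: `no-emergence` (no positive
area) and `no-linear-fit` (no qualifying prefix); a negative x-intercept
is clamped to 0 with a flag. In practice such series would go to manual
validation; the status flags stand in for that step. The exponential
phase $A(t) = A_0 e^{rt}$ is fitted over all post-emergence points,
log-linear start refined by Levenberg–Marquardt.

## 5. Batch statistics

* **Release kinematics**: a seed released pneumatically gets
  $a = \pi r^2 p / m$ from overpressure $p$ on the nozzle cross-section
  and reaches $v = \sqrt{2ad}$ (5.1 m/s for 30 mbar, 75 µm, 20 µg, 5 mm —
  fast enough to bounce). The mechanical "hammer" alternative reaches
  $\sqrt{2gh}$ after a ~1 mm fall; an elastic collision with a much
  heavier hammer caps the seed at twice the hammer speed. Both numbers
  are reported; the package asserts nothing about intermediate regimes.
* **Balance-noise simulation**: around each measured value a normal with
  SD = 15 % of the value (the old balance's repeatability), 100 draws
  each; the inflated SD converges to
  $\sqrt{\mathrm{SD}^2 + (0.15\,\mu)^2}$.
* **Minimal n**: smallest equal per-batch $n$ at which the two-sample
  t statistic from the batch distributions exceeds the critical value at
  α = 0.05 two-sided. All t-tests are **Welch** (unequal variances): the
  batch SDs differ markedly, and the Welch form reproduces the published
  15 (new balance) / 28 (inflated) pair, whereas pooled variances would
  give 14 for the first. The resampled counterpart keeps the base batch
  fixed (a deterministic normal-quantile sample rescaled to the summary
  moments) and varies only the noise draws, mirroring a procedure applied
  to one measured dataset; re-drawing the base batch each repetition
  would inflate the mean minimal n by Jensen's inequality, since
  $n \propto 1/\Delta^2$.
* **σ confidence intervals**: single-sample chi-square,
  $\sqrt{(n-1)/\chi^2_{1-\alpha/2,\,n-1}} \le \hat\sigma/\sigma \le
  \sqrt{(n-1)/\chi^2_{\alpha/2,\,n-1}}$; widths 41/28/20 % of σ at
  n = 50/100/200.
* **Density validation**: µg/nl is numerically g/cm³; defaults flag
  densities outside 0.8–1.4 g/cm³ (double pick-ups, broken seeds, carve
  failures).
* **Correlations**: pairwise-complete Pearson with `cor.test` p values
  and three-level stars (* < 0.05, ** < 0.01, *** < 0.001 — the
  conventional reading of the star levels). No multiple-testing
  correction is applied across the matrix, matching common practice for
  exploratory trait matrices; constant traits yield `NA`.

## 6. The synthetic-data generators

The generators define the conditions under which everything above is
tested, and every generator returns machine-readable ground truth.

* `render_silhouettes()` draws orthographic silhouettes of spheres,
  ellipsoids (closed-form projected conic) and superellipsoids (ray
  marching), with analytic volume (gamma-function closed form for
  superellipsoids), quadrature surface area, and orientation-independent
  L/W/H truth. Occlusion truncates all masks above one row, exactly as a
  nozzle does.
* `make_tray_image()` emulates tray misalignment as a rigid displacement
  (translation up to the jitter amplitude, rotation up to ~0.35°, both
  scaled with the amplitude) plus a small per-crossing wobble
  (≤ 15 % of the jitter, capped at 1.5 px) for fabrication inaccuracy and
  flex. Green blobs have exactly the requested pixel count. A pure
  i.i.d. 3 mm jitter of every crossing is deliberately not used: real
  misalignment is dominated by whole-tray displacement, and uniform-pitch
  extrapolation of border lines is only meaningful under that model.
* `make_growth_curve()` produces 0 before germination, a linear rise,
  and an exponential phase matched in value (not slope) at the switch —
  the exponential is fitted to all points in the real pipeline, so a mild
  slope discontinuity is realistic. Defaults are the control-batch
  operating point: germination 3.77 d, rate 1.02 mm²/d, daily sampling
  over 14 d, additive noise SD 0.05 mm², switch at day 8, exponential
  rate 0.5/d. The exponential rate is a realistic Arabidopsis relative
  growth rate once true leaves appear and makes the piecewise structure
  identifiable: the deviance gate cleanly rejects the first exponential
  point, so the zero-noise round trip recovers the generating parameters
  exactly.
* `make_seed_batch()` draws multivariate-normal trait vectors with the
  bundled batch moments and a correlation structure built from a latent
  factor model (guaranteed positive definite): volume loads on three
  size factors, mass tracks volume at r = 0.98, sphericity responds
  negatively to length, germination follows brightness negatively, and
  growth rate couples to mass. Physical traits are floored at a small
  positive value.

What passing tests show — and what they do not: the generators emulate
geometry, sampling and noise structure, not biology or optics. Real
seeds have grooves and concavities that no silhouette method can recover
(the visual hull is blind to them), mucilage and dust affect real
segmentation, soil texture is richer than the generator's noise, leaves
fold and overlap, and real trait distributions are only approximately
normal. Green tests therefore certify the algorithms against known
geometry and known noise, not instrument performance.

## 7. Problem sizes and runtime choices

Unit tests carve at 10 µm voxels (seconds per seed); the oracle checks at
the production setting of 5 µm voxels appear once each. The growth
recovery study uses 200 seeded curves; the resampled minimal-n procedure
uses 1000 repetitions of 100 draws per value; the end-to-end
demonstration runs 2 × 6 seeds at 20 µm voxels. These sizes were chosen
so the full suite documents every claim while remaining comfortable to
run interactively; all of them scale up by changing one argument.

## 8. Known limitations

* Concave features are invisible to the visual hull; volumes of grooved
  seeds are overestimated relative to CT.
* The occlusion extrapolation assumes a locally ellipsoidal cap; highly
  irregular occluded regions will be smoothed over.
* The crossing detector assumes walls brighter than soil and a tray
  filling most of the frame; behaviour on heavily overgrown trays is
  unspecified.
* ID string formats are package-defined (stable, but arbitrary).
* The correlation defaults mirror qualitative published relationships;
  they are not a fitted model of any particular dataset.
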