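---
title: "Methods: EV uptake quantification and EV-mitochondria apposition"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: EV uptake quantification and EV-mitochondria apposition}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette is the package's own account of its methods: the measurement
definitions, the statistical models, the synthetic-data model used to
validate them, and the numerical and design choices that were genuinely
open. Everything quantitative stated here is computed by the package's test
suite or by `scripts/acceptance.R`; nothing is quoted from external data.

## 1. Coordinates, calibration, segmentation

All rasters are indexed 1-based as `(row, col)` with row increasing
downward — R's native matrix convention; every geometric rule below is
invariant to that choice of origin. A `calibrated_image` carries its pixel
size in nanometres, and **the calibration must be supplied by the user**:
nm-scale distances are meaningless without it, TIFF resolution tags are
frequently wrong in re-exported microscopy files, and silently defaulting
would corrupt every downstream number. There is deliberately no default.

Segmentation is plain intensity thresholding after an optional Gaussian
pre-smooth (sigma in pixels, default 1 px for punctum channels, 2 px for the
soma marker):

* `otsu` (default): exhaustive maximization of between-class variance over
  the 255 interior edges of a 256-level grid spanning the intensity range,
  with exact class statistics (per-bin sums of the actual intensities rather
  than bin midpoints). The implementation is tested against a brute-force
  scan of all candidate levels.
* `percentile`: a type-1 (inverse-ECDF) quantile, so "the top 1% of pixels"
  means exactly the pixels above that order statistic.
* `absolute`: a fixed intensity, the override path for per-image manual
  optimization. Every mask records the numeric threshold actually used, and
  the pipelines write those values to a JSON-lines run log, so per-image
  "optimized" thresholds remain auditable.

Connected components use 8-connectivity by default (4 available):
punctate and filamentous structures are the targets, and 8-connectivity is
the conservative choice for not splitting diagonal filament steps. Labels
are assigned in deterministic raster-scan order. Particle measurements
follow common regionprops conventions: intensity-unweighted centroid, area
in px and µm², solidity as pixel area over the convex-hull area of the pixel
squares, eccentricity from the second central moments of pixel centres.

Punctum filtering defaults — area 0.03–1.5 µm², solidity ≥ 0.6,
eccentricity ≤ 0.98 — select diffraction-limited to small puncta and reject
elongated fragments of labelled processes. They are config values, not
claims about any particular dataset.

Soma detection adds morphological opening and closing (disc radius 2 px),
hole filling, and a minimum area of 50 µm² (a conservative floor for large
neuronal somata; debris and dendritic fragments fall well below it). Manual
curation of detected somata is reproduced as an explicit include-list of
label ids in the configuration — never an interactive step — so a curated
analysis replays bit-for-bit.

## 2. Edge-to-edge distance and contact

For a punctum P and organelle mask M, let `d_px` be the minimum over P's
pixels of the exact Euclidean distance transform of M (distances between
pixel centres; `EBImage::distmap`, verified exact against an all-pairs
brute force). Then:

* **contact** (0 nm) if P overlaps M or is 8-adjacent to it
  (`d_px ≤ √2`): adjacent pixels have zero boundary separation;
* otherwise `d_edge = (d_px − 1) · pixel size` — subtracting one pixel
  converts the centre-to-centre minimum into the boundary gap between
  pixel squares.

This realizes "minimum boundary separation, 0 nm = contact" on a pixel
grid: five single-pixel puncta at background gaps of 1–5 px from an
organelle bar at 31 nm/px measure 31, 62, 93, 124, 155 nm (mean 93 nm)
exactly. Distances are 2-D; axial (z) offsets are invisible to this
measure, a stated limitation for thick samples. Centroid-to-nearest-
organelle-pixel distances are also reported but play no role in binning.

## 3. Monte Carlo proximity null

The null hypothesis is that punctum positions are uninformative about the
organelle. Each iteration rigidly translates every punctum's *segmented
pixel shape* to a centroid drawn uniformly over the pixels of the cellular
ROI at which the whole shape stays inside the ROI; the organelle mask never
moves, and overlap with the organelle is permitted (observed puncta may
overlap it, so forbidding overlap would bias the null away from
proximity). Shapes are preserved but not rotated — the most conservative
reading of "random placement with organelle geometry preserved". The test
is one-sided toward proximity (smaller mean edge distance, or larger
fraction within a threshold), with the add-one empirical p-value
`(1 + #extreme)/(1 + N)`, which is never zero and makes `p = 1/(N+1)` the
attainable floor (hence "p < 0.0001" requires the 10,000-iteration pooled
setting). Defaults: 1,000 iterations per image, 10,000 for pooled binned
enrichment; per-image RNG substreams are derived deterministically from the
master seed, so runs are bit-reproducible and image-parallel-safe.

The per-image statistic is the mean edge distance; the pooled statistic is
the cumulative bin fraction (both are available and are always named in the
output). Whether a bin "within 100 nm" includes contact particles is
resolved by using cumulative `≤` semantics throughout, which subsumes
contact.

The ROI bounding the randomization must come from somewhere. Three
strategies are provided: a thresholded-and-filled membrane channel; a
user-supplied mask; and the default, the convex hull of the union of the
organelle and punctum masks dilated by 20 px — computable from the analysed
channels alone. The hull is the weakest assumption that keeps random
placements inside "where this cell's structures are"; its 20 px margin
(1.3 µm at 65 nm/px) loosens the hull without flooding empty background.
Calibration of the whole construction is checked empirically: on 500
null-generated images the test rejects at nominal α = 0.05 within ±0.02.

## 4. Distribution shape: bimodality coefficient and mixture selection

Sarle's bimodality coefficient is computed from the bias-corrected
(type-2) sample skewness and excess kurtosis,
`BC = (g₁² + 1) / (g₂ + 3(n−1)²/((n−2)(n−3)))`. The conventional decision
threshold 0.555 is (to three decimals) the uniform-distribution benchmark
5/9, which identifies this as Sarle's formula; the package verifies that a
10⁵-point uniform sample lands within ±0.005 of it. Because the threshold
*is* the uniform value, a sample at the benchmark is borderline by
construction, and the binary call there is not meaningful — only clear
exceedances are.

Mixture comparison fits 1- and 2-component Gaussian mixtures.
The 1-component fit is closed-form (mean, biased variance). The
2-component fit is EM with a deterministic below/above-median start plus 10
random-responsibility restarts, keeping the best log-likelihood;
tolerance 10⁻⁶ on the log-likelihood, at most 500 iterations per start, and
component variances floored at `(10⁻⁶·sd)²` to prevent collapse onto a
single point. EM on genuinely one-component data often plateaus without
meeting the tolerance (the weight split is weakly identified); the fit then
warns and returns the best iterate, which is the documented behaviour, not
an error. `BIC_k = −2·loglik + p_k·log(n)` with `p₁ = 2`, `p₂ = 5` free
parameters; `ΔBIC = BIC₂ − BIC₁ < 0` selects two components. On
one-component Gaussian samples (n = 500) the two-component model is
selected in well under 10% of seeds; on a well-separated 71%/29% mixture
with peaks at 440 and 2776 nm (sd 200 nm), the recovered means land within
5% and ΔBIC is strongly negative. The package's EM is cross-checked against
an independent implementation (mclust) on that mixture.

Correlation p-values use the exact two-sided t-transform
(`t = r√((n−2)/(1−r²))`, n−2 df), and `correlation_p_value(r, n)` exposes
the transform for recomputing a p from a reported `(r, n)` pair. One
caveat such recomputation inherits: a 3-decimal-rounded r near zero cannot
pin the p to 4 decimals (at n = 32, r = −0.040 gives 0.8279, while any
unrounded r near −0.0397 gives 0.8282), so agreement beyond ~3 decimals is
not expected for small |r|. Mann–Whitney uses exact enumeration when
`n₁·n₂ ≤ 400` with no ties, otherwise the normal approximation with
mid-rank tie correction and continuity correction; Fisher's exact test sums
hypergeometric point probabilities not exceeding the observed table's. Both
are verified against full enumeration for all group sizes with
`n₁ + n₂ ≤ 10`. No multiple-testing adjustment is applied — the analyses
report two correlations and a handful of planned comparisons.

## 5. The synthetic-data model

The generator emulates three image classes, each paired with exhaustive
ground truth (masks, per-punctum true distances, per-soma true counts):

* **Apposition fields** (default 256 px at 65 nm/px): the mitochondrial
  network is a union of dilated self-avoiding random walks (8-neighbour,
  direction-persistent, stopping early if boxed in) — filamentous geometry
  with tunable density, which is all the spatial statistics need. Puncta
  (discs, default radius 2 px ≈ 260 nm) are placed by a *distance plan*:
  exact pixel gaps, an exact contact fraction with a far-distance range, or
  a Gaussian mixture of target distances. Placement is validated with the
  same edge-distance definition the analysis uses, so planned truth is
  exact by construction; the equality of generator truth and analysis
  output on every generated field is the suite's central anti-drift test.
* **Soma fields** (default 512 px at 200 nm/px, 10 somata/image, semi-axes
  8–12 × 6–9 µm): per-soma punctum counts follow a zero-inflated model —
  with probability π = 0.67 the count is shifted-Poisson with mean
  µ⁺ = 4.2/0.67 ≈ 6.27, else zero — because a positive-cell fraction of
  0.67 is incompatible with a plain Poisson at overall mean 4.2 (which
  would leave only ~1.5% of cells empty). π·µ⁺ = 4.2 is the cohort mean.
  Puncta are single-pixel-scale discs (radius 1 px = 400 nm at this scale)
  kept ≥ 2 px inside the soma boundary, with > 4 px background gaps between
  puncta and > 8 px between somata so that the PSF blur cannot merge
  distinct objects above threshold — separations a well-sampled confocal
  field of sparse EV puncta satisfies.
* **Rendering**: background 100 ADU, structure amplitude 900 ADU, Gaussian
  PSF sigma 1 px, Poisson shot noise at 1 photon/ADU, Gaussian read noise
  sd 10 ADU, clipped at zero and quantized to integers (so 16-bit TIFF
  round trips are bit-exact). This emulates a well-exposed, deconvolved
  confocal image; peak SNR ≈ 30.

What passing tests on these data do **not** show: robustness to uneven
illumination, autofluorescent debris, punctum clumping at densities where
blur merges neighbours, anisotropic PSFs, or 3-D effects — none of which
the generator models. The synthetic validation demonstrates correctness of
the measurement and inference machinery under its stated assumptions, not
segmentation robustness on difficult real micrographs; on real data the
per-image threshold override and the audit log are the tools for the
former.

## 6. Problem sizes and determinism

The test suite and `scripts/acceptance.R` use sizes chosen to give each
check real statistical teeth while staying desk-scale: 500 somata
(50 fields × 10) for parameter recovery (recovered mean within 5% of 4.2,
positive fraction within 3 points of 67%); 500 null images for type-I
calibration of the Monte Carlo test (rejection rate within ±0.02 of
α = 0.05 at 199 iterations); 100 random fields for the all-pairs distance
oracle; full enumeration of rank and contingency tests up to n₁+n₂ = 10;
10⁵ points for the uniform BC benchmark. Every stochastic step takes an
explicit seed; pipelines derive per-image substreams from one master seed,
and rerunning any pipeline with the same configuration and seed reproduces
all numeric outputs bit-for-bit (asserted in the suite). Configuration
hashes and seeds are embedded in every artifact.

## 7. Known limitations

* Distances, areas and the randomization null are strictly 2-D; projected
  stacks conflate axial separation with contact.
* The contact rule is resolution-bound: anything below one pixel of
  boundary separation reads as 0 nm, so "contact" at 65 nm/px means
  "≤ ~65 nm", far above molecular tether scales.
* The hull ROI is a modelling choice; for cells whose silhouette is far
  from convex (strongly ramified cells) a membrane-channel or user mask is
  the better strategy.
* The mixture machinery stops at two components, and BC is a coarse screen:
  a contact spike plus any far tail can read as "bimodal" even when the far
  tail is a single population.
* Watershed splitting of touching somata is out of scope; curation of
  merged detections goes through the selection list.
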