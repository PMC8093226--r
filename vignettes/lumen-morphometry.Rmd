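---
title: "Gland-lumen morphometry for biochemical-recurrence prognosis: models, parameters, and design choices"
author: "lumenmorph authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Gland-lumen morphometry: models and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem and the pipeline

After radical prostatectomy, a rising serum PSA (two tests above 0.2 ng/mL —
biochemical recurrence, BCR) is the earliest sign that treatment failed.
`lumenmorph` implements an image-based prognostic pipeline built on a single
observation: the geometry and spatial arrangement of *gland lumens* — the
near-white open spaces of prostatic glands on an H&E slide — carry prognostic
signal. The pipeline is:

1. **Resolution normalization**: the region image is resampled to exactly
   1 µm/px (bilinear), so every downstream measurement is in microns.
2. **Lumen segmentation**: a classical baseline (stain deconvolution,
   Otsu-thresholded luminance inside the annotation, speckle removal, hole
   filling, area and centroid-membership filters) behind a pluggable
   interface; ground-truth label masks can bypass segmentation entirely.
3. **Feature extraction**: a fixed 242-feature catalog per region
   (96 shape + 52 global architecture + 68 proximity sub-graph features from
   the lumen polygons = 216 morphology/architecture features, plus 26
   Haralick texture features computed from the region pixels while
   *disregarding* the segmentation).
4. **Stability filtering**: features whose distributions on non-cancerous
   regions differ across contributing sites are removed before modeling.
5. **Risk modeling**: elastic-net penalized Cox regression (α = 0.5, λ by
   seeded 10-fold cross-validated partial-likelihood deviance, Breslow
   ties) on z-normalized features; the linear predictor is mapped through a
   logistic to a bounded [0, 1] score and thresholded into low/high risk.
6. **Evaluation and robustness**: Kaplan–Meier/logrank, hazard ratios,
   Harrell's c-index with paired bootstrap, multivariable Cox tables,
   Bonferroni-corrected subgroup analysis, a boundary-erosion sensitivity
   experiment, and a batch-effect embedding audit.

A six-feature reference model ships with the package
(`published_model()`): five lumen-shape aggregates and one sub-graph
arrangement feature, with per-SD weights given as logs of per-feature
hazard ratios. Because per-SD weights are meaningless without the original
normalization, this model refuses to score until the user supplies a
reference cohort (`set_normalization()`).

## The feature catalog

**Shape (96).** Each lumen polygon contributes 24 dimensionless
descriptors; the region aggregates each with four statistics
(mean, SD, median, p5/p95 ratio), names `shape:<stat>:<descriptor>`:

- `fd1..fd10`: Fourier descriptors of the centroid-distance signal. The
  boundary is resampled at 128 equal-arclength points (a power of two that
  resolves 30–300 µm lumens); FD*k* = |F<sub>k</sub>|/|F<sub>0</sub>|.
  The centroid-distance form (rather than complex coordinates) plus
  DC-normalization gives invariance to rotation, starting point, and scale.
- `hu1..hu7`: Hu invariant moments of the filled polygon, computed
  **exactly** from the vertex list with Green's-theorem closed forms —
  not from a raster. This makes rotation invariance exact to machine
  precision and needs no resolution knob. Values are signed-log
  compressed, `sign(m)·log10(1 + |m|·1e6)/6`, for numeric stability
  (config switch returns raw values).
- Ratios: mean/max centroid distance (`distance_ratio`), SD/mean radius,
  polygon/convex-hull area, hull/polygon perimeter, boundary smoothness,
  and circularity (4πA/P²).
- `fractal_dim`: a divider (compass) dimension — the boundary is walked
  with rulers at a geometric ladder of lengths and the dimension is the
  log–log slope, clamped to [1, 2]. The divider estimator uses inter-point
  distances only, so it is invariant to rigid motion by construction,
  where grid box counting is not; ruler comparisons carry a 10⁻⁹ relative
  tie tolerance so exactly-tied geometries (regular polygons) are stable.

The 24-descriptor list is this package's normative catalog; it contains
every shape descriptor used by the reference model. The p5/p95 statistic is
the *ratio* of the linear-interpolation percentiles (p95 = 0 yields the
missing sentinel); a config switch can change it to the p95−p5 range.
Fourier descriptor indices are 1-based (FD1 = first non-DC harmonic).

**Global architecture (52).** On lumen centroids: Voronoi cells (area,
perimeter, max chord) clipped to the annotation polygon — unbounded cells
are otherwise undefined; Delaunay edge lengths and triangle areas; MST edge
lengths; 1st/3rd/5th nearest-neighbor distances; local density (gland
counts in 50/100 µm disks, local lumen-area fraction) — each with the four
aggregation statistics — plus four region scalars (gland count, glands/mm²,
lumen area fraction, median lumen area). No computational-geometry package
is available in the target environment, so the Delaunay triangulation is a
Bowyer–Watson implementation and each Voronoi cell is the intersection of
bisector half-planes with the annotation polygon; both are oracle-tested
(empty-circumcircle property; exhaustive spanning-tree enumeration;
tessellation area conservation). Voronoi clipping assumes a convex
annotation; non-convex annotations are handled but may produce degenerate
zero-width bridges in extreme cases.

**Proximity sub-graphs (68).** Connected components of the ε-neighborhood
graph with ε = 2.0 × median 1-NN distance (config) — data-adaptive so the
construction is scale-free across gland densities. 17 metrics (pooled edge
lengths, pooled degrees, and 15 per-component topology/geometry metrics)
are aggregated by mean, SD, skewness (g1) and Fisher excess kurtosis (g2,
moment estimators, 0 by convention at zero variance).
`subgraph:kurtosis:edge_length` — the arrangement feature of the reference
model — is the excess kurtosis of all edge lengths pooled across
components.

**Texture (26).** Luminance inside the annotation is quantized to 32 gray
levels; symmetric normalized co-occurrence matrices at distance 1 px for
the four standard angles; the 13 classical Haralick statistics, summarized
by their mean and range across angles. Entropies use the natural log with
0·log 0 = 0; correlation is 0 by convention when a marginal variance
vanishes. Regions under 64×64 µm² yield sentinels.

Degenerate regions (fewer than 3 glands, missing image) never crash the
pipeline: affected features carry an `NA` sentinel and are excluded
pairwise downstream.

## The synthetic cohort generator

Everything is testable without clinical data via `simulate_cohort()`:

- **Lumens** are star-shaped polar forms — disks, ellipses, and crescents
  (a disk with a Gaussian radial notch, width 0.8 rad; chosen over boolean
  disk differences because the star-shaped form is simple by construction
  and needs no polygon-boolean library) — with smooth radial boundary
  noise, random rotation, and exact equivalent-diameter rescaling.
- **Placement** follows an inhomogeneous Poisson process with a
  kernel-smoothed log-Gaussian intensity field (the `density_heterogeneity`
  knob is the field's marginal SD) and a minimum centroid spacing of
  1.2 × mean lumen diameter.
- **Rendering** draws near-white lumens on textured pink stroma at
  1 µm/px on a 1024×1024 px default canvas; per-site stain presets
  perturb stroma hue and brightness to emulate scanner/staining batch
  effects. The label mask is the exact polygon rasterization.
- **Outcomes**: a Weibull proportional-hazards model (default shape 1.5,
  scale 8 years — a realistic post-prostatectomy BCR time scale) with
  linear predictor η = Σ wᵢzᵢ over standardized per-patient knobs
  (default: weight 1 on disk fraction, echoing the association between
  disk-shaped lumens and elevated risk). Censoring is administrative,
  Uniform(0, t_max), with t_max calibrated by Monte-Carlo inversion to the
  requested censoring fraction (default 0.5). Synthetic clinical
  covariates (grade group, PSA, margins, stage) and a synthetic
  genomic-classifier score are drawn correlated with η.
- Fixing `seed` reproduces the cohort bit-identically.

What the generator does **not** emulate: nuclei and epithelium, touching
glands, real stain spectra, annotation errors, or tissue artifacts
(folds, blur, pen marks). Passing tests therefore demonstrate the
pipeline's internal correctness and its statistical behavior under known
ground truth — not clinical performance on real slides.

## Modeling choices that were genuinely open

- **Score scale.** The bounded score is `plogis(lp)`. The original score
  scale behind "per 0.1 increase" reporting is not fixed by any external
  constraint; the logistic is monotone, bounded, and centers the training
  mean at 0.5.
- **Threshold rule.** The low/high cut maximizes the logrank χ² over every
  observed training score between the 10th and 90th percentiles, ties
  resolved to the lower cut; a median-split alternative is config-exposed.
  At the threshold itself the category is *low* (strict inequality).
- **Stability statistic.** Max pairwise two-sample Kolmogorov–Smirnov
  statistic across sites with a fixed cutoff τ = 0.4 (config), computed on
  non-cancerous regions; KS is distribution-free, rank-based (invariant to
  monotone per-feature rescaling), and sample-size-robust, unlike p-value
  thresholds. Sites contributing fewer than 10 regions are excluded.
- **Batch-effect audit.** The two-dimensional embedding is a deterministic
  principal-component projection of the standardized feature matrix, and
  the mixing score is the mean silhouette width of site labels in the
  embedding (high = site clustering, near zero/negative = good mixing).
  A linear deterministic embedding keeps the audit exactly reproducible
  across platforms with no stochastic layout stage; the site-clustering
  contrast it measures (image metrics cluster by site, morphometric
  features do not) does not depend on a nonlinear embedding.
- **Erosion rule.** "Remove the outer layer of glands" is operationalized
  as removing every lumen whose centroid lies on the convex hull boundary
  of all centroids — exactly the glands whose unclipped Voronoi cells are
  unbounded, which makes the rule oracle-testable. The annotation is then
  replaced by the hull of the remaining centroids dilated by the median
  remaining lumen radius, so region-level (texture, density) features
  shrink consistently. Patients whose regions empty carry their last valid
  score forward, flagged. Gland-topological removal was chosen over
  geometric annotation erosion; both readings are defensible, this one is
  deterministic and scale-free.
- **Segmentation cleanup.** Speckle removal uses opening *by
  reconstruction* (erosion with a 2 px-radius disk selects components;
  survivors keep their exact pixels). A plain opening rounds every
  boundary and measurably biases the high-order Fourier descriptors of
  segmented versus ground-truth lumens; reconstruction removes the same
  debris without touching surviving shapes. Minimum lumen area is
  40 µm² (config; no maximum).
- **BCR labeling.** Event at the second PSA strictly above 0.2 ng/mL
  (tests need not be consecutive); censoring at the last test; patients
  without a test ≥ 30 days post-surgery are excluded with a reason code.
- **Genomic-score categories.** Low < 0.45, high > 0.60, the closed
  interval [0.45, 0.60] intermediate; a merged mode pools low and
  intermediate.
- **c-index conventions.** Harrell's original: pairs are comparable iff
  the smaller observed time is an event; score ties count ½; higher score
  means higher risk.

## Numerical conventions

Coordinates are real-valued microns, origin at the image top-left, x
rightward, y downward; pixel (i, j) (0-based) has center
((j+0.5)·mpp, (i+0.5)·mpp). "Counterclockwise" means positive shoelace
area in these coordinates. Percentiles are linear-interpolation (type 7).
Sample SD uses n−1 (0 for a single value). Masks are 16-bit single-channel
TIFF labels; annotations are GeoJSON polygons in microns; features and
clinical tables are CSV. Zero-variance spreads below a 10⁻¹⁰ relative
floor are treated as exactly zero for the skewness/kurtosis conventions.

## Problem sizes used by the test-suite and acceptance script

The package's own experiments run at desk scale, chosen as the smallest
sizes at which each statistical property is stable: parameter-recovery
simulations use n = 300–500 with 25–50 replicate seeds; the end-to-end
simulate → extract → train → evaluate experiment uses a 400-patient cohort
(15–40 glands per region on a 640 µm canvas, disk-fraction-driven risk,
40% censoring) split 200/200 into training and validation; the erosion
experiment uses 30 gland-rich patients (90–130 glands per region, so that
ten boundary layers leave an interior) over 10 layers; the batch audit
renders 21 regions across 3 stain presets. Feature extraction is geometry-only where
texture is not needed (the reference model uses only shape and sub-graph
features), which keeps these experiments fast.

## Known limitations

- The classical segmenter expects near-white lumens on stained stroma; it
  is adequate for clean tiles and the synthetic renderer, not for
  artifact-ridden whole-slide images. Any segmenter can be plugged in, and
  ground-truth masks bypass it.
- The published six-feature model cannot reproduce its source-cohort
  hazard ratios without that cohort's normalization; it is usable only
  with user-supplied reference statistics.
- Voronoi clipping assumes a convex annotation polygon.
- The sub-graph metric list and the 24-descriptor shape list are normative
  reconstructions fixed by this package so that catalog counts are exact
  and testable.
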