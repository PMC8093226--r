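# lumenmorph

Quantitative gland-lumen morphometry for biochemical-recurrence (BCR)
prognosis after radical prostatectomy.

Prostate cancer outcome after surgery is usually anticipated from Gleason
grade, stage, margins and PSA — or from costly molecular assays. This
package implements an image-based alternative: from a single annotated
tumor region on an H&E slide it segments the gland **lumens** (the
near-white open spaces of prostatic glands), measures their shape and
spatial arrangement, and turns those measurements into a risk score for
time-to-BCR. A synthetic pseudo-H&E cohort generator with ground-truth
geometry and survival outcomes makes the entire pipeline testable without
clinical data.

It is intended for computational-pathology researchers who want a fully
inspectable, scriptable reference pipeline: every stage (segmentation,
features, stability filtering, model, evaluation, robustness experiments)
is an exported R function with a pinned numerical convention.

## The model

Each tumor region is reduced to a fixed 242-feature vector:

| block | count | contents |
|---|---|---|
| shape | 96 | 24 per-lumen descriptors (Fourier descriptors FD1–FD10 of the centroid-distance signal, Hu moments φ1–φ7, radius/convexity ratios, divider fractal dimension) × {mean, SD, median, p5/p95} |
| global architecture | 52 | Voronoi / Delaunay / MST / nearest-neighbor / local-density statistics on lumen centroids |
| sub-graph | 68 | 17 metrics of ε-neighborhood graph components × {mean, SD, skewness, excess kurtosis} |
| Haralick texture | 26 | 13 GLCM statistics (32 levels, distance 1, 4 angles) × {mean, range across angles} |

Features that survive a cross-site stability filter (max pairwise
two-sample Kolmogorov–Smirnov statistic on benign-region distributions,
cutoff τ = 0.4) enter an elastic-net penalized Cox model of time-to-BCR:

&nbsp;&nbsp;&nbsp;&nbsp;argmin<sub>β</sub> −ℓ<sub>partial</sub>(β) + λ [ α‖β‖₁ + (1−α)‖β‖₂²/2 ],&nbsp; α = 0.5,

with λ from seeded 10-fold cross-validated deviance, on z-normalized
features (so each βₓ is a per-SD log hazard ratio, HRₓ = e^βₓ). The linear
predictor is mapped through a logistic to a score in [0, 1] and cut into
low/high risk at a threshold that maximizes the training logrank χ². A
six-feature reference model with published per-SD hazard ratios ships as
`published_model()`; it requires user-supplied normalization before
scoring. Evaluation covers Kaplan–Meier/logrank, hazard ratios, Harrell's
c-index with paired bootstrap comparison, multivariable Cox tables,
Bonferroni-corrected subgroup analysis, a gland-layer boundary-erosion
sensitivity experiment, and a batch-effect embedding audit.

## Worked example

```r
library(lumenmorph)

# 1. simulate a cohort: disk-shaped-lumen fraction drives the hazard
spec <- cohort_spec(n_patients = 200, seed = 7, canvas_um = 640,
                    risk_weights = c(disk_fraction = 1), censor_rate = 0.4)
co <- simulate_cohort(spec)

# 2. extract the 242-feature catalog for every region
X  <- cohort_features(co$lumen_sets)
dim(X)
#> [1] 200 242

# 3. train on the first half, score the second
ok <- apply(X, 2, function(v) all(is.finite(v)))
tr <- 1:100; va <- 101:200
m  <- fit_elasticnet_cox(X[tr, ok], co$clinical$time[tr],
                         co$clinical$event[tr], seed = 7)
m  <- set_threshold(m, learn_threshold(risk_score(m, X[tr, ok])$score,
                                       co$clinical$time[tr],
                                       co$clinical$event[tr]))
sc <- risk_score(m, X[va, ok])

# 4. evaluate the stratification on the validation half
rep <- evaluate_stratification(sc$category, sc$score,
                               co$clinical$time[va], co$clinical$event[va],
                               B = 1000, seed = 7)
rep
#> <eval_report> logrank p = 0.135, HR = 1.70 (0.84-3.43), c-index = 0.672 (0.604-0.736)
```

The c-index (0.67 here) is the probability that, of two comparable
held-out patients, the one with the higher score recurs first; its
bootstrap CI excludes 0.5, so the continuous score is clearly prognostic
on this synthetic cohort. The dichotomized low/high split is noisier at
this sample size (HR 1.70 with a wide CI at this seed) — thresholding
discards information, which is why the package evaluates both. Under a
null generator (no knob carries risk) the same pipeline gives a c-index
near 0.5.

A thin command-line dispatcher over these functions is installed at
`inst/cli/lumenmorph.R` with subcommands `simulate`, `segment`,
`features`, `filter-stability`, `train`, `score`, `evaluate`, `erode`,
`audit`; every subcommand takes `--seed` and a `--config` YAML that can
override any numeric constant of the pipeline.

## Method vignette

`vignettes/lumen-morphometry.Rmd` documents the model, every tunable
parameter with its default and rationale, what the synthetic generator
does and does not emulate, the numerical conventions, and the design
decisions that were genuinely open.
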