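---
title: "Methods: NMF metafeatures from CT radiomics for BCG-response prediction"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: NMF metafeatures from CT radiomics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(radnmf)
```

## The problem and the pipeline

High-risk non-muscle-invasive bladder cancer is treated with BCG
instillation after transurethral resection, but a substantial minority of
patients fail therapy within a year. With only a handful of failures in a
typical single-centre cohort, supervised radiomics classifiers overfit
badly. The approach implemented here sidesteps supervision in the
high-dimensional step: radiomics features extracted from the pretreatment
CT lesion are decomposed by *nonnegative matrix factorization* (NMF) into a
few metafeatures — nonnegative linear combinations of features, analogous
to metagenes in expression analysis — and only the final, one-dimensional
step (picking the metafeature most associated with recurrence) touches the
outcome.

The pipeline is: extract → filter → scale → factorize → select → evaluate.

1. **Extraction** (`extract_all()`): the volume is resampled to a common
   spacing (trilinear for intensities, nearest-neighbour for the mask),
   ROI intensities are discretized with a fixed bin width, and 107
   "original image" features are computed: 14 shape, 18 first-order, 24
   GLCM, 16 GLRLM, 16 GLSZM, 14 GLDM, 5 NGTDM.
2. **Preprocessing** (`filter_collinear()`, `scale_unit()`): features with
   pairwise Pearson |r| above a threshold are removed greedily; survivors
   are min-max scaled to [0, 1], the nonnegative domain the factorization
   requires.
3. **Factorization** (`nmf_rss_curve()`, `select_rank()`,
   `nmf_best_fit()`): multiplicative-update NMF under the Frobenius
   objective, restarted per rank from seeded random initializations; the
   rank is the inflection of the best-RSS curve.
4. **Selection** (`standardize_scores()`, `select_component()`): each
   z-scored score row enters a univariate Cox model; the row with the
   highest Harrell C-index is the biomarker.
5. **Evaluation** (`evaluate_scores()`): ROC/AUC, Youden or frozen cutoff,
   confusion metrics, Kaplan–Meier with log-rank, Breslow-baseline
   calibration, decision-curve net benefit, and ICC for segmentation
   reproducibility.

A trained model scores new cohorts without refitting
(`run_validation()`): frozen feature list, frozen min-max parameters,
nonnegative least-squares projection onto the trained loadings, frozen
z-standardization, frozen component index and cutoff. The training cohort
itself is scored through the same projection map, so validating a model on
its own training data reproduces the training report exactly — a cheap,
strong consistency check.

## Tunable parameters

| Parameter | Default | Why |
|---|---|---|
| `target_spacing` | 1 x 1 x 2 mm | CT in-plane resolution is finer than the slice spacing; 1 x 1 x 2 mm preserves that anisotropy while putting all acquisitions on one grid. Centimetre-scale voxels would be larger than most bladder lesions. |
| `bin_width` | 25 HU | The de-facto default of fixed-bin-width CT discretization; soft-tissue ROIs spanning a few hundred HU yield 5–20 levels, enough for stable texture matrices at typical lesion sizes. |
| `r_threshold` | 0.90 | "High collinearity" is read as |r| > 0.9 Pearson; exposed in `run_config()` because the exact rule is a modelling choice, not an estimate. |
| `k_min..k_max` | 2..10 | The candidate-rank grid scanned for the RSS inflection. |
| `n_restarts` | 100 | Restarts per rank; NMF is sensitive to initialization, and best-of-100 makes the per-rank RSS reproducible in practice. Small matrices need far fewer (tests use 4–20). |
| `max_iter`, `tol` | 2000, 1e-6 | Multiplicative updates stop on relative RSS change; these converge on all synthetic suites. |
| `cutoff` | `"youden"` | Maximizes sensitivity + specificity − 1 on training z-scores; a fixed value (e.g. 0.2) can be frozen instead and reused in validation. The boundary is inclusive: score ≥ cutoff calls a failure. |
| `horizon_months` | 12 | The binary endpoint is failure within one year of starting BCG. |
| `n_bins` | 3 | Calibration bins; quantile bins keep every bin populated in cohorts of 24–104. |

## The synthetic-data generator

`make_phantom()` produces spheres, ellipsoids and "textured blobs"
(ellipsoids with a smooth angular boundary modulation and a smooth interior
intensity texture) on a voxel grid with configurable spacing, Hounsfield
levels and additive noise. Mask voxels are exactly those whose centre lies
inside the analytic surface, so mask volumes converge to the analytic
volume as spacing shrinks — the oracle used by the shape tests.

`make_cohort()` emulates the statistical structure the analysis assumes:

* `V = W_true H_true + noise`, with `W_true` sparse and nonnegative
  (unit-norm columns) and `H_true` gamma-distributed scores. Component
  supports are consecutive blocks of a random feature permutation, so the
  planted components are nearly disjoint and carry comparable energy; that
  near-orthogonality is what makes the planted rank identifiable from the
  RSS curve. Noise is Gaussian truncated at zero (clipping), which keeps
  the planted linear structure while guaranteeing nonnegativity — a
  lognormal alternative would confound the factors' scale.
* Failure follows an exponential proportional-hazards model on the
  z-scored scores of one designated component, with administrative
  censoring — the simplest process satisfying the proportionality the
  selection step assumes. The baseline hazard is calibrated by root
  finding so the expected fraction of failures before the horizon matches
  a target (defaults: 104 samples at 11%, validation-like cohorts 24 at
  46%; censoring at 36 months, matching a two-to-three-year follow-up).
* A validation draw can reuse the training draw's `W_true` (`truth =`),
  modelling a second cohort from the same population; scores, noise and
  outcomes are fresh.
* Every random quantity derives from a single integer seed through a
  deterministic seed-derivation chain; no global RNG state is consumed.

What the generator does *not* emulate: scanner physics and reconstruction
artefacts, inter-observer segmentation variability, multi-lesion anatomy,
non-proportional or time-varying hazards, and any real correlation
structure between radiomics families. Passing tests therefore demonstrate
the pipeline's correctness and its behaviour under its own assumptions,
not clinical performance on real CT data.

## Numerical choices

* **Feature definitions** follow the IBSI-style "original image" set used
  by the standard open-source CT radiomics extractors: texture matrices are
  built over the grey levels present in the ROI, feature weights use the
  actual bin numbers, GLCM/GLRLM aggregate over the 13 unique 3D
  directions at distance 1 (symmetric co-occurrences), and
  GLSZM/GLDM/NGTDM use 26-connectivity. Implementations are validated
  against analytic limits, hand enumerations and naive brute-force oracles
  in the test suite.
* **Degenerate ROIs** (one voxel, one grey level) return closed-form
  values — entropies 0, GLCM correlation 1 — never `NaN`, with a warning.
* **Surface mesh**: shape features triangulate the binary mask by marching
  cubes at iso-level 0.5, with vertices at edge midpoints. Such meshes
  overestimate the area of smooth surfaces by a few percent (a staircase
  effect that does not vanish with resolution), so a digital sphere scores
  sphericity ≈ 0.91 rather than 1.0. The bias is shared by the standard
  extractors on binary masks; tests assert the honest bound.
* **Discretization** is min-referenced (`floor((I − min)/w) + 1`), which
  makes every texture family exactly invariant to adding a constant to the
  image.
* **NMF initialization** draws `W`, `H` uniform on (0, 1] scaled by
  `mean(V)`; restart seeds derive deterministically from the master seed
  and the (rank, restart) index, so RSS curves are bit-reproducible.
  W-column normalization pins the score scale. Rank ties break toward the
  smaller rank; a flat RSS curve returns the smallest rank with a warning.
* **Restarts are per rank** ("repeated" factorization is read as restarts
  for each candidate rank, the reading that makes best-RSS curves
  comparable across ranks); the restart count is exposed in the
  configuration.
* **Validation scores are projections**, not refits: per-sample
  nonnegative least squares against the trained `W`. Refitting on the
  validation cohort would leak validation information into the factors and
  break the frozen-parameter contract.
* **Cox fitting** uses the Efron tie correction by default because
  month-granularity follow-up produces heavy ties (Breslow by flag), stops
  at |Δβ| < 1e-8 or 50 iterations, and caps |β| at 20 with a separation
  flag when the partial likelihood is monotone. Component selection uses
  the training cohort only; if the winning component's C-index is below
  0.5 its sign is flipped so that higher score means higher risk, and the
  flip is recorded in the model.
* **C-index comparability** follows the strict rule: a pair is usable when
  the earlier time is an observed event and the times differ; score ties
  count one half.

## Known limitations

* The 107-feature set corresponds to 75 texture features plus 14 shape and
  18 first-order; descriptions that count "68 texture features" (summing
  to 100) refer to a different accounting and are not reproducible from
  the standard set. This package fixes the contract at 107.
* End-to-end rank recovery on synthetic cohorts is weaker than raw-matrix
  rank recovery: the collinearity filter preferentially removes the
  strongest (most correlated) planted features and min-max scaling then
  amplifies the noisy survivors, flattening the RSS elbow. The selected
  *component* — the quantity the analysis actually reports — is recovered
  robustly even when the selected rank misses the planted one. The test
  suite asserts rank recovery on the generated matrix and component
  recovery end to end.
* Problem sizes in the test suite are chosen for fast, deterministic runs
  (cohorts of 24–104 samples, 20–54 features, rank grids to 10, 4–20
  restarts, 20-replicate stochastic checks); all are the package's own
  defaults or smaller, and every stochastic assertion fixes its seeds.
* Only original-image features are implemented (no wavelet/LoG filtering),
  one lesion per volume, recurrence-free survival as the single
  time-to-event endpoint, and no multivariable or clinically adjusted Cox
  models.
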