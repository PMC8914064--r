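# radnmf

Unsupervised radiomics analysis for pretreatment prediction of BCG
immunotherapy failure in high-risk non-muscle-invasive bladder cancer
(NMIBC). From contrast-enhanced CT volumes with lesion masks, the package
extracts the 107-feature "original image" radiomics set, factorizes the
nonnegative feature-by-sample matrix into a small number of metafeatures by
nonnegative matrix factorization (NMF), selects the metafeature most
predictive of recurrence by Cox concordance, and evaluates it as a
predictive (one-year BCG failure) and prognostic (recurrence-free survival)
biomarker. A synthetic-data module generates lesion phantoms and cohorts
with planted low-rank structure, so the entire analysis runs — and is
tested — without any patient data.

## The model

Let `V` be the `M x N` matrix of nonnegatively scaled radiomics features
(rows) over samples (columns). NMF seeks nonnegative factors

```
V ≈ W H,   W: M x k (metafeature loadings),   H: k x N (sample scores)
```

by multiplicative updates minimizing the Frobenius residual
`||V − WH||²_F`. For each candidate rank `k = 2..10` the factorization is
restarted from many seeded random initializations and the best residual sum
of squares (RSS) kept; the rank is chosen at the inflection of the RSS
curve (the interior point maximizing the discrete second difference
`rss(k−1) − 2·rss(k) + rss(k+1)`). Columns of `W` are normalized to unit
Euclidean norm so the scale of `H` — and hence the z-score cutoff — is well
defined. Each z-scored row of `H` is entered into a single-covariate Cox
proportional-hazards model (Newton–Raphson on the partial likelihood, Efron
tie correction) and the component with the highest Harrell C-index is
selected. Its scores are evaluated by ROC/AUC with a Youden-optimal (or
frozen) cutoff, confusion metrics, Kaplan–Meier curves with the log-rank
test, a Breslow-baseline calibration curve, and decision-curve net benefit.
New cohorts are scored without refitting: frozen feature list, frozen
min-max parameters, nonnegative least-squares projection onto the trained
`W`, frozen z-standardization and cutoff.

## Worked example

```r
library(radnmf)

# a textured lesion phantom and its 107-feature radiomics vector
vm <- make_phantom(phantom_spec(lesion_kind = "textured_blob",
                                radii = c(10, 9, 8), noise_sd = 6, seed = 23))
feats <- extract_all(vm)   # resamples to 1x1x2 mm, 25 HU bins
feats[, c("shape_MeshVolume", "shape_Sphericity",
          "firstorder_Entropy", "glcm_Contrast")]
#>   shape_MeshVolume shape_Sphericity firstorder_Entropy glcm_Contrast
#> 1             3029            0.840               2.17          1.26

# a synthetic training cohort (104 samples, ~11% one-year failures) with
# five planted components, one driving the hazard
tr <- make_cohort(cohort_spec(seed = 1))
model <- run_training(tr$features, tr$clinical,
                      run_config(n_restarts = 20, seed = 42))
model
#> <radnmf_model> 35 features kept (19 dropped), rank 3, component 1, cutoff 0.437
#> <rad_eval> AUC 0.834 | cutoff 0.437: sens 0.889 spec 0.789 | C-index 0.772 | log-rank p 4.6e-06

# a validation-like cohort (24 samples, ~46% failures) drawn from the same
# planted truth, scored with every training parameter frozen
va <- make_cohort(cohort_spec(n_samples = 24, target_failure = 0.46,
                              seed = 2), truth = tr)
ev <- run_validation(model, va$features, va$clinical)
glance(ev)
#>     auc sensitivity specificity c_index logrank_p cutoff
#> 1 0.721         0.4       0.786   0.746    0.0424  0.437
```

The training report says: the collinearity filter kept 35 of 54 features;
the RSS inflection chose 3 components on this draw; component 1 carried the
highest C-index; the Youden cutoff on its z-scores was 0.437. On the frozen
validation pass the component keeps most of its discrimination (AUC 0.72)
and prognostic value (C-index 0.75, log-rank p = 0.042) — the behaviour the
pipeline is designed to measure. `autoplot()` methods draw the RSS curve,
ROC, Kaplan–Meier, calibration and decision curves; `tidy()`/`glance()`
return the tables behind every fitted object.

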