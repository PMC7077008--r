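# glandrisk

Quantitative gland histomorphometry and recurrence-risk classification for
early-stage colon adenocarcinoma (ECA) histology images.

Tumor glands in well-differentiated colon adenocarcinoma are elongated,
lumen-bearing structures; as tumors become aggressive, gland shapes grow
irregular and the orientations of neighboring glands lose their local
alignment. `glandrisk` turns that architectural signal into a patient-level
recurrence call, for pathology-image researchers who have TMA core images
(or precomputed gland segmentations) and clinical follow-up tables:

- **Segmentation** — a deterministic lumen-seeded classical segmenter for
  lumen-bearing glands (Otsu-thresholded luminance seeds, ring dilation,
  seeded watershed split), plus GeoJSON contour import for segmentations
  produced by external tools.
- **Morphometry** — per-gland area, perimeter, circularity `4πA/P²`,
  eccentricity, solidity, axis ratio, boundary Fourier harmonics, and the
  box-counting fractal dimension of the boundary.
- **Orientation co-occurrence ("tensor") disorder** — axial orientations in
  [0°, 180°) quantized into 18 bins; for each gland, the joint distribution
  of neighbor-pair bins over its k-nearest-neighbor graph neighborhood;
  Haralick-type measures on that matrix (contrast average/energy/variance
  with circular bin distance, entropy, energy, information measures 1/2,
  …), aggregated as `mean_tensor_*` / `sd_tensor_*`.
- **Feature catalog** — 386 named features per core
  (`feature_manifest()` is the exact contract), including the five
  classifier features by name: `mean_tensor_info_measure1`,
  `mean_tensor_contrast_average`, `mean_circularity_entropy`,
  `mean_tensor_contrast_energy`, `sd_fractal_dimension_energy`.
- **Classifier** — mRMR (MID variant, mean±SD three-level discretization)
  selects m = 5 features; linear SVM, random forest and linear discriminant
  candidates are trained under stratified five-fold CV, and the best is
  locked (`lock_down()`); locked models map cores to
  ECAHBC-positive/negative risk groups.
- **Validation statistics** — confusion metrics (accuracy/PPV/NPV),
  Kaplan–Meier, log-rank, univariate/multivariate Cox (Efron ties),
  chi-square association, Cohen's kappa, and the clinical biomarker
  cutoffs (Ki67 ≥ 14% positive; CEA > 5 ng/ml elevated).
- **Synthetic cohorts** — TMA-like fields of perturbed-ellipse glands with
  von Mises axial orientations (concentration κ controls disorder), linked
  outcomes, and pseudo-H&E renders, so the whole pipeline is testable
  without patient data.

## Worked example

Separate ordered (κ = 20) from disordered (κ = 0.5) synthetic cores —
the synthetic restatement of the non-recurrent vs recurrent gland
phenotype:

```r
library(glandrisk)

kappas <- rep(c(20, 0.5), each = 15)
sets <- lapply(seq_along(kappas), function(i)
  sample_layout(synth_config(n_glands = 30, kappa = kappas[i], seed = 100 + i)))
features <- extract_feature_table(sets)
labels <- rep(c(0L, 1L), each = 15)          # 1 = disordered phenotype

X <- as.matrix(features[, -1])
sel <- mrmr_select(discretize(X[, apply(X, 2, sd) > 0])$levels, labels, m = 5)
sel$selected
#> [1] "mean_tensor_contrast_average"  "sd_fourier_energy_6_energy"
#> [3] "mean_tensor_info_measure1"     "mean_tensor_contrast_variance"
#> [5] "sd_tensor_max_probability"

model <- lock_down(lapply(c("svm", "rf", "dac"), function(mt)
  crossval_train(X[, sel$selected], labels, mt, seed = 1)))
mean(model$cv_metrics)                        # 1.00 (svm locked)

pred <- predict_risk(model, features[, -1])
confusion_metrics(pred, labels)$accuracy      # 1.000
```

mRMR lands on the orientation-disorder features first: the mean tensor
contrast average of a disordered core is an order of magnitude above an
ordered one (3.73 vs 0.74 for the first core of each class here), because
neighbor glands in a disordered field rarely share an orientation bin.
Risk groups (`"ECAHBC-positive"`) then feed the survival side:

```r
cohort <- simulate_cohort(
  lapply(seq_along(kappas), function(i)
    synth_config(kappa = kappas[i], seed = 100 + i)),
  synth_outcome_config(beta_disorder = 4, hr_recurrence = 4, seed = 1))
pos <- pred == "ECAHBC-positive"
logrank_test(cohort$survival_time[pos], cohort$event[pos],
             cohort$survival_time[!pos], cohort$event[!pos])
cox_fit(data.frame(ecahbc = as.integer(pos)),
        cohort$survival_time, cohort$event)
```

`run_pipeline(run_config(...))` chains all stages from a directory of
images/contours plus a cohort CSV into `features.csv`, `model.json`,
`risk.csv`, `report.json` and a hash manifest; a thin command-line wrapper
lives at `inst/cli/glandrisk.R`.

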