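---
title: "Gland histomorphometry and recurrence risk: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Gland histomorphometry and recurrence risk: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(glandrisk)
```

## The problem

In early-stage colon adenocarcinoma (ECA), the architecture of the tumor
glands — tubular epithelial structures whose degeneration grades the
disease — carries prognostic information that manual two-tier grading
captures only coarsely and with moderate inter-observer agreement. The idea
implemented here is to quantify that architecture on H&E tissue-microarray
(TMA) core images: segment the glands, measure each gland's shape, size and
axial orientation, summarize the *disorder* of neighboring gland
orientations with Haralick-type co-occurrence statistics, and train a
classifier on a small, mutual-information-selected feature subset to call
each patient ECAHBC-positive (high recurrence risk) or ECAHBC-negative.
Predicted risk groups are then validated with confusion metrics,
Kaplan–Meier/log-rank comparisons, and Cox proportional-hazards models.

Because real TMA cohorts cannot ship with a package, every stage is
exercised end to end on a synthetic glandular-tissue generator whose
disorder level is controlled by a single concentration parameter.

## Gland representation and conventions

All modules share one coordinate convention: 0-based pixel coordinates,
`(x, y) = (column, row)`, pixel centers at integers, polygons in pixel
units. Masks are rasterized from boundary polygons with the even-odd rule;
a pixel belongs to a gland exactly when its center lies inside the polygon
(half-open on the right/top edges, so abutting polygons never double-claim
a pixel). This makes areas deterministic: a 10×10 axis-aligned square
contains exactly 100 pixel centers.

A gland's *orientation* is the principal axis of its mask's second central
moments, reported on the axial circle [0°, 180°) — gland long axes are
undirected. Shapes whose two moment eigenvalues differ by less than 1% have
no meaningful axis; they are flagged degenerate and assigned 0° by
convention, which keeps downstream co-occurrence matrices well defined
without special-casing.

## Shape and size descriptors

Per gland we compute area (mask pixels), perimeter (boundary polygon),
circularity \(4\pi A/P^2\), moment eccentricity, solidity against the
convex hull, minor/major axis ratio, equivalent diameter, the box-counting
fractal dimension of the boundary, and the first ten boundary Fourier
harmonic magnitudes (of the complex contour DFT, normalized by the first
harmonic, hence invariant to starting vertex and scale).

**Box counting.** The boundary is resampled at 0.25-px arc-length steps and
covered with square boxes of side \(s \in \{2,4,8,16,32,64\}\) anchored at
the bounding-box corner (no grid-offset averaging, so the estimate is
deterministic); the dimension is the least-squares slope of \(\log N(s)\)
against \(\log(1/s)\). Two scale filters keep the fit inside the scaling
regime: scales below 1.5× the input polyline's median vertex spacing are
dropped (they see only the straight interpolation segments between vertices
and drag the slope toward 1), and scales above a quarter of the object's
span are dropped (boxes that cover most of the object saturate at
\(N \to 1\) and inflate the slope). At least the three largest scales are
always retained so the regression is well posed. On a 4-iteration Koch
polyline spanning 729 px this estimator returns 1.227 against the closed
form \(\log 4/\log 3 \approx 1.262\); smooth curves (lines, circles,
ellipses) return 0.94–1.00.

**Neighborhood ("local") statistics.** Disorder is a property of a gland's
surroundings, so each descriptor is also summarized over each gland's
neighborhood — itself plus its k-nearest-neighbor graph neighbors — by
mean, SD, entropy and energy. Entropy/energy bin the descriptor on the
image-wide observed range with `nbins = 10` (a fixed default recorded in
the feature manifest; the value is not derivable from first principles and
simply must be frozen for reproducibility). Entropy is in bits with
\(0\log 0 = 0\); a constant descriptor yields entropy 0 and energy 1.
Ranges narrower than \(10^{-9}\) (relative) are treated as constant so
floating-point dust cannot masquerade as heterogeneity.

## Orientation co-occurrence ("tensor") features

Gland neighborhoods come from a k-nearest-neighbor graph on centroids
(k = 5, union-symmetrized). Orientations are quantized into B = 18 bins of
10°, and for each gland the edges of the subgraph induced by its
1-hop neighborhood accumulate a symmetric B×B joint distribution
\(p(i,j)\) of neighbor orientation bins. These three constants (k, B,
radius) are not dictated by the science; they follow common practice in
orientation-disorder pathology features, are config-exposed, and are
recorded in the feature manifest. An isolated gland gets the uniform
matrix with an `empty_edges` flag rather than NaNs, so sparse cores never
poison image-level aggregates.

From each matrix we compute thirteen Haralick-type measures. Contrast
terms use the *circular* bin distance
\(d(i,j) = \min(|i-j|, B-|i-j|)\) — orientation is periodic, and a linear
\(|i-j|\) would make 5° and 175° maximally distant:

- contrast average \(\sum_d d\,q(d)\), contrast energy
  \(\sum_d d^2 q(d)\), contrast variance
  \(\sum_d (d-\mathrm{CA})^2 q(d)\), with \(q(d)\) the mass at circular
  distance \(d\);
- joint entropy \(-\sum p \log_2 p\) and energy \(\sum p^2\);
- marginal (intensity) mean, variance and entropy, and the marginal
  correlation;
- information measures
  \(\mathrm{IM1} = (H_{XY} - H_{XY1})/\max(H_X, H_Y)\) (0 at independence,
  negative for dependent matrices, bounded by −1) and
  \(\mathrm{IM2} = \sqrt{1 - e^{-2(H_{XY2} - H_{XY})}}\);
- maximum probability and diagonal mass.

Per-gland measures are aggregated across the image by mean and SD, giving
features named `mean_tensor_*` and `sd_tensor_*`. Adding a whole number of
bins to every orientation permutes the matrix without changing circular
distances, so the contrast, entropy, energy, information, maximum and
diagonal measures are exactly shift-invariant; the marginal mean/variance
and correlation intentionally are not — they carry the mean-orientation
information.

## The feature catalog

`extract_features()` concatenates (a) image-level aggregations (mean, SD,
median, range) of each per-gland descriptor, (b) the same aggregations of
each descriptor's neighborhood statistics, and (c) the 26 tensor features —
386 named features in the default configuration, enumerated exactly by
`feature_manifest()`. The five features the locked classifier is known to
select on real cohorts are present by name:
`mean_tensor_info_measure1`, `mean_tensor_contrast_average`,
`mean_circularity_entropy`, `mean_tensor_contrast_energy`, and
`sd_fractal_dimension_energy`. The original 797-feature catalog of the
motivating study is not reconstructible from its public description, so the
catalog here aims at family-level fidelity (every named family is covered,
configurable) and name-level fidelity for the five selected features; exact
parity of the remaining columns is explicitly not a goal. Feature
extraction is pure — gland order, list permutations and reruns change
nothing.

## Segmentation

The learned gland segmenters used on real slides are not this package's
contribution; segmentation here is a deterministic classical pipeline
designed for lumen-bearing glands: Rec.-709 luminance is thresholded at the
Otsu value (iterated on the bright sub-population while the bright class
exceeds 25% of pixels — H&E luminance is trimodal and a single split can
land between epithelium and stroma), bright connected components become
lumen seeds, seeds grow by a disc of radius `ring_dilation` (default 8 px)
to capture the epithelial ring, touching glands are separated by seeded
propagation to the nearest lumen, holes are filled, and components under
`min_gland_area` (default 200 px²) are dropped. Labels are ordered by
decreasing lumen area then centroid (y, x), so output is deterministic.
Images whose threshold sits inside the bulk of the luminance distribution
(no contrast, e.g. blank stroma) return an empty set. For real data with
external segmentations, GeoJSON contours or label masks are imported
instead and flow through the identical downstream machinery. The
gland-formation area fraction (gland union ÷ tissue mask) feeds the
two-tier grade: "low" at ≥ 50% glandular, "high" below — with the tissue
denominator an explicit argument, because delineating "tumor tissue" is a
judgment this package does not make.

## Synthetic cohorts

The generator emulates exactly what the downstream features measure, and
nothing more. A core is `n_glands` (default 30, a typical gland count for
an analyzable TMA core) non-overlapping perturbed ellipses in a square
field (default 384 px). Orientations are axial, so they are sampled with
the doubled-angle trick — \(2\theta \sim \mathrm{vonMises}(2\mu, \kappa)\),
halved into [0°, 180°): κ = 0 is complete disorder, κ = 20 visually aligned
fields. Boundaries are ellipses (mean axis ratio 2, the elongation typical
of tubular gland cross-sections) with low-order sinusoidal radial
perturbation of relative amplitude `shape_noise` (default 0.08), which
keeps polygons simple up to 0.3. Placement is dart throwing with an
envelope-radius packing fraction near 0.18, so placement terminates
reliably; an impossible configuration raises a packing error rather than
hanging. Renders paint pink stroma, a purple epithelial ring and a bright
near-white lumen plus seeded Gaussian noise — enough structure for the
lumen-seeded segmenter, with no pretension of photorealism (no nuclei, no
stain variation, no texture).

Outcomes link to architecture through one documented knob: a layout's
disorder score is \(1/(1+\kappa)\) (bounded, monotone), recurrence is
Bernoulli with probability \(\mathrm{logistic}(\beta \cdot
\mathrm{disorder})\), and survival is exponential with rate
`baseline_hazard` × `hr_recurrence`^recurrence, administratively censored
at `censor_time`. Defaults (baseline 0.01/month, HR 4, censoring at 60
months) give event fractions comparable to early-stage colon cohorts. Note
the logistic has no intercept — at β = 0 the recurrence rate is 0.5 by
construction, a convention chosen for its transparent null.

What passing synthetic tests does *not* show: robustness to stain
variability, sectioning artifacts, nuclei-scale texture, non-glandular
tissue, or segmentation of solid (lumen-free) tumor regions. Those belong
to the imported-contours path.

## Feature selection and the classifier

mRMR uses the MID (difference) form: features are first discretized to
three levels at mean ± population SD; the first pick maximizes relevance
\(I(f;y)\) (plug-in mutual information, bits), each later pick maximizes
\(I(f;y) - \frac{1}{|S|}\sum_{s \in S} I(f;s)\), ties broken by column
order. The classical formulation was chosen because the method's source
does not state a variant; both the discretization and the variant are
config-exposed. A copy of an already-selected feature scores relevance
minus (near-)full redundancy and is deferred in favor of independently
informative features.

Three candidate models are trained on the selected features under
seed-deterministic stratified five-fold cross-validation: a linear-kernel
SVM (C = 1, features standardized by training-fold statistics), a
500-tree random forest, and a linear discriminant. No hyperparameters are
searched — none are published for the original classifier, so defaults are
frozen and recorded in the fitted object. Class weighting (inverse
frequency; flat priors for the discriminant) is on by default because
early-stage recurrence prevalence (~20%) otherwise rewards the trivial
all-negative classifier. `lock_down()` keeps the candidate with the best
mean CV accuracy (ties: SVM > RF > DAC) and freezes it; only locked models
predict. Predictions bind columns by name, never by position.

## Survival and association statistics

Kaplan–Meier curves, the two-group log-rank test and Cox
proportional-hazards models are delegated to the `survival` package behind
this package's interfaces; a package should not re-derive Newton iterations
that a decades-hardened implementation provides, and the test suite instead
verifies the delegation against hand-computed product limits and a directly
maximized partial likelihood. Ties use the Efron approximation by default
(less biased than Breslow; switchable, since the original analyses were run
in software whose default is Breslow). Wald CIs are
\(\exp(\beta \pm 1.96\,\mathrm{se})\); monotone-likelihood failures are
reported as `converged = FALSE` rather than as spurious huge ratios.
`survival_table()` mirrors the common recipe of screening covariates
univariately at p < 0.05 before the joint model. The chi-square test is
Pearson without continuity correction; Cohen's kappa uses marginal-product
expected agreement with the degenerate convention κ = 1 for two identical
constant raters and 0 otherwise. Biomarker binarization follows the
clinical cutoffs: Ki67 labeling index positive at ≥ 14%, serum CEA normal
up to 5 ng/ml inclusive.

## Pipeline and reproducibility

`run_pipeline()` chains cohort reading, contour import or segmentation,
feature extraction, mRMR, CV training, lock-down, prediction, evaluation
and the survival comparison of predicted groups. Every output carries the
seed and an md5 hash of the scientific configuration (the output directory
is deliberately excluded from the hash, so reruns into a different
directory reproduce byte-identical features, model and report). Problem
sizes throughout the test suite — 30-gland cores, 100 + 100-core cohorts,
10 replicate seeds, 1000-patient survival simulations — were chosen as the
smallest sizes at which the statistical assertions are stable, and are
stated in the tests themselves.

## Known limitations

- The classical segmenter requires visible bright lumens; solid tumor nests
  and lumen-collapsed glands need imported masks.
- The catalog is family-faithful, not column-faithful, to the original
  797-feature design.
- Axial statistics assume elongated glands; near-isotropic glands are
  assigned 0° and dilute (never corrupt) orientation-disorder features.
- The synthetic outcome model is a single-pathway caricature: disorder is
  the only driver of recurrence, and survival is exponential.
- No probability calibration, nested model selection, competing risks or
  time-varying covariates.
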