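---
title: "Methods: whole-slide-image prognosis of 1-year disease-free survival in melanoma"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: whole-slide-image prognosis of 1-year disease-free survival in melanoma}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(melaprog)
```

## The task and the model

`melaprog` predicts a binary one-year endpoint for stage I--III cutaneous
melanoma patients from one annotated H&E whole-slide image (WSI) per
patient: *DF* (disease-free at one year) versus *non-DF* (recurrence).
Non-DF is the positive class everywhere in the package — in the AUC
orientation, in the confusion counts (a true positive is a correctly
identified recurrence), and in the classifier scores.

The pipeline is a classical multiple-instance design: a slide is reduced
to a bag of small crops, each crop is scored by a per-backend classifier,
and crop scores are pooled back to a slide (= patient) score by a
percentile vote. Stages:

1. **Tessellation.** The pathologist-annotated ROI is cut into a regular
   grid of 224 x 224-pixel tiles (the working magnification is assumed
   20x), anchored at the ROI bounding box; a tile must lie fully inside
   the image and have at least half of its pixels inside the ROI mask.
2. **Cell detection and density filtering.** Nuclei are detected per tile
   and cell density is the count divided by the tile area. Within one
   ROI, only tiles whose density strictly exceeds the 90th percentile of
   that ROI's density distribution are retained — the most
   cell-rich, and hence most informative, tissue.
3. **Crop sampling.** Each retained tile yields up to 50 candidate crops
   of 112 x 112 pixels whose centers are drawn from an isotropic Gaussian
   centred on the tile; a crop is kept only if fewer than 25% of its
   pixels are background (Luma > 170).
4. **Stain normalization.** Crops are colour-normalized by Macenko's
   method to a canonical H&E reference, removing slide-to-slide staining
   variation.
5. **Feature extraction.** Each crop becomes a fixed-length feature
   vector through a pluggable backend: ResNet50 (2048 features),
   DenseNet201 (1920) or InceptionV3 (2048, 299-pixel input) tapped at
   the global-average-pooled penultimate layer, or the deterministic
   `toy` descriptor used throughout the tests.
6. **Crop classifier.** A nested "waterfall" selector — per-feature
   rank-AUC filter at 0.60, then PCA keeping the minimal component count
   reaching 80% cumulative explained variance — feeds an RBF-kernel SVM
   with class-balanced weights; decision values are sigmoid-calibrated to
   scores in $[0, 1]$.
7. **Vote-score aggregation.** The slide score is the 75th percentile of
   its crops' scores; with one representative slide per patient this is
   the patient score.
8. **Ensembling.** With three backends, if at least two of the three
   patient scores strictly exceed $th$, the maximum is the final score,
   otherwise the minimum. $th$ is the training-set fraction of non-DF
   patients rounded to two decimals (0.28 for a 12/43 split). A
   clinical-covariate SVM can be soft-voted (averaged) with the ensemble.
9. **Evaluation.** Patient-stratified 5-fold cross-validation repeated
   for 5 rounds; per round, predictions pooled over the 5 test folds give
   one ROC; the operating threshold maximizes Youden's
   $J = \mathrm{sensitivity} + \mathrm{specificity} - 1$; reported
   metrics are accuracy, sensitivity, specificity, precision, F1 and
   G-mean $= \sqrt{\mathrm{sensitivity} \times \mathrm{specificity}}$,
   summarized by medians and IQRs across rounds.

## Parameters that matter

| Parameter | Default | Where | Meaning |
|---|---|---|---|
| `tile_side` | 224 px | preprocessing | tile grid size at working magnification |
| `density_percentile` | 90 | preprocessing | strict cut on the per-ROI cell-density distribution |
| `crop_side` | 112 px | preprocessing | crop size (one-fourth of the tile *area*) |
| `max_crops` | 50 | preprocessing | candidate crops per tile |
| `luma_cutoff` / `bg_max` | 170 / 0.25 | preprocessing | background pixel call and rejection rule (strict) |
| `io`, `beta`, `alpha` | 255, 0.15, 1 | stains | Macenko white level, OD transparency cutoff, robust angular percentile |
| `auc_cutoff` | 0.60 | crop model | per-feature rank-AUC filter (kept when exactly equal) |
| `variance_threshold` | 0.80 | crop model | PCA cumulative explained variance |
| `cost`, `gamma` | 1, $1/(p \cdot \mathrm{var})$ | crop model | RBF-SVM hyperparameters, balanced class weights |
| `percentile` | 75 | aggregation | vote-score pooling percentile |
| `th` | training non-DF fraction, 2 dp | aggregation | ensemble threshold (0.28 at 12/43) |
| `k`, `rounds` | 5, 5 | evaluation | cross-validation plan |

All of them are surfaced in `preprocess_options()`, the model functions
and `experiment_config()`, and can be set in one YAML file.

## Design choices where the design was open

* **Crop size.** "One-fourth of the tile size" is read as one-fourth of
  the tile *area*, i.e. 112 px for 224-px tiles: crops are later resized
  *up* to 224, and a 56-px crop would have to be upsampled 16-fold, which
  would be an odd design for texture features. `--crop-side` makes the
  other reading available.
* **Strict inequalities.** "Exceeded" is read strictly at three places:
  the density filter (`> P90`), the background rule (`< 25%` kept, so a
  crop at exactly 25% is rejected), and the ensemble vote (`> th`, so a
  score exactly at 0.28 does not count as exceeding). Each is pinned by a
  unit test.
* **Ensemble threshold as a ratio, not a constant.** 0.28 equals the
  non-DF (positive-class) fraction 12/43, although it is described in
  prose as the DF ratio; the package computes it from the training split
  as the non-DF fraction and recovers 0.28 exactly on a 12/43 split.
* **Percentile convention.** Linear interpolation between order
  statistics (`quantile(type = 7)`), fixed project-wide for the density
  filter, the 75th-percentile vote, and concentration scaling.
* **Per-slide stain models.** Stain vectors are estimated per slide,
  pooled over that slide's retained tiles, then applied to its crops:
  112-px crops are often too small (or too stroma-only) for a stable
  angular estimate. Per-crop estimation remains available.
* **Cell detection.** The original workflow used interactive software
  for cell detection; here it is a defined operator — multiscale
  Laplacian-of-Gaussian blob detection (4 scales spanning nuclear
  diameters 5--19 px, response threshold 0.08, non-maximum suppression at
  0.7 of the minimum diameter) on the hematoxylin concentration channel
  obtained by non-negative deconvolution with the canonical stain
  matrix. On rendered nuclei it recovers well-separated ground-truth
  centroids exactly.
* **Calibration.** SVM scores in $[0,1]$ come from a sigmoid (Platt) fit
  on the training-fold decision values. This is deterministic — no
  internal cross-validation — so identical configs reproduce identical
  score tables byte for byte.
* **Stratified folds.** With 12 positives among 43 patients,
  unstratified 5-fold splits can produce single-class test folds, for
  which a per-round ROC is undefined; stratification deals positives
  round-robin first (every fold receives at least two), negatives
  continue the deal, and fold labels are then permuted randomly.
* **Median unit.** Metrics are computed per round on predictions pooled
  over that round's five test folds, and medians/IQRs are taken over the
  5 round-level values, matching a "five rounds" boxplot reading.
* **F1.** The harmonic form
  $2 \cdot \mathrm{sens} \cdot \mathrm{prec} / (\mathrm{sens} + \mathrm{prec})$
  is used; a printed formula with a product denominator would be
  identically 2 and is treated as a typographical slip.
* **Empty AUC selection.** If no feature reaches the 0.60 cutoff (common
  under a null), the 10 features farthest from AUC 0.5 are used and a
  warning is emitted loudly; the test suite exercises this path.

## The synthetic cohort generator

Real WSIs cannot ship with a package, so every stage is exercised on a
generator whose ground truth is known (`cohort_config()`,
`generate_cohort()`, `render_slide()`).

* **Clinical records** follow the design cohort's marginals: 72/28
  DF/non-DF imbalance (12/43 by default), near-even gender, trunk-heavy
  tumor site, stage I--III with II dominant, T0--T4 with T4 dominant, age
  $\sim \mathcal{N}(64, 14.9)$. Covariates are independent of outcome by
  default, reflecting the absence of significant clinical associations
  in cohorts of this size; `clinical_association = TRUE` plants a stage
  shift so the clinical SVM has something to find in its own tests.
* **Slides** are formed in optical density under Beer--Lambert: a
  hematoxylin field of soft elliptical nuclei (semi-axis about 4 px,
  lognormal size jitter, random orientation) placed by an inhomogeneous
  Poisson process inside an elliptical ROI, and an eosin stroma field
  (smooth lognormal texture, 0.4--0.7 OD, strongly displaced inside
  nuclei), combined through a per-slide stain matrix — the canonical H&E
  pair perturbed entrywise by `stain_jitter` (sd 0.05) — and
  exponentiated to 8-bit RGB. Outside the ROI (and inside a few random
  "tear" artifacts) pixels are near-white with Luma > 170, so the
  background filter is exercised meaningfully.
* **Study conditions.** Default slide side 1120 px (a 5 x 5 tile grid),
  nuclear density 20 per $10^4\,\mathrm{px}^2$ (about 1000--1500 nuclei
  per slide), per-slide density multiplier lognormal with sd 0.15.
  These were chosen once as desk-scale stand-ins for cell-rich tumor
  tissue and are not tuned per experiment.
* **Planted signal.** Non-DF slides have nuclear density scaled by
  $1 + 0.4\,e$ and nuclear-size log-sd by $1 + 0.3\,e$ for effect size
  $e$ (default 1.5; 0 gives class-exchangeable images). The form mirrors
  the intuition that the model reads nuclear morphology and cell-density
  distributions; no quantitative description of what distinguishes the
  classes in real tissue is available, so this is a modelling choice,
  and results on the generator say nothing about real-data effect sizes.

What the generator deliberately does **not** emulate: pyramidal
multi-resolution structure, scanner-specific noise, tissue-type
heterogeneity (fat, vessels, necrosis), lymphocyte/tumor-cell distinction
(all nuclei share one morphology family), and any real relationship
between histology and outcome. Passing tests therefore demonstrate that
the *pipeline machinery* is correct and leakage-free, not that the
method attains any particular accuracy on clinical material.

## Numerical notes

* Optical density uses $-\log_{10}((I + 1)/I_0)$, which round-trips the
  8-bit lattice exactly; concentrations come from an exact vectorized
  two-variable non-negative least squares (active-set enumeration).
* Stain estimation sorts tissue pixels before deterministic subsampling
  (cap 50 000), making the estimate a function of the pixel *set* —
  invariant to rotation and pixel order. A second eigenvalue below
  $10^{-4}$ of the first is treated as a single-stain degenerate image.
* PCA component counts use a $10^{-9}$ slack on the cumulative-variance
  comparison so that exact-arithmetic cases (e.g. ten equal eigenvalues
  at an 80% threshold giving eight components) are not lost to floating
  point.
* Youden thresholds scan midpoints between consecutive distinct scores
  plus sentinels outside the range; ties prefer the higher-sensitivity
  point, then the smaller threshold.
* All randomness flows from a single integer seed through a string-tagged
  32-bit hash (`derive_seed`), so cohort generation, crop sampling and
  fold assignment are independently reproducible and never consume the
  caller's RNG state.

## What the calibration checks can and cannot show

The null-calibration check runs the full pipeline on a 40-patient
cohort with `effect_size = 0` and asks the median patient-level AUC to
lie in $[0.35, 0.65]$. One cohort yields essentially *one* draw of a
random patient ranking: the rounds re-randomize folds but share the same
slides, so their AUCs are strongly correlated. For $n = 40$ with an
11/29 split the null AUC has standard deviation
$\sqrt{(n_1 + n_2 + 1)/(12\,n_1 n_2)} \approx 0.10$, so the band is only
about $\pm1.5\sigma$ wide for a single draw and a correctly calibrated
pipeline would still land outside it for a substantial fraction of
seeds, in either direction. The calibration statistic is therefore the
median over three independent null cohorts (consecutive seeds), which
narrows the sampling sd to about $0.07$ while testing the same quantity
against the same band; the label-permutation leakage check, which is a
single draw by construction, uses a $\pm2\sigma$ band ($[0.3, 0.7]$)
for the same reason. Problem sizes used
by the checks — 40 patients for calibration and signal recovery, 10 for
byte-level determinism, 448-px slides for the stain oracle — are the
package's chosen desk-scale study conditions.

## Known limitations

* The three CNN backends are architecture specs with a plug-in slot;
  without a local deep-learning runtime the `toy` descriptor is the only
  executable backend, and it is far weaker than ImageNet features.
* One slide per patient is assumed throughout (slide score = patient
  score); multi-slide patients would need an extra pooling rule.
* The endpoint is the binary 1-year label; no time-to-event modelling.
* The ensemble rule is the fixed two-of-three vote; weighted or learned
  ensembling is out of scope.
* `N` (lymph-node) staging is not simulated and is excluded from the
  clinical model by default, matching the covariate set actually used.
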