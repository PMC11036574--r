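---
title: "radimmune: models, conventions and design decisions"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{radimmune: models, conventions and design decisions}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(radimmune)
```

This vignette is the package's own account of its science: the two models it
implements, the assumptions they rest on, the tunable parameters and why their
defaults are what they are, what the synthetic-data generator does and does
not emulate, and the numerical conventions that make results reproducible to
the byte.

## 1. The two-stage model

**Stage 1 — immunomarker classifier.** Each patient contributes the change,
between baseline and the time point right after ten radiotherapy fractions
(10F), in a panel of immune biomarkers measured by immunohistochemistry:
infiltrating CD8+ T-cell count, CD68+ macrophage count, and eleven
IFN-responsive molecules. The classifier is a sparse linear score fit by
L1-penalized logistic regression against the CR/PR response label. The
*reference* model shipped with the package is fixed:

$$\mathrm{score} = 0.4569 + 0.0041\,\Delta\mathrm{CD8} - 0.0009\,\Delta\mathrm{CD68},$$

with high-score group defined by score ≥ 0.307 (a Youden-index cutoff).
These four constants are pinned by tests and never refit;
`build_immunomarker_classifier()` produces *new* models of the same family
from data. The score is treated as a linear predictor, not a probability —
its published distribution (medians 0.042 / 0.548, IQRs extending below 0)
is incompatible with a probability scale, so no inverse-logit is applied.

**Stage 2 — radiomics signature.** From the pre-treatment CT volume and a
binary VOI mask on the same grid, 97 features are extracted (section 2),
screened univariately at *p* < 0.2, z-score normalized, and fed to the same
LASSO-CV machinery, with the stage-1 class (high/low immune score) as the
default target (`label_definition = "immune_class"`), or the CR/PR response.
The point of stage 2 is substitution: imaging is cheap and repeatable,
biopsies are not.

Assumptions worth stating: markers enter linearly (no interactions); the
binary immune class is a faithful summary of the marker dynamics; texture on
the *native* anisotropic grid carries the class signal (no resampling is
done, matching extraction from planning-CT grids); and one VOI per patient
covering the gross tumor plus uterus.

## 2. The 97-feature bank

The registry (`inst/extdata/feature_registry.json`) fixes the names,
categories and order: 24 first-order intensity, 20 shape, 53 textural
(24 GLCM, 16 GLRLM, 13 GLSZM). The exact composition of the original
in-house MATLAB bank is not recoverable, so this registry — assembled from
standard radiomics definitions to match the published category counts — is
the package's single source of truth; `extract_all()` refuses to emit
anything that disagrees with it. No wavelet/filtered classes, no 2D mode,
and no IBSI-certification claim.

Key numerical conventions, chosen once and tested:

* **Quantization**: equal-width bins over the in-mask HU range, default
  `n_bins = 64`; a constant VOI maps to level 1. Fixed bin *count* (rather
  than fixed width) keeps texture features stable under HU calibration
  shifts.
* **Moments**: population (1/n) convention for variance, skewness, kurtosis
  (excess); entropy/uniformity in log base 2 on the quantized histogram.
  Degenerate limits are constants, never NaN: constant VOI ⇒ skewness 0,
  kurtosis 0, entropy 0, uniformity 1; zero-variance GLCM correlation and
  the informational measures ⇒ 0; `fo_cv` at mean 0 ⇒ 0.
* **Texture matrices**: 13 unique lattice directions at voxel distance 1 on
  the native grid. The GLCM is symmetrized and *merged* (summed over
  directions, features computed once) — deterministic and oracle-friendly;
  per-direction averaging is available (`glcm_aggregate = "average"`).
  GLRLM runs accumulate over the same 13 directions; GLSZM zones are
  26-connected. Background voxels carry level 0 and break pairs, runs and
  zones, so nothing ever crosses the mask boundary. On VOIs of ≤ 64 voxels
  all three matrices are tested against brute-force enumerators.
* **Surface area**: marching tetrahedra on the *antialiased* indicator —
  each dual-grid corner takes the mean of its 8 adjacent voxel labels and
  the 0.5-isosurface is triangulated with linear edge interpolation.
  Meshing the raw binary field overestimates area by a large constant
  factor (a digitized ball plateaus near sphericity 0.79); the antialiased
  mesh converges (sphericity 0.98 at radius 12, surface within 2% of the
  analytic sphere). Masks thinner than one voxel have no corners above 0.5;
  they fall back to exposed-voxel-face area so every shape feature stays
  finite, down to a single voxel.
* **Geometry** is always computed in physical mm from the voxel spacing;
  principal axes use population second moments with length $4\sqrt\lambda$;
  elongation/flatness are $\sqrt{\lambda_k/\lambda_1}$ with the 0/0 case
  defined as 1; in-plane maximum diameters project boundary-voxel centers
  onto the named plane.

## 3. Signature construction conventions

* **Screening**: per-feature single-predictor logistic regression, Wald
  p-value on the slope (likelihood-ratio behind `test = "lrt"`); retain
  *p* < α, default α = 0.2. Quasi-separated features (non-convergence or
  |slope| > 15) have meaningless Wald p-values and are *retained* with
  p flagged `NA` — a perfectly separating feature is the strongest possible
  candidate, not a discard.
* **Normalization**: z-score with sample sd; constant columns dropped with a
  warning. Full-cohort statistics are used before CV — faithful to the
  original analysis; this leaks the feature scale across folds, which is
  documented here deliberately.
* **λ grid**: 100 log-spaced values from $\lambda_{max} =
  \max_j |x_j^\top(y-\bar y)|/n$ (the smallest λ zeroing all coefficients)
  down to $10^{-4}\lambda_{max}$.
* **λ selection**: minimum mean cross-validated binomial deviance
  ("minimum criteria"), *not* the 1-SE rule; exact ties break toward the
  largest (sparsest) λ. Folds are stratified by class, seed-reproducible and
  exhaustive; when the minority class is smaller than the fold count the
  fold count shrinks to it (with a warning) so every fold keeps both
  classes — at the published cohort size (n = 30, 13 PR) ten folds are
  feasible, but simulated 30-patient cohorts routinely produce smaller
  minorities.
* **Solver**: glmnet (`standardize = FALSE`; normalization is explicit and
  stored). At λ → 0 the fit matches unpenalized `glm` to 10⁻³ (tested); at
  λ ≥ λ_max the model is intercept-only with intercept = log-odds of
  prevalence (tested).
* A fitted model stores its normalization parameters and can be rewritten as
  a closed-form raw-unit formula (`denormalized_formula()`), the same shape
  as the published immune-score formula; the identity between the two
  scoring routes is tested to 10⁻⁹.

**A limitation worth knowing.** Minimum-criteria CV-λ is model-selection
inconsistent: the CV deviance is nearly flat in small spurious coefficients,
so the selected support usually contains the informative features *plus* a
few noise features (measured on synthetic marker panels: both informative
markers recovered in 100/100 replicates at n = 200, but the support equals
exactly the informative pair in only ~7/100; under null labels the support
is near-empty — median 1 of 13 — but exactly empty in only ~30% of runs).
Sparser selection would need the 1-SE rule or stability selection, both out
of scope here because the minimum criterion is part of the reproduced
method. The corresponding acceptance check asserts exact-set recovery and is
knowingly red; the attainable containment property is asserted and green.

## 4. Evaluation conventions

* CR is the positive class; a patient is called high when score ≥ cutoff
  (both published cutoffs, 0.307 and 1.036, are "≥" rules).
* ROC thresholds are the distinct scores; AUC is the Mann-Whitney statistic
  with ties counting ½ (equals the trapezoidal area; tested against
  exhaustive pair enumeration). The 95% CI is DeLong's by default,
  percentile bootstrap behind a flag.
* The Youden cutoff maximizes sens + spec − 1 over attainable thresholds,
  ties toward the higher threshold; a non-positive maximal J warns.
* Group association uses the **uncorrected** Pearson χ² (df = 1): on the
  published radiomics 2×2 (19 low / 11 high, 37% vs 91% CR) the uncorrected
  p is 0.00398 ≈ the printed 0.004, while the Yates-corrected value (0.0125)
  is not; correction stays behind a flag. Printed percentages use half-up
  rounding (83%/17%).
* Rank-sum tests follow base R's exact-vs-normal-approximation policy
  (exact when tie-free and n < 50), two-sided.
* Hematological ratios: NLR = ANC/ALC, PNR = PLT/ANC, PLR = PLT/ALC,
  LMR = ALC/AMC, at either timepoint; zero denominators flag the affected
  ratio as NA rather than erroring the record.

## 5. The synthetic cohort: what it emulates, what it does not

`generate_cohort()` draws, per patient: a latent class (hot/cold,
`hot_fraction`), marker deltas from class-conditional normals, blood counts
(log-normal around adult reference means at baseline, attenuated at 10F —
strongest for lymphocytes — so the *ratio definitions* are exercised on
computed, not drawn, ratios), a CR label from
$\mathrm{Bernoulli}(\sigma(\text{slope}\cdot(\text{score}-\text{center})))$
with the score from the *reference* model, eleven class-independent noise
marker deltas completing the 13-marker panel, and a CT volume: an
ellipsoidal tumor (half-axes 7–11 voxels in-plane, 2.5–4.5 slices) of
45 HU plus a correlated noise field whose Gaussian smoothing length is
class-dependent (cold tumors smoother by `texture_effect` voxels; marginal
sd renormalized to 30 HU so classes differ in correlation length, not
variance), on fat-like background (−80 HU), at 1 × 1 × 5 mm spacing.

Defaults state one world, chosen once: `hot_fraction = 0.6` (the published
high-score group is 18/30); marker-delta parameters (hot ΔCD8 ~ N(150, 60),
ΔCD68 ~ N(−50, 60); cold N(−30, 40) / N(80, 70)) put the class-mean immune
scores at ≈ 1.12 and ≈ 0.26, straddling the 0.307 cutoff;
`response_center = 0.69` is their midpoint and `response_slope = 5` then
gives an expected CR rate ≈ 0.58, matching the published 56.7%. These are
config values, never estimates of the original cohort.

Per-patient randomness is split by purpose (markers / blood / volume) from
seeds derived from (cohort seed, patient index), so adding a field to one
block never perturbs draws in another, and identical (config, seed) is
byte-identical — including the written NIfTI files.

What a green test establishes: the pipeline detects a texture signal of the
stated form and calibrates correctly in its absence. What it does not: no
anatomically realistic pelvis, no scanner/reconstruction effects, no partial
volume at mask boundaries, no inter-observer segmentation variability, no
correlation between tumor shape and immune state (shape features carry no
class signal by construction — only texture does).

## 6. Fixed I/O conventions

NIfTI-1 only (built-in minimal reader/writer: 3D scalar images, gzip, both
endiannesses, datatypes uint8/int16/int32/float32/float64, scl rescaling,
diagonal sforms). Masks: any strictly positive voxel is foreground; grids
must match the paired volume to 10⁻³ mm in spacing. The cohort CSV schema is
fixed (marker counts at both timepoints, blood counts, age, FIGO stage,
tumor size, nodal status, optional CR/PR response); unknown columns pass
through, which is how the extra marker-delta columns travel. `extract_voi()`
crops to the tight bounding box (optional margin, clipped), preserving
foreground count and shifting the physical origin.

## 7. Known limitations

* The feature registry is *a* faithful 97-feature bank matching the
  published counts, not *the* original one; absolute feature values are not
  comparable to the original study's, only the pipeline's behaviour is.
* The published radiomics-score coefficients were never released; refit
  models are labelled as such (`label_definition`, seed, λ all serialized).
* Published AUCs (0.842 / 0.875 / 0.864) and cohort medians depend on the
  undeposited patient data and are deliberately not acceptance targets;
  the synthetic world checks power and calibration instead.
* Single-center design reproduced as-is: no train/test cohort split, CV
  only — the known optimism of that choice is inherited by design.
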