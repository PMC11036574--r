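# radimmune

CT radiomics signatures for chemoradiotherapy-induced changes in
tumor-infiltrating immune cells.

## The problem

During concurrent chemoradiotherapy (CCRT) for cervical squamous cell
carcinoma, the tumor microenvironment changes quickly: in some patients
infiltrating CD8+ T cells rise and CD68+ macrophages fall after the first ten
radiotherapy fractions (an immune-inflamed, "hot" shift), in others the
reverse happens. These dynamics track short-term treatment response (complete
vs partial response, CR/PR), but measuring them requires repeat biopsies.
`radimmune` implements a two-stage, fully reproducible pipeline for this
setting:

1. **Immunomarker classifier** — a linear *immune score* over the
   10-fractions-minus-baseline changes in marker counts, selected from a
   13-marker immunohistochemistry panel by LASSO-penalized logistic regression
   with stratified ten-fold cross-validation. The published reference model is
   shipped as a fixed constant:

   ```
   immune score = 0.4569 + 0.0041 · ΔCD8 − 0.0009 · ΔCD68,   high ⇔ score ≥ 0.307
   ```

2. **Radiomics signature** — from each patient's pre-treatment CT and VOI
   mask (native 1.0 × 1.0 × 5.0 mm grid, no resampling), a bank of **97
   features** (24 first-order intensity, 20 shape, 53 texture: 24 GLCM +
   16 GLRLM + 13 GLSZM) is extracted; features are screened by univariate
   logistic regression at *p* < 0.2, z-score normalized, and a sparse linear
   signature is fit by LASSO (10-fold CV, minimum-deviance λ) to predict the
   immune class without a second biopsy.

Evaluation reproduces the standard arithmetic: ROC/AUC with DeLong 95% CIs,
Youden-index cutoffs, high/low stratification with uncorrected Pearson χ²,
Wilcoxon rank-sum tests, hematological ratios (NLR, PNR, PLR, LMR) and their
Youden dichotomization, and univariate/multivariate logistic odds ratios.

Because the underlying patient data are not public, the package includes a
seedable **synthetic cohort generator**: a latent hot/cold state drives the
marker deltas, the CR probability (through the reference immune score), and
the in-tumor CT texture (class-dependent correlation length of the HU noise
field), so the entire pipeline is testable end to end from nothing but a seed.

## Worked example

```r
library(radimmune)

cfg <- pipeline_config(output_dir = "readme_run",
                       cohort = cohort_config(n_patients = 30, seed = 11))
run_pipeline(cfg)
```

The run directory then contains `features.csv` (30 × 97), `screening.json`,
`immune_model.json`, `radiomics_model.json`, `scores.csv`,
`evaluation.json`, `config.json` and `log.json`. For this cohort and seed the
evaluation reads:

```
immune classifier  : AUC 0.875 (95% CI 0.731-1.000), Youden cutoff 0.844
                     sens 0.857  spec 0.938  chi2 19.20  p 1.2e-05
radiomics signature: 71/97 screened, 6 nonzero, AUC 0.977, cutoff 0.173
                     CR rate low 14%, high 57% (p 0.05)
```

i.e. on a 30-patient synthetic cohort the refit immunomarker classifier
separates CR from PR (AUC 0.875), and the radiomics signature — six nonzero
texture/shape coefficients out of 97 candidates — recovers the immune class
from imaging alone (AUC 0.977 against its own training target; see the
methods vignette for what held-out performance looks like at n = 200).
The fixed reference model evaluates as published:

```r
immune_score(0, 0)      # 0.4569  (intercept: no marker change)
immune_score(150, -50)  # 1.1169  (typical "hot" shift)
```

A command-line interface with the same stages is installed at
`system.file("cli", "radimmune", package = "radimmune")` with subcommands
`simulate`, `extract`, `fit-immune`, `fit-radiomics`, `evaluate`, `run-all`
and `fixtures`.

## Repository layout

- `R/` — implementation (volume/mask I/O and NIfTI-1 reader/writer,
  synthetic cohort, 97-feature bank + registry, signature construction,
  evaluation statistics, pipeline).
- `inst/extdata/feature_registry.json` — the authoritative 97-feature
  registry (name, category, formula id, emission order).
- `vignettes/radimmune-methods.Rmd` — model, assumptions, parameter
  defaults, numerical conventions and limitations.
- `tests/testthat/` — unit, property and acceptance suites, including
  brute-force texture-matrix oracles.
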