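---
title: "Methods: building and validating a blood DNAm proxy for general cognitive ability"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: building and validating a blood DNAm proxy for general cognitive ability}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE, collapse = TRUE, comment = "#>")
```

## The problem and the model

Epigenetic clocks index aging, not cognition; genome-wide methylation
predictors of cognition are unwieldy for portable use. This package implements
the middle path: a **parsimonious blood DNA-methylation proxy score for
general cognitive ability (g)**, built by penalized regression on a small
candidate panel of cognition-associated CpGs, and a full validation battery
for judging what such a score does and does not capture.

The workflow has four stages:

1. **Derive g.** Each cognitive test is z-standardized and the battery's
   correlation matrix is eigendecomposed; g is the first unrotated principal
   component, sign-fixed so that higher g means better performance, and
   standardized to mean 0, SD 1. The variance share of PC1 is
   `eigenvalue / n_tests` because correlation-matrix eigenvalues sum to the
   number of tests.

2. **Train.** With standardized g as the outcome, the design contains the
   candidate CpGs (beta values standardized by training means `mu_j` and SDs
   `sigma_j`) as *penalized* columns and cell-type fractions (one reference
   cell type dropped, z-scored), sex, and plate (dummy-coded) as *unpenalized*
   covariates. The weighted elastic net minimizes
   $$\frac{1}{2n}\lVert y-\beta_0-X\beta\rVert^2+\lambda\sum_j
   w_j\Big(\alpha\lvert\beta_j\rvert+\tfrac{1-\alpha}{2}\beta_j^2\Big),
   \qquad w_j\in\{0,1\},$$
   solved by cyclic coordinate descent with covariance updates (compiled),
   warm starts along a decreasing lambda path, and unshrunken updates for
   `w_j = 0` columns. Tuning is a joint search: one fixed, seeded fold
   assignment (default seed 20251014) is reused across an alpha grid (0 to 1
   by 0.1); within each alpha the **1-SE rule** picks the largest lambda whose
   mean CV MSE is within one standard error of the path minimum, and the
   (alpha, lambda_1SE) pair with the smallest CV MSE wins. Ties go to the
   smallest alpha (denser, more ridge-like) and, within an alpha, to the
   largest lambda (sparsest).

3. **Score.** For any cohort, probes are aligned to the training pool,
   standardized with the *training* `mu_j`, `sigma_j`, non-finite entries set
   to 0 (so unmeasured or missing probes contribute nothing), combined as
   `raw = sum_j b_j x_j`, and z-scaled by the training raw-score mean/SD.
   Covariate coefficients are stored in the artifact but never applied outside
   the training fit; this is what makes the score portable across platforms.
   Samples missing more than 10% of the measured pool are excluded.

4. **Validate.** Criterion validity (squared-correlation R2 against measured
   g, plus RMSE/MAE and rank correlation), incremental validity over
   demographics (delta-R2 and semi-partial R2 from nested OLS), MCI
   discrimination (logistic models, per-SD odds ratios, AUC with DeLong paired
   tests and likelihood-ratio chi-squared for nested pairs), distinctness from
   an aging clock (both scores residualized on chronological age),
   moderation, bootstrap mediation (product of coefficients, percentile CIs),
   partial correlations with pairwise-complete handling, and a dual-criterion
   (z >= 3 or MAD-Z >= 3.5) outlier sensitivity mask.

## Quality control

The QC order is fixed: metadata sample filters (bisulfite conversion and sex
concordance are treated as inputs, not recomputed) -> probe filters
(cross-reactive, non-`cg`, SNP-proximal, then the candidate allowlist) ->
detection-p masking (p > 0.01) and imputation -> replicate-probe collapsing
(per-locus arithmetic mean) -> M-value PCA outlier flagging (|z| > 3 on PC1 or
PC2 of the sample-by-CpG matrix, column-centered, unscaled — M-value variance
is already comparable across probes). Scoring always stays on the beta scale;
M-values (`log2(beta/(1-beta))`, betas clipped to `[1e-6, 1-1e-6]`) are used
where variance-sensitive statistics need them.

**Imputation.** Dedicated methylation imputation machinery is out of scope
here; the package substitutes a deterministic scheme in the same spirit
(inter-probe linear structure): each incomplete probe is regressed,
ridge-stabilized, on its `k = 10` most-correlated other probes, with
predictors mean-completed first so the scheme works under scattered per-cell
missingness, and the probe mean as fallback. An early draft regressed on
fully *complete* probes only; with per-cell detection failures the probability
that any probe is complete decays as `0.98^n`, so that design silently
degrades to mean imputation on realistic cohorts — the redesign is tested
against exactly that failure.

**Cognitive-test imputation** uses the battery correlation matrix: a
subject's missing tests are predicted from their observed z-scores via the
conditional-mean formula `R[m,o] R[o,o]^{-1} z_o`; subjects missing half or
more of the battery are excluded.

## The synthetic cohort generator

No public data with this structure exists (the motivating cohorts are
restricted), so the generator is first-class, tested code that defines the
study conditions:

* **Demographics** match a population-based aging cohort: age ~ truncated
  normal(75.22, 7.01) on [65, 95], 57% female, race 78/16.5/5.5%
  White/Black/other, education 12.8 (SD 3) years with a -1.2-year
  minority-group shift, MCI prevalence 23.8% (the diagnostic threshold is
  solved so expected prevalence matches), six Dirichlet cell fractions
  (granulocyte-dominated), and 2-4 plates.
* **Latent ability**: `g_raw = -0.25 age_z + 0.25 edu_z + race shifts +
  noise`, standardized. The test battery is `lambda_k g + sqrt(1-lambda_k^2)
  noise` with loadings uniform on [0.4, 0.8]; with ~19 such tests PC1 carries
  about 40% of battery variance, matching what real neuropsychological
  batteries show, and correlates > 0.95 with the latent g.
* **Methylation** is generated on the M scale and mapped through the inverse
  logit2, which keeps betas in (0,1) automatically: baseline ~ N(0, 1.5),
  per-probe age and cell-composition coefficients, additive plate shifts, and
  N(0, 0.35) residual noise. The 30 causal probes add `±0.045 * g`.
* **Platforms**: the second platform keeps a seeded 558/600 of probes,
  applies per-cell detection failures, and duplicates loci as replicate
  probes, exercising zero-fill transport and replicate collapsing.
* A **comparator clock** column (`0.9 age_z - 0.15 g + noise`) emulates an
  age-dominated mortality clock; log-normal age-correlated biomarker columns
  and an MMSE-like screener round out the phenotype table.

### Calibration of the defaults

Two defaults are calibrated analytically rather than guessed:

* **Causal effect size** (`causal_effect_sd = 0.045`). For k probes with
  equal absolute effect a and residual SD sigma, the best linear combination
  attains `R2 = a^2 / (a^2 + sigma^2/k)`; with k = 30 and sigma ~ 0.37 this
  puts the *ideal* score-g R2 near 0.3 and the realized held-out R2 near
  0.2-0.3 at n_train ~ 1464 — the same order as published blood-DNAm
  cognition proxies (low teens of percent) while keeping each probe's
  marginal association detectable (z ~ 4.7).
* **Mediation structure.** Minority-group status shifts half of the causal
  probes' baselines against their causal sign (so the fitted score is lower),
  partly through an education loading (`edu_probe_weight = 0.03`). The
  population product-of-coefficients paths (treatment -> composite ->
  cognition, given age, sex, cells and plate) are available in closed form
  (`implied_mediation()`), and the baseline shift defaults to the value that
  makes the proportion mediated exactly `target_prop_mediated = 0.35`. The
  proportion is invariant to outcome attenuation (measured g vs latent g), so
  the same target holds whichever outcome is analyzed. Because education
  carries part of the path, adjusting for education attenuates the mediated
  share — a qualitative property the validation battery must reproduce.
* **Probe-level age confounding** (`probe_age_sd = 0.02`) is deliberately
  mild: the candidate panel emulates hits from *age-adjusted* cognition EWAS,
  which should carry little marginal age loading. Larger values turn hundreds
  of null probes into indirect g proxies through the age -> cognition path and
  push the score-age correlation far beyond what cognition-specific DNAm
  scores show.

## Numerical choices

* Coordinate descent: convergence when the largest coefficient change in a
  sweep is below 1e-7, at most 1e5 sweeps; non-convergence is an error naming
  the lambda. Lambda paths: 100 geometric points from `lambda_max` (computed
  on the partial residual after an OLS fit on the unpenalized columns) down
  to `1e-4 lambda_max`; `alpha` is floored at 1e-3 in the `lambda_max` formula
  so the ridge end has a finite path.
* The reference solver used in cross-checks is FISTA with the exact proximal
  operator of the weighted penalty — an independent code path, kept slow and
  simple on purpose.
* Solutions satisfy the KKT conditions to ~1e-8. Where glmnet is used as an
  extra cross-check, mixed-alpha comparisons account for glmnet's internal
  response standardization, which rescales the ridge term by the (1/n-based)
  SD of y; for the lasso the two objectives coincide and agreement is direct.
* Model artifacts are JSON with 17 significant digits, so write/read round
  trips are bit-exact; unknown schema versions are explicit errors.
* Boundary clipping before the M transform uses eps = 1e-6. Degenerate
  inputs (constant tests, zero-variance probes, single-member groups, zero
  MAD, zero total effect in mediation) produce named errors or explicit
  undefined-with-reason results, never silent numbers.

## What passing tests show — and what they do not

The synthetic cohort reproduces the *statistical structure* the analysis
assumes: a single latent factor behind the battery, sparse causal probes
confounded by age, cells and batch, platform panel mismatch, and a
group-difference structure with a known mediated share. Passing tests
therefore demonstrate solver and procedure correctness, calibration of the
inferential tests at their nominal size, exact transport arithmetic, and
recovery of known generative parameters. They do **not** demonstrate that a
real 29-CpG score generalizes to any particular population: the generator has
no genomic correlation structure between probes (co-methylated regions enter
only the imputation tests), no assay nonlinearity, no cohort-specific
selection effects, and its null probes are truly null, whereas real candidate
panels are enriched for partially replicating signals.

Two honest limitations surfaced by the tests are worth stating. First,
selection *precision* at these effect sizes is modest: with 30 causal probes
among 600 and per-probe z near 4-5, the 1-SE elastic net recovers ~90% of the
causal set but roughly a third of its selected members are null probes —
sparser-than-truth recovery with some false inclusion is the known behaviour
of CV-tuned elastic nets in this regime, and users should treat the selected
set as a predictive panel, not a list of causal loci. Second, the mediation
estimates are descriptive decompositions of observational associations, not
causal identification; the package exposes both the unadjusted and
education-adjusted shares precisely because they differ.

## Problem sizes

Default end-to-end runs use n = 2069 subjects (70/30 stratified split), 600
probes with 30 causal, an 11-point alpha grid and 10 folds; a full pipeline
run completes in about 90 seconds on one CPU, and the size calibrations use
3000-5000 null replicates per test. These sizes were chosen so the whole
validation battery is routinely re-runnable on a laptop.
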