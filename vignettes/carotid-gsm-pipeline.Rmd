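---
title: "Carotid plaque echogenicity, diet scores and sex-stratified cohort models"
author: "carotidgsm"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Carotid plaque echogenicity, diet scores and sex-stratified cohort models}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## What this package does

`carotidgsm` implements, as a tested pipeline, a population-cohort analysis of
carotid-plaque echogenicity and diet:

1. **Echogenicity.** Annotated B-mode ultrasound frames are turned into plaque
   gray-scale statistics. The gray-scale median (GSM) of a plaque on
   brightness-normalized ultrasound is a marker of plaque composition: low GSM
   indicates echolucent, lipid-rich, vulnerable plaque; high GSM indicates
   fibrous/calcified, stable plaque.
2. **Diet scores.** FFQ-style intake tables are aggregated into nutrient and
   food-group profiles and scored for adherence to the Mediterranean diet
   (MEDAS, 14 binary items) and the DASH diet (10 components scored 0/0.5/1).
3. **Cohort models.** Sex-stratified multiple linear regressions relate GSM to
   diet and supplement exposures in the plaque sub-cohort, and multiple
   logistic regressions relate plaque presence to collapsed diet categories in
   the full cohort — under multiple imputation by chained equations with
   Rubin's-rules pooling.
4. **Synthetic data.** Because individual-level cohort data of this kind are
   not redistributable, a generator produces ultrasound-like frames with known
   plaque echogenicity and cohorts with known effect sizes, prevalences and
   missing-at-random missingness, so the whole pipeline is verifiable by
   parameter recovery.

## Echogenicity measurement

### Geometry and rasterization

Frames are 8-bit grayscale rasters; pixel coordinates are 0-based, row-major,
origin at the top-left, and pixel $(x, y)$ has its center at
$(x + 0.5,\, y + 0.5)$. An observer's annotation consists of three polygons:
the plaque outline and one reference region each in the vessel lumen and the
adventitia. Polygons are rasterized by the even-odd rule applied at pixel
centers. These conventions are stated explicitly because the original
annotation tooling for such data is typically interactive and undocumented;
every rasterization choice here is pinned by brute-force oracle tests.

### Brightness normalization

Ultrasound brightness is machine- and operator-dependent, so plaque gray
statistics are only comparable after anchoring: the lumen (blood) is the
darkness reference and the adventitia the brightness reference. We use the
standard two-point linear map with the conventional anchors 0 and 190,

$$ g' = \operatorname{clip}_{[0,255]}\!\left(\operatorname{round}\!\big(190\,(g - L)/(A - L)\big)\right), $$

where $L$ and $A$ are the **medians** of the raw gray values in the lumen and
adventitia regions. The median (rather than the mean) makes the anchors robust
to small annotation slips. Rounding is half-up; values above the adventitia
anchor may exceed 190 up to the 8-bit ceiling of 255. If $A \le L$ the
annotation cannot discriminate the references and the package raises a
structured error rather than producing garbage. By construction the median of
the normalized lumen region is 0 and of the adventitia region 190, exactly.

### Noise reduction, cropping, statistics

Noise reduction is a single-pass 3×3 median filter with half-sample symmetric
(edge-repeating) borders, applied to the raw frame *before* normalization;
because the reference anchors are medians over large regions, the order has no
practical effect on them, and the choice is recorded here as the package's
convention. Cropping to the plaque's bounding box (with the offset recorded)
mirrors the automatic cropping such pipelines perform; it does not change any
statistic. Per plaque and observer we report the minimum, maximum, mean and
median normalized gray value; the median of an even pixel count is the mean of
the two central order statistics.

The participant-level outcome is the **flat arithmetic mean over all
plaque-by-observer measurements** (both observers' segmentations count as
separate measurements). A mode that first averages observers within each
plaque is available (`aggregate_participants(method = "per_plaque")`) for
sensitivity analyses.

### Interobserver agreement

Plaques are segmented twice by different observers; reliability is summarized
on a reproducible random subsample (default 5% of participants; the
denominator — participants versus plaques — is a parameter, since either
convention is defensible). We report the two-way random-effects,
absolute-agreement, single-measurement intraclass correlation ICC(2,1)
computed from the ANOVA mean squares, the mean paired difference and
Bland–Altman 95% limits of agreement. Pairs whose absolute difference exceeds
3 SD of the paired differences are flagged for remeasurement; the multiplier
is configurable, and the rule is intentionally simple — it selects gross
disagreements, not subtle bias.

## Diet scores

FFQ aggregation is strictly linear: each daily output equals
$\sum_{\text{items}} \text{frequency} \times \text{portion} \times
\text{per-gram coefficient}$. The composition table shipped for tests is
synthetic and unit-normalized so worked examples have closed forms; real
analyses supply their instrument's table.

MEDAS items are pre-coded binary adherence indicators; the total (0–14) is
grouped into the categories 0–3, 4, 5, 6+. DASH components score 1 at the
target, 0.5 at the intermediate threshold, 0 otherwise; totals (multiples of
0.5 in 0–10) are grouped into 0–3.5, 3.6–4.5, 4.6–5.0, 5.1+. Note the DASH
category bounds leave the open interval (4.5, 4.6) uncovered — harmless,
because 0.5-step totals cannot fall there; the tests assert this exhaustively.
Both sets of component thresholds live in editable YAML configuration rather
than code, because published screener variants differ in wording and cutoffs;
the shipped defaults follow the widely used 14-item MEDAS screener and
DASH-trial targets with half-compliance intermediates, and are explicitly
provisional. Missing score inputs are handled in two deliberately different
ways: *within* a score, a missing item scores 0 (conservative) and is counted
in `n_missing`; *between* stages, missing score categories propagate as `NA`
into imputation rather than being zeroed, so the regressions see properly
imputed exposures.

`any_supplement` is accepted as its own questionnaire datum when present —
instruments typically ask about more preparations than the six analyzed
(multivitamins, multiminerals, calcium, magnesium, vitamin B, folate) — and is
otherwise derived as a three-valued OR of the tracked flags.

## Cohort models

### Imputation

Missing values are imputed by chained equations: `m = 20` completed copies,
10 sweeps each, matching common practice for cohort analyses of this size.
Univariate conditional models are:

* predictive mean matching (PMM, type-1 matching, 5 donors, Bayesian
  parameter draws with a small proportional ridge) for numeric variables;
* Bayesian logistic draws for binary variables;
* PMM on integer level codes for the four-level diet-adherence categories.

The last point is a deliberate design choice: the categories are *ordinal*
(they are groupings of an underlying score), and PMM with observed donors
respects both the ordering and the support exactly, while a multinomial model
would ignore the ordering and is substantially more expensive at this scale.
Ordinal codes also enter other variables' predictor matrices linearly; with
four ordered levels this is a standard, low-bias simplification. Unordered
factors with more than two levels are refused rather than mis-modelled.

Identifiers are excluded from predictor matrices. Variables that are 100%
missing are refused by name. Imputation chains are independent across copies
and reproducible under a seed.

### Pooling and models

Per-imputation estimates are pooled with Rubin's rules: $\bar Q$ the mean
estimate, $\bar W$ the mean within-imputation variance, $B$ the
between-imputation variance, total variance $T = \bar W + (1 + 1/m)B$,
Barnard–Rubin small-sample degrees of freedom, Wald $t$ intervals at
$\alpha = 0.05$. The identity $T = \bar W + (1+1/m)B$ is asserted to machine
precision in the tests, and pooling over copies of complete data reproduces
the single complete-data fit exactly.

The linear GSM models are fitted separately for men and women in the plaque
sub-cohort, one exposure at a time (diet categories with reference "< 4
points" for MEDAS and "< 3.6 points" for DASH; supplements versus no intake),
adjusted for physical inactivity, age, SES index, BMI, smoking, energy
intake, dyslipidemia, hypertension, diabetes, myocardial infarction, heart
failure, atrial fibrillation, stroke/TIA, peripheral artery disease, eGFR and
four medication classes. The SES index is consumed as an opaque numeric input
(its construction from education/profession/income is instrument-specific and
out of scope).

The logistic plaque-presence models use the full cohort with the four diet
categories collapsed to low/medium/high (reference: medium) — MEDAS 0–3 / 4–5
/ 6+, DASH 0–3.5 / 3.6–5.0 / 5.1+ — and adjust for age, sex, education
(ISCED levels mapped 0–2 low, 3–4 medium, 5–8 high), BMI, diabetes,
hypertension, dyslipidemia, smoking, heart failure, atrial fibrillation,
myocardial infarction, stroke and inactivity. They accept either an
imputation set (pooled, the default analysis path) or a single data frame
(complete-case mode); whether the original full-cohort analysis pooled or
used complete cases is not determinable from its report, so both paths are
first-class. Rank-deficient designs error with the aliased terms listed;
separation is detected from degenerate fitted probabilities and flagged.
No multiple-comparison adjustment is applied anywhere, deliberately; the
output contains only unadjusted p-values, as asserted by a test.

Descriptive tables report median [IQR] for continuous variables and n (%)
for categorical ones, with missing counts listed separately and percentages
over the full column (that convention matters when comparing prevalences —
see the generator calibration below). Group comparisons use the Wilcoxon
rank-sum and chi-squared tests, the standard nonparametric defaults when no
test is otherwise specified.

## The synthetic-data generator

### Images

`generate_image()` paints a dark lumen band (default raw mean 25), a bright
adventitia band (170) and an elliptical plaque (≈2400 px) whose raw level is
chosen so its *post-normalization* mean hits a requested target; annotation
polygons are the very shapes that were painted, so annotation and image are
consistent by construction. Additive Gaussian noise (default σ = 6 raw gray
units, a realistic speckle-scale perturbation for 8-bit B-mode exports) is
followed by quantization and clipping. The ground-truth record stores the
exact normalized plaque mean implied by the painted integer value, so at
σ = 0 measurement is exact and at σ = 8 a ≥2000-pixel plaque recovers the
truth within 1 gray unit (a 3σ/√n bound with quantization headroom). What the
generator does **not** emulate: speckle correlation, depth-dependent
attenuation, shadowing and observer ambiguity at plaque borders — so passing
recovery tests validates the measurement arithmetic, not robustness to real
sonographic artifacts.

### Cohorts

`generate_cohort()` draws a population aged 45–74 with a 50/50 sex split.
All parameters live in one documented YAML
(`inst/extdata/cohort_defaults.yaml`). Three groups of defaults matter:

* **Prevalences and distributions.** Sex-specific diet-category and
  supplement probabilities are taken from the descriptive table of the cohort
  being emulated as *conditional-on-observed* probabilities (counts divided
  by observed n), with the matching sex-specific missingness rates stored
  alongside. Percentages recomputed over the full column after injecting the
  default missingness therefore reproduce the printed full-denominator
  percentages (e.g. 43.8% any-supplement use among women, 37.8% of women in
  MEDAS 6+, 2.4% folate supplementation among men) in expectation. Specific
  preparations are drawn only among any-supplement users, since "any
  supplement" covers more preparations than the six tracked flags.
  Comorbidity and medication prevalences and the SES/BMI/eGFR/energy
  distributions are plausible values for a European urban cohort of this age
  band; they are documented in the YAML and are not calibration targets.
* **Plaque model.** Plaque presence follows a logistic model whose
  coefficients encode the reported adjusted odds ratios (male 1.6, age 1.08
  per year, low education 1.4, hypertension 1.6, hyperlipidemia 1.5, smoking
  1.4; MEDAS high/low 1.07/0.86, DASH high/low 1.18/0.95, any supplement
  0.96; risk-factor magnitudes are plausible choices where only direction
  and significance were reported). The intercept is calibrated once, by
  root-finding on a large simulated linear-predictor sample, so the marginal
  prevalence is 21.63% (2163 of 10,000), and then frozen in the YAML.
* **GSM outcome.** For plaque-positive rows GSM is drawn from a sex-specific
  right-skewed shifted gamma. The three parameters (shape, scale, shift) are
  solved at run time from the target quartiles (men 46.0/56.5/68.5, women
  44.25/55.8/70.33): the quartile-skewness ratio pins the shape (it is
  monotone in it), then scale and shift follow in closed form. Covariate
  effects on GSM are zero by default except the declared folate effect in men
  (+9.12 GSM units), so adjusted-model recovery targets exactly one nonzero
  coefficient against a realistic covariate background.

Covariates are independent except the declared links (sex → diet, supplements
and outcome distribution; the plaque model's terms → plaque presence). Real
cohorts have richer correlation (diet with SES and smoking, comorbidity
clustering); recovery results here are therefore statements about the
pipeline's correctness under its own declared structure, not about robustness
to confounding patterns the generator does not contain.

Missingness injection is missing-at-random given sex by default (sex-specific
Bernoulli masking; sex and identifiers are never masked), with the original
values retained in a truth attribute.

## Numerical choices and problem sizes

* Rounding in normalization is half-up (`floor(x + 0.5)`), applied before
  clipping; banker's rounding would make anchor checks flaky at exact halves.
* PMM uses a proportional ridge of 1e-5 on the cross-product matrix; logistic
  draws cap linear predictors at ±30 before inverse-logit.
* The pooled fraction-of-missing-information is floored at 1e-12 so that
  zero-between-variance pooling yields the complete-data degrees of freedom
  instead of 0/0.
* Ties in PMM donor distances are broken by first occurrence after a uniform
  random donor-rank draw; imputation is exactly reproducible under a seed.
* Test and verification problem sizes were chosen to make Monte-Carlo bounds
  sharp but cheap: recovery of regression effects uses cohorts of 100,000
  (the folate effect in men is a ~2.5% exposure, so smaller cohorts leave the
  3-SE band uninformatively wide); calibration checks use 10,000–45,000;
  coverage uses 200 replicates at n = 5,000 with complete data, pooling the
  linear and logistic coverage events; the imputation stage itself is
  verified at m = 20 with 10 iterations on the plaque sub-cohort
  (~21,600 rows), the same configuration the analysis scripts use.

## Known limitations

* The echogenicity module ingests PNG exports, not DICOM; acquisition
  metadata never enters the pipeline.
* DASH/MEDAS threshold defaults are provisional stand-ins for the deployed
  instrument's appendix; they are configuration, not findings.
* The juxtaluminal black area (JBA), an alternative vulnerability marker, is
  out of scope.
* The generator's independence structure understates real-world confounding;
  see above.
* Logistic separation detection is heuristic (fitted probabilities within
  1e-7 of the boundary or non-convergence); penalized-likelihood fallbacks
  are not provided.
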