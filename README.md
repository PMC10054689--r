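# carotidgsm

Carotid plaques that look dark (echolucent) on B-mode ultrasound are
lipid-rich and rupture-prone; bright (echogenic) plaques are fibrous or
calcified and stable. The standard quantitative marker is the **gray-scale
median (GSM)** of the plaque region after anchored brightness normalization —
the vessel lumen is mapped to gray value 0 and the adventitia to 190, i.e.

```
g' = clip[0,255]( round( 190 * (g - L) / (A - L) ) )
```

with `L` and `A` the median raw gray values of the annotated lumen and
adventitia reference regions.

`carotidgsm` implements a full, tested analysis pipeline around this marker
for population-cohort studies of diet and atherosclerosis:

* **Echogenicity**: polygon annotations → even-odd rasterization → 3×3 median
  denoising → anchored normalization → plaque min/max/mean/median →
  participant-level GSM; interobserver agreement via ICC(2,1) and
  Bland–Altman limits, with outlier flagging for remeasurement.
* **Diet scores**: FFQ intake tables → nutrient/food-group profiles → MEDAS
  (14 binary items, categories 0–3 / 4 / 5 / 6+) and Folsom-style DASH
  scores (10 components at 0 / 0.5 / 1, categories 0–3.5 / 3.6–4.5 /
  4.6–5.0 / 5.1+), plus supplement-use coding.
* **Cohort models**: multiple imputation by chained equations (PMM +
  Bayesian logistic draws; m = 20, 10 iterations), Rubin's-rules pooling
  with Barnard–Rubin degrees of freedom, sex-stratified adjusted linear
  models of GSM in the plaque sub-cohort, adjusted logistic models of plaque
  presence in the full cohort (odds ratios for high/low vs medium diet
  adherence), and Table-1-style descriptives.
* **Synthetic data**: a generator for ultrasound-like frames with known
  plaque echogenicity and for cohorts with known effect sizes, prevalences
  and missing-at-random missingness, so every stage is verifiable by
  parameter recovery. All generator defaults live in
  `inst/extdata/cohort_defaults.yaml`.

The methods vignette (`vignettes/carotid-gsm-pipeline.Rmd`) documents the
model, all tunable parameters and the design decisions.

## Worked example

Measure a synthetic annotated frame and recover its known echogenicity:

```r
library(carotidgsm)

gi <- generate_image(image_spec(target_gsm = 56.5, sigma = 8), seed = 2)
measure_frame(gi$frame, gi$annotation)
#>    frame_id observer_id n_pixels gsm_min gsm_max gsm_mean gsm_median
#> 1 synthetic         sim     2024       5      68 55.58053         55
gi$ground_truth$gsm_mean
#> [1] 56
```

The measured plaque mean (55.58 over 2024 pixels) sits within one gray unit
of the generator's ground truth (56), as the 3σ/√n bound predicts at σ = 8.

Simulate a cohort, impute, and fit the sex-stratified GSM model for folate
supplementation (the generator's default male folate effect is +9.12 GSM
units):

```r
g      <- generate_cohort(20000, seed = 3)
sub    <- g$data[g$data$plaque_present, ]        # plaque sub-cohort
masked <- inject_missingness(sub, seed = 4)      # documented MAR rates
imp    <- mice_impute(masked, m = 5, iterations = 5, seed = 5)
fit    <- fit_gsm_linear(imp, "male", "folate")
fit[fit$term == "folateTRUE", c("term", "estimate", "se", "conf_low", "conf_high")]
#>         term estimate      se conf_low conf_high
#> 2 folateTRUE 13.18675 2.58009  7.97078  18.40271
```

The pooled estimate brackets the generating effect within sampling error
(about 50 folate-supplementing men carry the signal at this cohort size).
The plaque-presence side (generator default: DASH high-vs-medium odds ratio
1.18):

```r
pl <- fit_plaque_logistic(generate_cohort(100000, seed = 11)$data, "dash3")
pl[pl$term == "dash3high", c("term", "or", "or_low", "or_high")]
#>        term       or   or_low  or_high
#> 3 dash3high 1.180517 1.136037 1.226739
```

The numbered drivers under `analysis/` run the full narrative — simulate
frames, measure them, simulate the 10,000-participant cohort, score diets,
fit all models — writing tables under `results/`.

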