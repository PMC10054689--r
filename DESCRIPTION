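Package: carotidgsm
Title: Carotid Plaque Echogenicity, Diet Scores and Sex-Stratified Cohort Models
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Measures carotid-plaque echogenicity (gray-scale median, GSM) from
    annotated B-mode ultrasound frames using anchored two-point brightness
    normalization (lumen = 0, adventitia = 190), computes MEDAS and DASH
    dietary-adherence scores from food-frequency-questionnaire style intake
    tables, and estimates sex-stratified associations of diet and supplement
    use with plaque GSM (linear models) and plaque presence (logistic models)
    under multiple imputation by chained equations with Rubin's-rules pooling.
    A synthetic-data module generates ultrasound-like frames with known plaque
    echogenicity and population-style cohorts with known effect sizes,
    prevalences and missing-at-random missingness, so the entire pipeline is
    verifiable by parameter recovery.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    png,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    mgcv,
    withr
Config/testthat/edition: 3
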