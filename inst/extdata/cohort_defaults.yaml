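# Default parameters of the synthetic cohort generator.
#
# The generator emulates a population-based cardiovascular cohort aged 45-74
# with carotid ultrasound: a logistic model decides plaque presence, a
# sex-specific right-skewed outcome model draws plaque GSM, and diet-score /
# supplement prevalences, comorbidity prevalences and per-variable
# missingness follow the published descriptives of the cohort the package
# emulates (diet/supplement probabilities are conditional on being observed;
# the matching missingness rates are listed under `missingness`, so that
# full-denominator percentages reproduce the printed descriptive table).
# Covariates are independent except the declared links: sex drives diet and
# supplement probabilities and the outcome distribution; age, sex, education,
# hypertension, dyslipidemia, smoking and the diet/supplement terms drive
# plaque presence.

p_female: 0.5
age: {min: 45, max: 74, center: 59.5}

# ISCED 2011 level probabilities (levels 0-8); collapsed to low/medium/high.
isced_probs: [0.002, 0.013, 0.135, 0.450, 0.050, 0.080, 0.120, 0.120, 0.030]

ses:   {male: {mean: 13.3, sd: 4.2}, female: {mean: 11.4, sd: 3.6}, min: 0, max: 30}
bmi:   {meanlog_of: 26.5, sdlog: 0.14}
egfr:  {male: {mean: 89, sd: 10}, female: {mean: 85, sd: 10}, min: 15, max: 150}
energy_kcal:
  male:   {median: 2311.52, sdlog: 0.316}
  female: {median: 1729.92, sdlog: 0.291}

prevalence:
  smoking: 0.22
  no_sports: {male: 0.32, female: 0.27}
  dyslipidemia: 0.30
  hypertension: 0.55
  diabetes: 0.10
  prior_mi: 0.04
  heart_failure: 0.05
  atrial_fibrillation: 0.06
  prior_stroke_tia: 0.035
  pad: 0.09
  lipid_lowering: 0.22
  antihypertensives: 0.40
  antidiabetics: 0.08
  antiplatelets: 0.18

# Diet-adherence category probabilities by sex, conditional on observed
# (counts / observed n of the emulated descriptive table).
medas_probs:
  levels: ["0-3", "4", "5", "6+"]
  male:   [0.411818, 0.247273, 0.159091, 0.181818]
  female: [0.150183, 0.203907, 0.221001, 0.424908]
dash_probs:
  levels: ["0-3.5", "3.6-4.5", "4.6-5.0", "5.1+"]
  male:   [0.359091, 0.342727, 0.138182, 0.160000]
  female: [0.114774, 0.324786, 0.211233, 0.349206]

# Supplement use, conditional on observed. Specific preparations are drawn
# only among any-supplement users (P(flag | any) = p_flag / p_any), because
# "any supplement" also covers preparations beyond the six tracked ones.
supplements:
  any_supplement: {male: 0.308231, female: 0.477488}
  multivitamins:  {male: 0.084063, female: 0.084123}
  multiminerals:  {male: 0.068301, female: 0.120853}
  calcium:        {male: 0.059545, female: 0.069905}
  magnesium:      {male: 0.156743, female: 0.240521}
  vitamin_B:      {male: 0.039405, female: 0.077014}
  folate:         {male: 0.026270, female: 0.054502}

# Logistic model for plaque presence (log odds ratios). The intercept is
# calibrated so the marginal prevalence is 0.2163 under these defaults.
plaque_model:
  intercept: -2.182328
  male: 0.470004          # OR 1.6
  age_per_year: 0.076961  # OR 1.08 per year, age centered at `age$center`
  education_low: 0.336472 # OR 1.4 vs medium/high
  hypertension: 0.470004  # OR 1.6
  dyslipidemia: 0.405465  # OR 1.5
  smoking: 0.336472       # OR 1.4
  medas_high: 0.067659    # OR 1.07 (6+ vs 4-5)
  medas_low: -0.150823    # OR 0.86 (0-3 vs 4-5)
  dash_high: 0.165514     # OR 1.18 (5.1+ vs 3.6-5.0)
  dash_low: -0.051293     # OR 0.95 (0-3.5 vs 3.6-5.0)
  any_supplement: -0.040822  # OR 0.96

# GSM outcome model for plaque-positive rows: a shifted gamma calibrated to
# the sex-specific median and quartiles, plus the declared effects. All other
# covariate effects on GSM are zero by default.
gsm_model:
  male:   {q25: 46.00, median: 56.50, q75: 68.50}
  female: {q25: 44.25, median: 55.80, q75: 70.33}
  effects:
    folate_male: 9.12
    folate_female: 0.0

# Per-variable missingness rates by sex (missing-at-random given sex);
# rates are the NA fractions of the emulated descriptive table.
missingness:
  ses:                 {male: 0.525765, female: 0.710098}
  bmi:                 {male: 0.053945, female: 0.068404}
  smoking:             {male: 0.004026, female: 0.006515}
  no_sports:           {male: 0.080515, female: 0.086862}
  energy_kcal:         {male: 0.113527, female: 0.109664}
  medas_category:      {male: 0.114332, female: 0.110749}
  dash_category:       {male: 0.114332, female: 0.110749}
  any_supplement:      {male: 0.080515, female: 0.083605}
  multivitamins:       {male: 0.080515, female: 0.083605}
  multiminerals:       {male: 0.080515, female: 0.083605}
  calcium:             {male: 0.080515, female: 0.083605}
  magnesium:           {male: 0.080515, female: 0.083605}
  vitamin_B:           {male: 0.080515, female: 0.083605}
  folate:              {male: 0.080515, female: 0.083605}
  dyslipidemia:        {male: 0.042673, female: 0.051031}
  hypertension:        {male: 0.035427, female: 0.019544}
  diabetes:            {male: 0.047504, female: 0.064061}
  prior_mi:            {male: 0.008052, female: 0.007600}
  heart_failure:       {male: 0.012077, female: 0.005429}
  atrial_fibrillation: {male: 0.081320, female: 0.106406}
  prior_stroke_tia:    {male: 0.005636, female: 0.010858}
  pad:                 {male: 0.519324, female: 0.537459}
  egfr:                {male: 0.084541, female: 0.115092}
  lipid_lowering:      {male: 0.031401, female: 0.022801}
  antihypertensives:   {male: 0.031401, female: 0.022801}
  antidiabetics:       {male: 0.031401, female: 0.022801}
  antiplatelets:       {male: 0.031401, female: 0.022801}
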