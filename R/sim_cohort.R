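#' Cohort generator specification
#'
#' Loads the documented default parameters of the synthetic cohort generator
#' (see `system.file("extdata", "cohort_defaults.yaml", package =
#' "carotidgsm")`) and applies any overrides. The defaults encode the
#' descriptives and effect sizes of the population cohort the package
#' emulates: sex-specific diet-score and supplement prevalences, plausible
#' covariate distributions for ages 45-74, a plaque-presence logistic model
#' whose intercept is calibrated to a marginal prevalence of 21.63%, and a
#' sex-specific shifted-gamma GSM outcome model calibrated to the printed
#' medians and quartiles.
#'
#' @param ... named overrides merged into the default list (nested lists are
#'   merged with [utils::modifyList()]).
#' @return A list of class `cohort_spec`.
#' @export
cohort_spec <- function(...) {
  path <- system.file("extdata", "cohort_defaults.yaml", package = "carotidgsm")
  spec <- yaml::read_yaml(path)
  dots <- list(...)
  if (length(dots)) spec <- utils::modifyList(spec, dots)
  structure(spec, class = c("cohort_spec", "list"))
}

#' Calibrate a shifted gamma to a median and quartiles
#'
#' Solves for shape, scale and shift of `shift + Gamma(shape, scale)` so that
#' its 25th, 50th and 75th percentiles match the targets. The quartile
#' skewness `(q75 - q50)/(q50 - q25)` pins down the shape (it is monotone in
#' it); scale and shift follow in closed form.
#'
#' @param q25,q50,q75 target quartiles (must be strictly increasing with
#'   right skew, i.e. `q75 - q50 > q50 - q25`... the ratio must exceed the
#'   symmetric limit of 1).
#' @return List with `shape`, `scale`, `shift`.
#' @export
calibrate_shifted_gamma <- function(q25, q50, q75) {
  if (!(q25 < q50 && q50 < q75)) stop_gsm("bad_spec", "quartiles must increase")
  target_ratio <- (q75 - q50) / (q50 - q25)
  ratio <- function(logk) {
    k <- exp(logk)
    q <- stats::qgamma(c(0.25, 0.5, 0.75), shape = k, rate = 1)
    (q[3] - q[2]) / (q[2] - q[1])
  }
  if (target_ratio <= 1) stop_gsm("bad_spec", "distribution must be right-skewed")
  sol <- stats::uniroot(function(lk) ratio(lk) - target_ratio,
                        interval = c(-4, 12), tol = 1e-10)
  shape <- exp(sol$root)
  qg <- stats::qgamma(c(0.25, 0.5, 0.75), shape = shape, rate = 1)
  scale <- (q75 - q25) / (qg[3] - qg[1])
  shift <- q50 - scale * qg[2]
  list(shape = shape, scale = scale, shift = shift)
}

#' Draw plaque GSM values from the generator's outcome model
#'
#' Baseline GSM (before covariate effects) for one sex stratum: a shifted
#' gamma calibrated to the stratum's target quartiles, clipped to \[0, 255\].
#'
#' @param n number of draws.
#' @param sex `"male"` or `"female"`.
#' @param spec a [cohort_spec()].
#' @return Numeric vector of GSM values.
#' @export
draw_gsm <- function(n, sex = c("male", "female"), spec = cohort_spec()) {
  sex <- match.arg(sex)
  tg <- spec$gsm_model[[sex]]
  par <- calibrate_shifted_gamma(tg$q25, tg$median, tg$q75)
  g <- par$shift + stats::rgamma(n, shape = par$shape, scale = par$scale)
  pmin(pmax(g, 0), 255)
}

#' Generate a synthetic cohort with known effects
#'
#' Draws `n` participants: covariates per the spec's distributions, plaque
#' presence from the spec's logistic model, and GSM for plaque-positive rows
#' from the sex-specific outcome model plus the declared effects (by default
#' only folate supplementation in men shifts GSM). The returned truth record
#' holds every coefficient used, sufficient to score parameter recovery.
#'
#' @param n cohort size.
#' @param spec a [cohort_spec()].
#' @param seed integer seed; the same seed yields an identical table.
#' @return List with `data` (the cohort data frame, `gsm` is `NA` where
#'   `plaque_present` is `FALSE`) and `truth` (generator parameters).
#' @export
generate_cohort <- function(n, spec = cohort_spec(), seed = NULL) {
  if (n < 1L) stop_gsm("bad_spec", "n must be at least 1")
  if (!is.null(seed)) set.seed(seed)
  sex <- factor(ifelse(stats::runif(n) < spec$p_female, "female", "male"),
                levels = c("male", "female"))
  male <- sex == "male"
  n_m <- sum(male); n_f <- n - n_m

  age <- sample(spec$age$min:spec$age$max, n, replace = TRUE)
  isced <- sample(0:8, n, replace = TRUE, prob = spec$isced_probs)
  education_category <- categorize_education(isced)

  by_sex_norm <- function(cfg) {
    out <- numeric(n)
    out[male] <- stats::rnorm(n_m, cfg$male$mean, cfg$male$sd)
    out[!male] <- stats::rnorm(n_f, cfg$female$mean, cfg$female$sd)
    pmin(pmax(out, cfg$min), cfg$max)
  }
  ses <- by_sex_norm(spec$ses)
  egfr <- by_sex_norm(spec$egfr)
  bmi <- stats::rlnorm(n, log(spec$bmi$meanlog_of), spec$bmi$sdlog)
  energy <- numeric(n)
  energy[male] <- stats::rlnorm(n_m, log(spec$energy_kcal$male$median),
                                spec$energy_kcal$male$sdlog)
  energy[!male] <- stats::rlnorm(n_f, log(spec$energy_kcal$female$median),
                                 spec$energy_kcal$female$sdlog)

  draw_flag <- function(p) {
    if (is.list(p)) {
      out <- logical(n)
      out[male] <- stats::runif(n_m) < p$male
      out[!male] <- stats::runif(n_f) < p$female
      out
    } else {
      stats::runif(n) < p
    }
  }
  prev <- spec$prevalence
  smoking <- draw_flag(prev$smoking)
  no_sports <- draw_flag(prev$no_sports)
  dyslipidemia <- draw_flag(prev$dyslipidemia)
  hypertension <- draw_flag(prev$hypertension)
  diabetes <- draw_flag(prev$diabetes)
  prior_mi <- draw_flag(prev$prior_mi)
  heart_failure <- draw_flag(prev$heart_failure)
  atrial_fibrillation <- draw_flag(prev$atrial_fibrillation)
  prior_stroke_tia <- draw_flag(prev$prior_stroke_tia)
  pad <- draw_flag(prev$pad)
  lipid_lowering <- draw_flag(prev$lipid_lowering)
  antihypertensives <- draw_flag(prev$antihypertensives)
  antidiabetics <- draw_flag(prev$antidiabetics)
  antiplatelets <- draw_flag(prev$antiplatelets)

  draw_cat <- function(cfg, ordered_levels) {
    out <- character(n)
    out[male] <- sample(cfg$levels, n_m, replace = TRUE, prob = cfg$male)
    out[!male] <- sample(cfg$levels, n_f, replace = TRUE, prob = cfg$female)
    factor(out, levels = ordered_levels, ordered = TRUE)
  }
  medas_category <- draw_cat(spec$medas_probs, spec$medas_probs$levels)
  dash_category <- draw_cat(spec$dash_probs, spec$dash_probs$levels)

  supp <- spec$supplements
  p_any <- ifelse(male, supp$any_supplement$male, supp$any_supplement$female)
  any_supplement <- stats::runif(n) < p_any
  draw_supp <- function(cfg) {
    p_cond <- ifelse(male, cfg$male / supp$any_supplement$male,
                     cfg$female / supp$any_supplement$female)
    any_supplement & (stats::runif(n) < p_cond)
  }
  multivitamins <- draw_supp(supp$multivitamins)
  multiminerals <- draw_supp(supp$multiminerals)
  calcium <- draw_supp(supp$calcium)
  magnesium <- draw_supp(supp$magnesium)
  vitamin_B <- draw_supp(supp$vitamin_B)
  folate <- draw_supp(supp$folate)

  pm <- spec$plaque_model
  medas3 <- collapse_medas(medas_category)
  dash3 <- collapse_dash(dash_category)
  lp <- pm$intercept +
    pm$male * male +
    pm$age_per_year * (age - spec$age$center) +
    pm$education_low * (education_category == "low") +
    pm$hypertension * hypertension +
    pm$dyslipidemia * dyslipidemia +
    pm$smoking * smoking +
    pm$medas_high * (medas3 == "high") +
    pm$medas_low * (medas3 == "low") +
    pm$dash_high * (dash3 == "high") +
    pm$dash_low * (dash3 == "low") +
    pm$any_supplement * any_supplement
  plaque_present <- stats::runif(n) < stats::plogis(lp)

  gsm <- rep(NA_real_, n)
  idx_m <- which(plaque_present & male)
  idx_f <- which(plaque_present & !male)
  gsm[idx_m] <- draw_gsm(length(idx_m), "male", spec)
  gsm[idx_f] <- draw_gsm(length(idx_f), "female", spec)
  eff <- spec$gsm_model$effects
  gsm[idx_m] <- gsm[idx_m] + eff$folate_male * folate[idx_m]
  gsm[idx_f] <- gsm[idx_f] + eff$folate_female * folate[idx_f]
  gsm <- pmin(pmax(gsm, 0), 255)

  data <- data.frame(
    participant_id = sprintf("P%06d", seq_len(n)),
    sex = sex, age = age, isced_level = isced,
    education_category = education_category,
    ses = ses, bmi = bmi, smoking = smoking, no_sports = no_sports,
    energy_kcal = energy, egfr = egfr,
    dyslipidemia = dyslipidemia, hypertension = hypertension,
    diabetes = diabetes, prior_mi = prior_mi, heart_failure = heart_failure,
    atrial_fibrillation = atrial_fibrillation,
    prior_stroke_tia = prior_stroke_tia, pad = pad,
    lipid_lowering = lipid_lowering, antihypertensives = antihypertensives,
    antidiabetics = antidiabetics, antiplatelets = antiplatelets,
    medas_category = medas_category, dash_category = dash_category,
    any_supplement = any_supplement, multivitamins = multivitamins,
    multiminerals = multiminerals, calcium = calcium, magnesium = magnesium,
    vitamin_B = vitamin_B, folate = folate,
    plaque_present = plaque_present, gsm = gsm,
    stringsAsFactors = FALSE)

  list(data = data,
       truth = list(plaque_model = pm, gsm_effects = eff,
                    gsm_model = spec$gsm_model, n = n, seed = seed))
}

#' Mask cells to emulate missingness
#'
#' Replaces cells with `NA` per variable-specific rates. Mechanisms:
#' `"mar_sex"` (rates differ by sex, missing-at-random given sex — sex and
#' the identifier themselves are never masked) or `"mcar"` (a single rate per
#' variable; sex-specific rates are averaged). The pre-masking values are
#' kept in the `truth` attribute and the masked-cell indicator in `mask`.
#'
#' @param data cohort data frame.
#' @param rates named list: per variable either a single rate or
#'   `list(male =, female =)`. Default: the generator's documented rates.
#' @param mechanism `"mar_sex"` or `"mcar"`.
#' @param seed integer seed.
#' @return The data frame with `NA`s injected; attributes `truth` (original
#'   data) and `mask` (logical data frame of masked cells).
#' @export
inject_missingness <- function(data, rates = cohort_spec()$missingness,
                               mechanism = c("mar_sex", "mcar"), seed = NULL) {
  mechanism <- match.arg(mechanism)
  if (!is.null(seed)) set.seed(seed)
  male <- data$sex == "male"
  out <- data
  mask <- as.data.frame(matrix(FALSE, nrow(data), ncol(data),
                               dimnames = list(NULL, names(data))))
  for (v in names(rates)) {
    if (!v %in% names(data)) next
    r <- rates[[v]]
    if (is.list(r)) {
      if (any(unlist(r) > 1 | unlist(r) < 0)) stop_gsm("bad_spec", "rates must be in [0, 1]")
      p <- if (mechanism == "mar_sex") ifelse(male, r$male, r$female)
           else (r$male + r$female) / 2
    } else {
      if (r > 1 || r < 0) stop_gsm("bad_spec", "rates must be in [0, 1]")
      p <- rep(r, nrow(data))
    }
    hit <- stats::runif(nrow(data)) < p
    out[[v]][hit] <- NA
    mask[[v]] <- hit
  }
  attr(out, "truth") <- data
  attr(out, "mask") <- mask
  out
}
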