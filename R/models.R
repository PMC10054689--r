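#' Adjustment sets for the cohort models
#'
#' `gsm_covariates()` is the adjustment list for the linear GSM models (fitted
#' in the plaque sub-cohort): physical inactivity, age, socioeconomic-status
#' index, BMI, smoking, energy intake, dyslipidemia, hypertension, diabetes,
#' prior myocardial infarction, heart failure, atrial fibrillation, prior
#' stroke/TIA, peripheral artery disease, eGFR and four medication classes.
#' `plaque_covariates()` is the adjustment list for the logistic
#' plaque-presence models (full cohort): age, sex, education category, BMI,
#' diabetes, hypertension, dyslipidemia, smoking, heart failure, atrial
#' fibrillation, myocardial infarction, stroke and physical inactivity.
#'
#' @return Character vector of column names.
#' @export
gsm_covariates <- function() {
  c("no_sports", "age", "ses", "bmi", "smoking", "energy_kcal",
    "dyslipidemia", "hypertension", "diabetes", "prior_mi", "heart_failure",
    "atrial_fibrillation", "prior_stroke_tia", "pad", "egfr",
    "lipid_lowering", "antihypertensives", "antidiabetics", "antiplatelets")
}

#' @rdname gsm_covariates
#' @export
plaque_covariates <- function() {
  c("age", "sex", "education_category", "bmi", "diabetes", "hypertension",
    "dyslipidemia", "smoking", "heart_failure", "atrial_fibrillation",
    "prior_mi", "prior_stroke_tia", "no_sports")
}

#' Collapse four diet-adherence categories into low/medium/high
#'
#' For the plaque-presence models the four adherence categories are collapsed
#' to three groups with `medium` as the reference: MEDAS `low` = 0-3 points,
#' `medium` = 4-5, `high` = 6+; DASH `low` = 0-3.5 points, `medium` =
#' 3.6-5.0, `high` = 5.1+.
#'
#' @param category factor of MEDAS/DASH categories.
#' @return Factor with levels `medium`, `low`, `high` (`medium` = reference).
#' @export
collapse_medas <- function(category) {
  map <- c("0-3" = "low", "4" = "medium", "5" = "medium", "6+" = "high")
  factor(unname(map[as.character(category)]), levels = c("medium", "low", "high"))
}

#' @rdname collapse_medas
#' @export
collapse_dash <- function(category) {
  map <- c("0-3.5" = "low", "3.6-4.5" = "medium", "4.6-5.0" = "medium",
           "5.1+" = "high")
  factor(unname(map[as.character(category)]), levels = c("medium", "low", "high"))
}

#' Sex-stratified adjusted linear model for plaque GSM
#'
#' Ordinary least squares of participant GSM on one exposure plus the full
#' adjustment set ([gsm_covariates()]), fitted within one sex stratum of the
#' plaque sub-cohort in each completed dataset and pooled with Rubin's rules.
#' Exposures: `"medas_category"` (reference `0-3`, i.e. < 4 points),
#' `"dash_category"` (reference `0-3.5`, i.e. < 3.6 points) or one supplement
#' flag (reference: no intake). Each exposure is analyzed in its own model.
#'
#' @param imputations an `imputation_set` from [mice_impute()], or a single
#'   complete data frame (then a single unpooled fit is returned in the same
#'   layout).
#' @param stratum `"male"` or `"female"`.
#' @param exposure exposure column name.
#' @param covariates adjustment set; default [gsm_covariates()].
#' @return Pooled fit data frame (see [pool_rubin()]) with attributes
#'   `family = "linear"` and `stratum`.
#' @export
fit_gsm_linear <- function(imputations, stratum = c("male", "female"), exposure,
                           covariates = gsm_covariates()) {
  stratum <- match.arg(stratum)
  form <- stats::reformulate(c(exposure, covariates), response = "gsm")
  fit_one <- function(dat) {
    dat <- dat[dat$sex == stratum & !is.na(dat$gsm), , drop = FALSE]
    if (nrow(dat) == 0L) stop_gsm("bad_argument", "empty stratum")
    fit <- stats::lm(form, data = dat)
    cf <- stats::coef(fit)
    if (anyNA(cf)) {
      stop_gsm("rank_deficient",
               paste("aliased terms in the GSM model:",
                     paste(names(cf)[is.na(cf)], collapse = ", ")))
    }
    list(estimate = cf, variance = diag(stats::vcov(fit)),
         dfcom = fit$df.residual)
  }
  pooled <- pool_fits(imputations, fit_one)
  attr(pooled, "family") <- "linear"
  attr(pooled, "stratum") <- stratum
  pooled
}

#' Adjusted logistic model for plaque presence
#'
#' Logistic regression of plaque presence on one exposure plus the adjustment
#' set ([plaque_covariates()]), in the full cohort. Exposures:
#' `"dash3"` / `"medas3"` (high and low adherence vs medium, via
#' [collapse_dash()] / [collapse_medas()]) or `"any_supplement"` (yes vs no).
#' Given an `imputation_set` the fits are pooled with Rubin's rules;
#' given a data frame a single (complete-case) fit is returned.
#' Odds ratios are exponentiated coefficients with Wald 95% CIs.
#'
#' @param x `imputation_set` or data frame with a logical `plaque_present`.
#' @param exposure `"dash3"`, `"medas3"` or `"any_supplement"`.
#' @param covariates adjustment set; default [plaque_covariates()].
#' @return Pooled fit data frame with extra columns `or`, `or_low`, `or_high`
#'   and attribute `family = "logistic"`.
#' @export
fit_plaque_logistic <- function(x, exposure = c("dash3", "medas3", "any_supplement"),
                                covariates = plaque_covariates()) {
  exposure <- match.arg(exposure)
  fit_one <- function(dat) {
    dat <- add_collapsed_scores(dat)
    dat <- dat[stats::complete.cases(dat[, c("plaque_present", exposure, covariates)]), ]
    y <- dat$plaque_present
    if (length(unique(y)) < 2L) {
      stop_gsm("single_class", "plaque_present has a single class")
    }
    form <- stats::reformulate(c(exposure, covariates),
                               response = "plaque_present")
    fit <- withCallingHandlers(
      stats::glm(form, data = dat, family = stats::binomial()),
      warning = function(w) {
        if (grepl("fitted probabilities numerically 0 or 1", conditionMessage(w))) {
          stop_gsm("separation", "complete or quasi-complete separation detected")
        }
        invokeRestart("muffleWarning")
      })
    cf <- stats::coef(fit)
    if (anyNA(cf)) {
      stop_gsm("rank_deficient",
               paste("aliased terms in the plaque model:",
                     paste(names(cf)[is.na(cf)], collapse = ", ")))
    }
    mu <- stats::fitted(fit)
    if (!fit$converged || any(mu > 1 - 1e-7) || any(mu < 1e-7)) {
      stop_gsm("separation", "complete or quasi-complete separation detected")
    }
    list(estimate = cf, variance = diag(stats::vcov(fit)),
         dfcom = nrow(dat) - length(cf))
  }
  pooled <- pool_fits(x, fit_one)
  pooled$or <- exp(pooled$estimate)
  pooled$or_low <- exp(pooled$conf_low)
  pooled$or_high <- exp(pooled$conf_high)
  attr(pooled, "family") <- "logistic"
  pooled
}

add_collapsed_scores <- function(dat) {
  if (!"medas3" %in% names(dat) && "medas_category" %in% names(dat)) {
    dat$medas3 <- collapse_medas(dat$medas_category)
  }
  if (!"dash3" %in% names(dat) && "dash_category" %in% names(dat)) {
    dat$dash3 <- collapse_dash(dat$dash_category)
  }
  dat
}

# Run a single-dataset fitter over either an imputation set (pool) or one
# data frame (plain fit reported in the pooled layout, B = 0).
pool_fits <- function(x, fit_one) {
  if (inherits(x, "imputation_set")) {
    fits <- lapply(x$imputations, fit_one)
    est <- lapply(fits, `[[`, "estimate")
    va <- lapply(fits, `[[`, "variance")
    dfcom <- fits[[1]]$dfcom
    pool_rubin(est, va, dfcom = dfcom)
  } else {
    f <- fit_one(x)
    se <- sqrt(f$variance)
    tcrit <- stats::qt(0.975, f$dfcom)
    stat <- f$estimate / se
    data.frame(term = names(f$estimate),
               estimate = unname(f$estimate),
               se = unname(se),
               W = unname(f$variance),
               B = 0,
               T = unname(f$variance),
               df = f$dfcom,
               conf_low = unname(f$estimate - tcrit * se),
               conf_high = unname(f$estimate + tcrit * se),
               p_value = unname(2 * stats::pt(-abs(stat), f$dfcom)),
               m = 1L,
               row.names = NULL,
               stringsAsFactors = FALSE)
  }
}
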