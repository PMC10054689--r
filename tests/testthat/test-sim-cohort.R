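test_that("the cohort generator is deterministic under a seed", {
  a <- generate_cohort(500, seed = 5)$data
  b <- generate_cohort(500, seed = 5)$data
  expect_identical(a, b)
})

test_that("with all coefficients zero the intercept fixes the prevalence", {
  spec <- cohort_spec()
  spec$plaque_model <- lapply(spec$plaque_model, function(x) 0)
  spec$plaque_model$intercept <- qlogis(0.2163)
  g <- generate_cohort(20000, spec, seed = 6)$data
  p_hat <- mean(g$plaque_present)
  se <- sqrt(0.2163 * (1 - 0.2163) / 20000)
  expect_lt(abs(p_hat - 0.2163), 3 * se)
})

test_that("the truth record carries the generating coefficients", {
  g <- generate_cohort(100, seed = 7)
  expect_equal(g$truth$gsm_effects$folate_male, 9.12)
  expect_equal(exp(g$truth$plaque_model$dash_high), 1.18, tolerance = 1e-4)
  expect_true(all(c("plaque_model", "gsm_model", "n", "seed") %in% names(g$truth)))
})

test_that("GSM is present exactly for plaque-positive rows and lies in [0, 255]", {
  g <- generate_cohort(5000, seed = 8)$data
  expect_true(all(is.na(g$gsm[!g$plaque_present])))
  expect_false(anyNA(g$gsm[g$plaque_present]))
  expect_true(all(g$gsm >= 0 & g$gsm <= 255, na.rm = TRUE))
  expect_true(all(g$age >= 45 & g$age <= 74))
})

test_that("the calibrated shifted gamma reproduces its target quartiles", {
  for (sex in c("male", "female")) {
    tg <- cohort_spec()$gsm_model[[sex]]
    par <- calibrate_shifted_gamma(tg$q25, tg$median, tg$q75)
    q <- par$shift + qgamma(c(0.25, 0.5, 0.75), shape = par$shape,
                            scale = par$scale)
    expect_equal(q, c(tg$q25, tg$median, tg$q75), tolerance = 1e-6)
  }
  expect_error(calibrate_shifted_gamma(50, 60, 65), class = "gsm_bad_spec")
})

test_that("specific supplement flags only occur among any-supplement users", {
  g <- generate_cohort(5000, seed = 9)$data
  flags <- g[, c("multivitamins", "multiminerals", "calcium", "magnesium",
                 "vitamin_B", "folate")]
  expect_true(all(!apply(flags, 1, any) | g$any_supplement))
})

test_that("missingness injection hits the requested rates and keeps the truth", {
  g <- generate_cohort(10000, seed = 10)$data
  masked <- inject_missingness(g, rates = list(energy_kcal = 0.112),
                               mechanism = "mcar", seed = 11)
  p_hat <- mean(is.na(masked$energy_kcal))
  se <- sqrt(0.112 * 0.888 / 10000)
  expect_lt(abs(p_hat - 0.112), 3 * se)
  truth <- attr(masked, "truth")
  expect_identical(truth$energy_kcal, g$energy_kcal)
  mask <- attr(masked, "mask")
  expect_equal(sum(mask$energy_kcal), sum(is.na(masked$energy_kcal)))
  # rate 0 leaves the table unchanged
  un <- inject_missingness(g, rates = list(energy_kcal = 0), seed = 12)
  expect_identical(un$energy_kcal, g$energy_kcal)
  expect_error(inject_missingness(g, rates = list(bmi = 1.2)),
               class = "gsm_bad_spec")
})

test_that("sex-specific missingness is steeper for the sex with the higher rate", {
  g <- generate_cohort(20000, seed = 13)$data
  masked <- inject_missingness(g, seed = 14)  # default rates, MAR on sex
  na_rate <- tapply(is.na(masked$ses), g$sex, mean)
  expect_gt(na_rate[["female"]], na_rate[["male"]])
})
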