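test_that("FFQ aggregation is linear in intakes", {
  comp <- synthetic_composition()
  ffq <- data.frame(participant_id = "p1", item = "bread",
                    freq_per_day = 2, portion_g = 100)
  prof <- ffq_to_profile(ffq, comp)
  expect_equal(prof$energy_kcal, 2 * 100 * 2.5)  # 500 kcal/day
  expect_equal(prof$serv_grains, 2 * 100 * 0.0125)

  # all-zero intakes give an all-zero profile
  ffq0 <- data.frame(participant_id = "p1", item = c("bread", "milk"),
                     freq_per_day = 0, portion_g = c(50, 200))
  prof0 <- ffq_to_profile(ffq0, comp)
  expect_true(all(prof0[, -1] == 0))

  # doubling every frequency doubles every field
  set.seed(41)
  ffq2 <- data.frame(participant_id = rep(c("p1", "p2"), each = 6),
                     item = sample(comp$item, 12, replace = TRUE),
                     freq_per_day = runif(12, 0, 3),
                     portion_g = runif(12, 10, 300))
  p1 <- ffq_to_profile(ffq2, comp)
  ffq2$freq_per_day <- 2 * ffq2$freq_per_day
  p2 <- ffq_to_profile(ffq2, comp)
  expect_equal(as.matrix(p2[, -1]), 2 * as.matrix(p1[, -1]))

  expect_error(ffq_to_profile(transform(ffq, item = "unobtanium"), comp),
               class = "gsm_unknown_item")
})

test_that("MEDAS totals and categories follow the published cutpoints", {
  all1 <- matrix(1, 1, 14); all0 <- matrix(0, 1, 14)
  expect_equal(score_medas(all1)$medas_total, 14L)
  expect_equal(as.character(score_medas(all1)$medas_category), "6+")
  expect_equal(score_medas(all0)$medas_total, 0L)
  expect_equal(as.character(score_medas(all0)$medas_category), "0-3")
  # category is a pure function of the total, checked over all attainable totals
  expect_equal(as.character(medas_category(0:14)),
               c(rep("0-3", 4), "4", "5", rep("6+", 9)))
  expect_error(score_medas(matrix(1, 1, 13)), class = "gsm_bad_argument")
  expect_error(score_medas(matrix(2, 1, 14)), class = "gsm_bad_argument")
})

test_that("missing MEDAS items contribute zero and are flagged", {
  resp <- matrix(1, 2, 14)
  resp[2, c(3, 7)] <- NA
  sc <- score_medas(resp)
  expect_equal(sc$medas_total, c(14L, 12L))
  expect_equal(sc$n_missing, c(0L, 2L))
})

test_that("DASH component scoring and categories behave per the 0/0.5/1 scheme", {
  comp_targets <- dash_default_config()
  # a profile meeting every target
  best <- data.frame(participant_id = 1, serv_grains = 8, serv_vegetables = 5,
                     serv_fruits = 5, serv_dairy = 3, serv_meat = 1,
                     serv_nuts_seeds_legumes = 1, serv_sweets = 0.2,
                     saturated_fat_g = 10, fat_g = 50, sodium_mg = 1500,
                     energy_kcal = 2000)
  # saturated fat 10g*9/2000 = 4.5% energy (target <= 6), fat 22.5% (<= 27)
  expect_equal(score_dash(best, comp_targets)$dash_total, 10)
  worst <- data.frame(participant_id = 1, serv_grains = 1, serv_vegetables = 0.5,
                      serv_fruits = 0.5, serv_dairy = 0.2, serv_meat = 5,
                      serv_nuts_seeds_legumes = 0.1, serv_sweets = 3,
                      saturated_fat_g = 40, fat_g = 90, sodium_mg = 5000,
                      energy_kcal = 2000)
  expect_equal(score_dash(worst, comp_targets)$dash_total, 0)
  # category boundaries at the printed cutpoints
  expect_equal(as.character(dash_category(c(3.5, 4.5, 5.0, 5.5))),
               c("0-3.5", "3.6-4.5", "4.6-5.0", "5.1+"))
  # every attainable total (multiples of 0.5) lands in exactly one category
  totals <- seq(0, 10, by = 0.5)
  expect_false(anyNA(dash_category(totals)))
})

test_that("improving a single DASH component never lowers the total", {
  cfg <- dash_default_config()
  base <- data.frame(participant_id = 1, serv_grains = 4, serv_vegetables = 2.5,
                     serv_fruits = 1, serv_dairy = 1.5, serv_meat = 2.5,
                     serv_nuts_seeds_legumes = 0.4, serv_sweets = 1,
                     saturated_fat_g = 20, fat_g = 70, sodium_mg = 3000,
                     energy_kcal = 2200)
  t0 <- score_dash(base, cfg)$dash_total
  better <- base; better$serv_fruits <- 5
  expect_gte(score_dash(better, cfg)$dash_total, t0)
  lower_sodium <- base; lower_sodium$sodium_mg <- 1000
  expect_gte(score_dash(lower_sodium, cfg)$dash_total, t0)
})

test_that("missing DASH components score zero conservatively and are counted", {
  cfg <- dash_default_config()
  prof <- data.frame(participant_id = 1, serv_grains = 8, serv_vegetables = 5,
                     serv_fruits = NA, serv_dairy = 3, serv_meat = 1,
                     serv_nuts_seeds_legumes = 1, serv_sweets = 0.2,
                     saturated_fat_g = 10, fat_g = 50, sodium_mg = 1500,
                     energy_kcal = 2000)
  sc <- score_dash(prof, cfg)
  expect_equal(sc$n_missing, 1L)
  expect_equal(sc$dash_total, 9)
})

test_that("supplement coding implements the three-valued OR", {
  flags <- data.frame(participant_id = 1:4,
                      multivitamins = c(FALSE, FALSE, NA, TRUE),
                      multiminerals = FALSE, calcium = FALSE,
                      magnesium = FALSE, vitamin_B = FALSE,
                      folate = c(FALSE, TRUE, FALSE, FALSE))
  out <- code_supplements(flags)
  expect_equal(out$any_supplement, c(FALSE, TRUE, NA, TRUE))
  # a supplied any_supplement column is honored (it may cover more preparations)
  flags$any_supplement <- c(TRUE, TRUE, FALSE, TRUE)
  expect_equal(code_supplements(flags)$any_supplement, c(TRUE, TRUE, FALSE, TRUE))
})

test_that("ISCED levels collapse into the declared three categories", {
  expect_equal(as.character(categorize_education(c(0, 1, 2, 3, 4, 5, 8, NA))),
               c("low", "low", "low", "medium", "medium", "high", "high", NA))
  expect_error(categorize_education(9), class = "gsm_bad_argument")
})
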