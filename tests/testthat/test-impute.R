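make_mcar_data <- function(n = 400, rate = 0.1, seed = 51) {
  set.seed(seed)
  x <- rnorm(n, 10, 2)
  y <- 2 + 0.8 * x + rnorm(n, 0, 1)
  b <- runif(n) < plogis(-1 + 0.2 * x)
  d <- data.frame(participant_id = seq_len(n), x = x, y = y, b = b)
  d_miss <- d
  set.seed(seed + 1)
  d_miss$y[runif(n) < rate] <- NA
  d_miss$b[runif(n) < rate] <- NA
  list(full = d, miss = d_miss)
}

test_that("a complete table yields m identical copies equal to the input", {
  d <- make_mcar_data()$full
  imp <- mice_impute(d, m = 3, iterations = 2, seed = 1)
  expect_equal(imp$m, 3L)
  for (k in 1:3) expect_equal(imp$imputations[[k]], d)
})

test_that("PMM imputations are observed donor values", {
  md <- make_mcar_data()
  imp <- mice_impute(md$miss, m = 2, iterations = 3, seed = 2)
  miss_idx <- which(is.na(md$miss$y))
  donors <- md$miss$y[!is.na(md$miss$y)]
  for (k in 1:2) {
    imputed <- imp$imputations[[k]]$y[miss_idx]
    expect_true(all(imputed %in% donors))
    expect_false(anyNA(imp$imputations[[k]]))
  }
})

test_that("imputation is reproducible under a seed", {
  md <- make_mcar_data()
  i1 <- mice_impute(md$miss, m = 2, iterations = 2, seed = 9)
  i2 <- mice_impute(md$miss, m = 2, iterations = 2, seed = 9)
  expect_equal(i1$imputations, i2$imputations)
})

test_that("MCAR imputation recovers the complete-data mean", {
  md <- make_mcar_data(n = 1000, rate = 0.1, seed = 53)
  imp <- mice_impute(md$miss, m = 10, iterations = 5, seed = 3)
  pooled_mean <- mean(vapply(imp$imputations, function(d) mean(d$y), numeric(1)))
  full_mean <- mean(md$full$y)
  mc_se <- sd(md$full$y) / sqrt(sum(is.na(md$miss$y)))
  expect_lt(abs(pooled_mean - full_mean), 2 * mc_se)
})

test_that("fully missing variables are refused by name", {
  d <- make_mcar_data()$miss
  d$z <- NA_real_
  expect_error(mice_impute(d, m = 2, iterations = 1), class = "gsm_all_missing")
  # and a rate-1 masking produces exactly that situation
  full <- make_mcar_data()$full
  masked <- inject_missingness(full, rates = list(y = 1.0), mechanism = "mcar")
  expect_true(all(is.na(masked$y)))
  expect_error(mice_impute(masked, m = 2, iterations = 1), class = "gsm_all_missing")
})

test_that("ordered factors are imputed to valid observed categories", {
  set.seed(55)
  n <- 300
  d <- data.frame(participant_id = seq_len(n),
                  x = rnorm(n),
                  cat = factor(sample(c("0-3", "4", "5", "6+"), n, TRUE),
                               levels = c("0-3", "4", "5", "6+"), ordered = TRUE))
  d$cat[sample(n, 30)] <- NA
  imp <- mice_impute(d, m = 2, iterations = 3, seed = 4)
  for (k in 1:2) {
    expect_false(anyNA(imp$imputations[[k]]$cat))
    expect_true(is.ordered(imp$imputations[[k]]$cat))
    expect_true(all(levels(imp$imputations[[k]]$cat) == levels(d$cat)))
  }
})
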