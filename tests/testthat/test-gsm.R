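test_that("plaque gray statistics match closed forms", {
  px <- matrix(77L, 16, 16)
  mask <- matrix(TRUE, 16, 16)
  r <- compute_gsm_stats(px, mask, frame_id = "f", observer_id = "o")
  expect_equal(c(r$gsm_min, r$gsm_max, r$gsm_mean, r$gsm_median),
               c(77, 77, 77, 77))
  expect_equal(r$n_pixels, 256)

  px2 <- matrix(0L, 16, 16)
  mask2 <- matrix(FALSE, 16, 16)
  px2[1, 1:4] <- c(10L, 20L, 30L, 40L)
  mask2[1, 1:4] <- TRUE
  r2 <- compute_gsm_stats(px2, mask2)
  expect_equal(c(r2$gsm_min, r2$gsm_max, r2$gsm_mean, r2$gsm_median),
               c(10, 40, 25, 25))
  expect_error(compute_gsm_stats(px2, matrix(FALSE, 16, 16)),
               class = "gsm_empty_region")
})

test_that("order statistics obey min <= median <= max and min <= mean <= max", {
  set.seed(21)
  for (rep in 1:5) {
    px <- matrix(sample(0:255, 256, replace = TRUE), 16, 16)
    mask <- matrix(runif(256) < 0.3, 16, 16)
    if (!any(mask)) mask[1, 1] <- TRUE
    r <- compute_gsm_stats(px, mask)
    expect_true(r$gsm_min <= r$gsm_median && r$gsm_median <= r$gsm_max)
    expect_true(r$gsm_min <= r$gsm_mean && r$gsm_mean <= r$gsm_max)
  }
})

test_that("measured plaque mean recovers the generator ground truth", {
  # noiseless: exact
  gi0 <- generate_image(image_spec(sigma = 0), seed = 1)
  r0 <- measure_frame(gi0$frame, gi0$annotation, denoise = FALSE)
  expect_equal(r0$gsm_mean, gi0$ground_truth$gsm_mean)
  # sigma = 8 raw gray units, >= 2000 plaque pixels: within 1 GSM unit
  gi8 <- generate_image(image_spec(sigma = 8), seed = 2)
  r8 <- measure_frame(gi8$frame, gi8$annotation)
  expect_gte(r8$n_pixels, 2000)
  expect_lt(abs(r8$gsm_mean - gi8$ground_truth$gsm_mean), 1.0)
})

test_that("participant GSM is the flat mean over plaque-by-observer measurements", {
  res <- data.frame(participant_id = c("a", "a"),
                    frame_id = c("f1", "f1"),
                    gsm_median = c(50, 60))
  agg <- aggregate_participants(res)
  expect_equal(agg$gsm, 55)
  expect_equal(agg$n_measurements, 2L)

  res2 <- data.frame(participant_id = "b", frame_id = paste0("f", 1:3),
                     gsm_median = c(40, 60, 80))
  expect_equal(aggregate_participants(res2)$gsm, 60)

  # 5 plaques x 2 observers, values 1..10
  res3 <- data.frame(participant_id = "c",
                     frame_id = rep(paste0("f", 1:5), each = 2),
                     gsm_median = 1:10)
  expect_equal(aggregate_participants(res3)$gsm, 5.5)
  expect_error(aggregate_participants(res3[0, ]), class = "gsm_no_measurements")
})

test_that("per-plaque-first aggregation averages observers within plaque", {
  res <- data.frame(participant_id = "a",
                    frame_id = c("f1", "f1", "f2"),
                    gsm_median = c(10, 30, 80))
  expect_equal(aggregate_participants(res, method = "flat")$gsm, 40)
  expect_equal(aggregate_participants(res, method = "per_plaque")$gsm, 50)
})
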