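test_that("normalization maps the reference anchors to 0 and 190", {
  fx <- tiny_annotated_frame(lumen_value = 40, adventitia_value = 160)
  norm <- normalize_brightness(fx$frame, fx$annotation)
  expect_equal(unname(norm$reference), c(40, 160))
  raw <- fx$frame$pixels
  expect_true(all(norm$pixels[raw == 40] == 0))
  expect_true(all(norm$pixels[raw == 160] == 190))
  expect_true(all(norm$pixels[raw == 100] == 95))  # midpoint of the linear map
})

test_that("values beyond the adventitia anchor are clipped at 255", {
  # raw 255 with L=40, A=160 maps to 190*215/120 = 340.4 before clipping
  expect_equal(normalize_gray(255, 40, 160), 255L)
  expect_equal(normalize_gray(c(40, 160, 100), 40, 160), c(0L, 190L, 95L))
})

test_that("non-discriminating references raise an error", {
  fx <- tiny_annotated_frame(lumen_value = 120, adventitia_value = 120)
  expect_error(normalize_brightness(fx$frame, fx$annotation),
               class = "gsm_bad_references")
})

test_that("normalization preserves pixel ordering where clipping is inactive", {
  set.seed(5)
  g <- sort(sample(0:200, 50))
  out <- normalize_gray(g, 40, 160)
  expect_true(all(diff(out) >= 0))
})

test_that("an already-anchored frame is unchanged outside clipping", {
  set.seed(6)
  g <- sample(0:255, 400, replace = TRUE)
  # with anchors L = 0, A = 190 the map is the identity on [0, 255]
  expect_equal(normalize_gray(g, 0, 190), g)
})

test_that("region medians of a generated image anchor exactly at 0 and 190", {
  gi <- generate_image(image_spec(sigma = 6), seed = 3)
  norm <- normalize_brightness(gi$frame, gi$annotation)
  dims <- dim(gi$frame$pixels)
  lmask <- rasterize_polygon(gi$annotation$lumen, dims)
  amask <- rasterize_polygon(gi$annotation$adventitia, dims)
  expect_equal(median(norm$pixels[lmask]), 0)
  expect_equal(median(norm$pixels[amask]), 190)
})

test_that("median filter removes isolated impulse noise and is an identity on flat images", {
  flat <- matrix(80L, 16, 16)
  expect_equal(denoise(flat), flat)
  salt <- matrix(50L, 16, 16)
  salt[8, 8] <- 255L
  out <- denoise(salt)
  expect_equal(out[8, 8], 50L)
  expect_true(all(out == 50L))
})

test_that("median filter equals the brute-force sorted-neighborhood median", {
  set.seed(11)
  px <- matrix(sample(0:255, 256, replace = TRUE), 16, 16)
  expect_equal(denoise(px), brute_median_filter(px))
  # output range is a subset of the input range
  out <- denoise(px)
  expect_gte(min(out), min(px))
  expect_lte(max(out), max(px))
})

test_that("cropping returns the minimal bounding box with a consistent offset", {
  px <- matrix(7L, 20, 20)
  mask <- matrix(FALSE, 20, 20)
  mask[4:8, 11:13] <- TRUE  # rows 3-7, cols 10-12 in 0-based coordinates
  res <- crop_to_roi(px, mask)
  expect_equal(dim(res$frame), c(5, 3))
  expect_equal(unname(res$offset), c(3L, 10L))
  expect_true(all(res$mask))
  # identity crop
  full <- matrix(TRUE, 20, 20)
  expect_equal(dim(crop_to_roi(px, full)$frame), c(20, 20))
  expect_error(crop_to_roi(px, matrix(FALSE, 20, 20)), class = "gsm_empty_region")
})

test_that("random-mask crops agree with an exhaustive index scan", {
  set.seed(12)
  for (rep in 1:3) {
    mask <- matrix(runif(400) < 0.1, 20, 20)
    if (!any(mask)) mask[5, 5] <- TRUE
    res <- crop_to_roi(matrix(0L, 20, 20), mask)
    idx <- which(mask, arr.ind = TRUE)
    expect_equal(unname(res$offset),
                 c(min(idx[, 1]) - 1L, min(idx[, 2]) - 1L))
    expect_equal(dim(res$frame),
                 c(diff(range(idx[, 1])) + 1L, diff(range(idx[, 2])) + 1L))
  }
})
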