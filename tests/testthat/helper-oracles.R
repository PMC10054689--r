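# Independent brute-force oracles, kept deliberately naive and separate from
# the package's implementations.

# Scalar even-odd point-in-polygon test (textbook crossing-number loop).
brute_point_in_polygon <- function(px, py, poly) {
  n <- nrow(poly)
  inside <- FALSE
  j <- n
  for (i in seq_len(n)) {
    xi <- poly[i, 1]; yi <- poly[i, 2]
    xj <- poly[j, 1]; yj <- poly[j, 2]
    if ((yi > py) != (yj > py)) {
      xint <- (xj - xi) * (py - yi) / (yj - yi) + xi
      if (px < xint) inside <- !inside
    }
    j <- i
  }
  inside
}

brute_rasterize <- function(poly, dims) {
  h <- dims[1]; w <- dims[2]
  mask <- matrix(FALSE, h, w)
  for (x in seq_len(w)) {
    for (y in seq_len(h)) {
      mask[y, x] <- brute_point_in_polygon(x - 0.5, y - 0.5, poly)
    }
  }
  mask
}

# Per-pixel sorted-neighborhood 3x3 median with edge-replicated borders
# (equivalent to the package's half-sample symmetric reflection for a
# 3x3 kernel).
brute_median_filter <- function(px) {
  h <- nrow(px); w <- ncol(px)
  out <- px
  for (i in seq_len(h)) {
    for (j in seq_len(w)) {
      ri <- pmin(pmax((i - 1):(i + 1), 1), h)
      ci <- pmin(pmax((j - 1):(j + 1), 1), w)
      out[i, j] <- sort(as.vector(px[ri, ci]))[5]
    }
  }
  out
}

# ICC(2,1) from stats::aov mean squares on long-format data.
aov_icc21 <- function(x, y) {
  n <- length(x)
  long <- data.frame(y = c(x, y),
                     target = factor(rep(seq_len(n), 2)),
                     rater = factor(rep(1:2, each = n)))
  tab <- summary(stats::aov(y ~ target + rater, data = long))[[1]]
  msr <- tab["target", "Mean Sq"]
  msc <- tab["rater", "Mean Sq"]
  mse <- tab["Residuals", "Mean Sq"]
  k <- 2
  (msr - mse) / (msr + (k - 1) * mse + k * (msc - mse) / n)
}
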