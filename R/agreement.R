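#' Reproducible reliability subsample
#'
#' Draws a simple random sample (without replacement) of `ceiling(fraction*n)`
#' participant ids for re-reading by all observers, reproducibly under a seed.
#'
#' @param ids vector of participant ids.
#' @param fraction fraction to draw, in (0, 1\]; default 0.05.
#' @param seed integer seed.
#' @return Vector of sampled ids.
#' @export
interobserver_subsample <- function(ids, fraction = 0.05, seed = 1L) {
  if (length(ids) == 0L) stop_gsm("no_measurements", "empty id list")
  if (!(fraction > 0 && fraction <= 1)) {
    stop_gsm("bad_argument", "fraction must be in (0, 1]")
  }
  size <- ceiling(fraction * length(ids))
  with_local_seed(seed, sample(ids, size))
}

# Run expr under a temporary RNG state; the caller's stream is untouched.
with_local_seed <- function(seed, expr) {
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_seed) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_seed) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

#' Interobserver agreement of paired GSM measurements
#'
#' Agreement between two observers' measurements of the same plaques:
#' two-way random-effects, absolute-agreement, single-measurement intraclass
#' correlation (ICC(2,1)), the mean paired difference with Bland-Altman 95%
#' limits of agreement, and flags for pairs whose absolute difference exceeds
#' `k` standard deviations of the paired differences (candidates for
#' remeasurement).
#'
#' @param x,y numeric vectors: the two observers' measurements, pairwise.
#' @param k outlier multiplier; default 3.
#' @return List with `n`, `icc`, `mean_diff`, `sd_diff`, `loa` (lower, upper),
#'   and `outliers` (indices of flagged pairs).
#' @export
interobserver_agreement <- function(x, y, k = 3) {
  if (length(x) != length(y)) stop_gsm("bad_argument", "x and y must be the same length")
  ok <- stats::complete.cases(x, y)
  x <- x[ok]; y <- y[ok]
  n <- length(x)
  if (n < 2L) stop_gsm("insufficient_data", "need at least 2 complete pairs")

  # ICC(2,1) from the two-way ANOVA mean squares (targets x raters).
  dat <- cbind(x, y)
  nr <- 2L
  row_means <- rowMeans(dat)
  col_means <- colMeans(dat)
  grand <- mean(dat)
  ss_rows <- nr * sum((row_means - grand)^2)
  ss_cols <- n * sum((col_means - grand)^2)
  ss_tot <- sum((dat - grand)^2)
  ss_err <- ss_tot - ss_rows - ss_cols
  msr <- ss_rows / (n - 1)
  msc <- ss_cols / (nr - 1)
  mse <- ss_err / ((n - 1) * (nr - 1))
  icc <- (msr - mse) / (msr + (nr - 1) * mse + nr * (msc - mse) / n)

  d <- x - y
  md <- mean(d)
  sdd <- stats::sd(d)
  loa <- md + c(-1, 1) * 1.96 * sdd
  outliers <- if (is.finite(sdd) && sdd > 0) which(abs(d) > k * sdd) else integer(0)
  list(n = n, icc = icc, mean_diff = md, sd_diff = sdd,
       loa = c(lower = loa[1], upper = loa[2]), outliers = outliers)
}
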