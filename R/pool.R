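#' Pool estimates across imputations with Rubin's rules
#'
#' For each model term, the pooled estimate is the mean of the per-imputation
#' estimates Q̄; the total variance combines the mean within-imputation
#' variance W̄ and the between-imputation variance B as
#' `T = W̄ + (1 + 1/m) B`. Degrees of freedom use the Barnard-Rubin
#' small-sample adjustment; 95% confidence intervals are
#' `Q̄ ± t(df, 0.975) * sqrt(T)` and p-values are two-sided Wald t tests.
#'
#' @param estimates m x p matrix (or list of named vectors) of per-imputation
#'   coefficient estimates.
#' @param variances matching m x p matrix/list of squared standard errors.
#' @param dfcom complete-data residual degrees of freedom (n - number of
#'   parameters), used by the Barnard-Rubin adjustment; `Inf` falls back to
#'   the classic large-sample df.
#' @return Data frame with one row per term: `term`, `estimate`, `se`,
#'   `W` (within), `B` (between), `T` (total variance), `df`, `conf_low`,
#'   `conf_high`, `p_value`, `m`.
#' @export
pool_rubin <- function(estimates, variances, dfcom = Inf) {
  estimates <- as_term_matrix(estimates)
  variances <- as_term_matrix(variances)
  if (!identical(dim(estimates), dim(variances)) ||
      !identical(colnames(estimates), colnames(variances))) {
    stop_gsm("mismatched_terms", "estimates and variances must share terms")
  }
  m <- nrow(estimates)
  if (m < 2L) stop_gsm("bad_argument", "Rubin pooling needs m >= 2 imputations")
  qbar <- colMeans(estimates)
  wbar <- colMeans(variances)
  B <- apply(estimates, 2, stats::var)
  Tt <- wbar + (1 + 1 / m) * B
  lambda <- pmax((1 + 1 / m) * B / Tt, 1e-12)  # fraction of missing information
  df_old <- (m - 1) / lambda^2
  if (is.finite(dfcom)) {
    df_obs <- (dfcom + 1) / (dfcom + 3) * dfcom * (1 - lambda)
    df <- df_old * df_obs / (df_old + df_obs)
  } else {
    df <- df_old
  }
  se <- sqrt(Tt)
  tcrit <- stats::qt(0.975, df)
  stat <- qbar / se
  data.frame(term = colnames(estimates),
             estimate = qbar,
             se = se,
             W = wbar,
             B = B,
             T = Tt,
             df = df,
             conf_low = qbar - tcrit * se,
             conf_high = qbar + tcrit * se,
             p_value = 2 * stats::pt(-abs(stat), df),
             m = m,
             row.names = NULL,
             stringsAsFactors = FALSE)
}

as_term_matrix <- function(x) {
  if (is.matrix(x)) return(x)
  terms <- names(x[[1]])
  if (is.null(terms)) stop_gsm("mismatched_terms", "estimates must be named")
  for (el in x) {
    if (!identical(names(el), terms)) {
      stop_gsm("mismatched_terms", "all fits must share the same terms")
    }
  }
  do.call(rbind, x)
}
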