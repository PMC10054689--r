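#' Table-1-style descriptive summary
#'
#' Continuous variables are summarized as median \[IQR\], categorical
#' variables as n (%) per level, each with the count of missing values, plus
#' a between-group comparison p-value: Wilcoxon rank-sum for continuous
#' variables and the chi-squared test for categorical ones. Percentages use
#' the full group size as denominator, with missingness reported separately.
#'
#' @param data data frame.
#' @param group grouping column (two groups), default `"sex"`.
#' @param vars variables to summarize; default: everything except the group
#'   and `participant_id`.
#' @return Data frame with columns `variable`, `level`, `overall`, one column
#'   per group, `n_missing`, `p_value` and `test`.
#' @export
descriptive_table <- function(data, group = "sex", vars = NULL) {
  if (nrow(data) == 0L) stop_gsm("bad_argument", "empty table")
  if (is.null(vars)) {
    vars <- setdiff(names(data), c(group, "participant_id"))
  }
  g <- factor(data[[group]])
  glev <- levels(g)
  rows <- list()
  fmt_cont <- function(x) {
    q <- stats::quantile(x, c(0.25, 0.5, 0.75), na.rm = TRUE, names = FALSE)
    sprintf("%.2f [%.2f, %.2f]", q[2], q[1], q[3])
  }
  fmt_cat <- function(x, denom) sprintf("%d (%.1f)", sum(x, na.rm = TRUE),
                                        100 * sum(x, na.rm = TRUE) / denom)
  for (v in vars) {
    x <- data[[v]]
    if (is.numeric(x)) {
      p <- tryCatch(suppressWarnings(stats::wilcox.test(x ~ g)$p.value),
                    error = function(e) NA_real_)
      row <- data.frame(variable = v, level = "median [IQR]",
                        overall = fmt_cont(x), stringsAsFactors = FALSE)
      for (lv in glev) row[[lv]] <- fmt_cont(x[g == lv])
      row$n_missing <- sum(is.na(x))
      row$p_value <- p
      row$test <- "wilcoxon"
      rows[[length(rows) + 1L]] <- row
    } else {
      xf <- if (is.logical(x)) factor(x, levels = c(FALSE, TRUE)) else factor(x)
      p <- tryCatch(suppressWarnings(stats::chisq.test(table(xf, g))$p.value),
                    error = function(e) NA_real_)
      show_levels <- if (is.logical(x)) "TRUE" else levels(xf)
      for (lv2 in show_levels) {
        ind <- xf == lv2
        row <- data.frame(variable = v, level = lv2,
                          overall = fmt_cat(ind, length(ind)),
                          stringsAsFactors = FALSE)
        for (lv in glev) row[[lv]] <- fmt_cat(ind[g == lv], sum(g == lv))
        row$n_missing <- sum(is.na(x))
        row$p_value <- p
        row$test <- "chi-squared"
        rows[[length(rows) + 1L]] <- row
      }
    }
  }
  do.call(rbind, rows)
}
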