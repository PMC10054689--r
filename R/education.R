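#' Collapse ISCED education levels into three categories
#'
#' International Standard Classification of Education levels 0-8 are mapped to
#' `low` (0-2), `medium` (3-4) and `high` (5-8). Missing levels propagate.
#'
#' @param isced_level integer vector of ISCED levels (0-8) or NA.
#' @return Factor with levels `low`, `medium`, `high`.
#' @export
categorize_education <- function(isced_level) {
  bad <- !is.na(isced_level) & !(isced_level %in% 0:8)
  if (any(bad)) {
    stop_gsm("bad_argument",
             sprintf("ISCED levels must be 0-8; offending values: %s",
                     paste(unique(isced_level[bad]), collapse = ", ")))
  }
  cat <- cut(isced_level, breaks = c(-Inf, 2, 4, Inf),
             labels = c("low", "medium", "high"))
  factor(cat, levels = c("low", "medium", "high"))
}
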