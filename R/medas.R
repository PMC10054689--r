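#' MEDAS (Mediterranean Diet Adherence Screener) scoring
#'
#' The screener has 14 binary items (twelve on food intake, two on food
#' habits); each item scores 1 for adherence and 0 otherwise, so the total
#' runs 0-14. Totals are grouped into the adherence categories
#' `0-3`, `4`, `5` and `6+`. Missing items contribute 0 to the total and are
#' counted in `n_missing` so downstream imputation can treat incomplete
#' screeners explicitly.
#'
#' @param responses data frame or matrix of exactly 14 columns, values in
#'   \{0, 1, NA\}; one row per participant.
#' @param participant_id optional id vector (defaults to row order).
#' @return Data frame with `participant_id`, `medas_total`, `medas_category`
#'   (factor `0-3` < `4` < `5` < `6+`) and `n_missing`.
#' @export
score_medas <- function(responses, participant_id = NULL) {
  m <- as.matrix(responses)
  if (ncol(m) != 14L) stop_gsm("bad_argument", "MEDAS needs exactly 14 items")
  vals <- m[!is.na(m)]
  if (length(vals) && !all(vals %in% c(0, 1))) {
    stop_gsm("bad_argument", "MEDAS items must be 0, 1 or NA")
  }
  if (is.null(participant_id)) participant_id <- seq_len(nrow(m))
  total <- rowSums(m, na.rm = TRUE)
  data.frame(participant_id = participant_id,
             medas_total = as.integer(total),
             medas_category = medas_category(total),
             n_missing = as.integer(rowSums(is.na(m))),
             stringsAsFactors = FALSE)
}

#' @rdname score_medas
#' @param total integer MEDAS totals in \[0, 14\].
#' @export
medas_category <- function(total) {
  cut(total, breaks = c(-Inf, 3, 4, 5, Inf),
      labels = c("0-3", "4", "5", "6+"),
      ordered_result = TRUE)
}

medas_levels <- c("0-3", "4", "5", "6+")
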