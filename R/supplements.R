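#' Code supplement-use flags
#'
#' Tracks use (at least one month in the last twelve) of multivitamin and
#' multimineral preparations, calcium, magnesium, vitamin-B complex and folic
#' acid. `any_supplement` may be supplied directly (questionnaires typically
#' ask about more preparations than the tracked six); when absent it is
#' derived as the three-valued OR of the tracked flags: `TRUE` if any flag is
#' `TRUE`, `FALSE` if all are `FALSE`, `NA` otherwise. Missing flags propagate
#' as `NA` for downstream imputation rather than being silently zeroed.
#'
#' @param flags data frame with `participant_id` and logical columns
#'   `multivitamins`, `multiminerals`, `calcium`, `magnesium`, `vitamin_B`,
#'   `folate`, optionally `any_supplement`.
#' @param any_from character vector of flag names feeding the derived
#'   `any_supplement` (configurable because "any intake" may cover more
#'   preparations than those analyzed).
#' @return Data frame with `participant_id`, the tracked flags and
#'   `any_supplement`.
#' @export
code_supplements <- function(flags,
                             any_from = c("multivitamins", "multiminerals", "calcium",
                                          "magnesium", "vitamin_B", "folate")) {
  tracked <- c("multivitamins", "multiminerals", "calcium", "magnesium",
               "vitamin_B", "folate")
  missing_cols <- setdiff(tracked, names(flags))
  if (length(missing_cols)) {
    stop_gsm("bad_argument", paste("missing supplement columns:",
                                   paste(missing_cols, collapse = ", ")))
  }
  out <- flags[, c("participant_id", tracked)]
  if ("any_supplement" %in% names(flags)) {
    out$any_supplement <- as.logical(flags$any_supplement)
  } else {
    m <- as.matrix(flags[, any_from, drop = FALSE])
    any_true <- apply(m, 1, function(r) any(r %in% TRUE))
    all_false <- apply(m, 1, function(r) all(r %in% FALSE))
    out$any_supplement <- ifelse(any_true, TRUE, ifelse(all_false, FALSE, NA))
  }
  out
}
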