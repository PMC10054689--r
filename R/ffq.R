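#' Aggregate FFQ intakes into a nutrient / food-group profile
#'
#' A food-frequency questionnaire records, for each item, the consumption
#' frequency (times/day) and portion size (grams). Combined with a per-gram
#' composition table this yields daily energy, nutrient and food-group-serving
#' intakes. Every output is linear in the intakes:
#' `output = sum over items of frequency * portion * per-gram coefficient`.
#'
#' @param ffq long-format data frame with columns `participant_id`, `item`,
#'   `freq_per_day`, `portion_g`. Missing items simply contribute nothing.
#' @param composition data frame with column `item` plus one column per
#'   per-gram coefficient (e.g. `energy_kcal`, `saturated_fat_g`, `fat_g`,
#'   `sodium_mg`, `serv_grains`, `serv_vegetables`, ...). Coefficients are
#'   per gram of the item.
#' @return Wide data frame: one row per participant, one column per
#'   composition coefficient (same names), values in per-day units.
#' @export
ffq_to_profile <- function(ffq, composition) {
  need <- c("participant_id", "item", "freq_per_day", "portion_g")
  if (!all(need %in% names(ffq))) {
    stop_gsm("bad_argument", paste("ffq must have columns:", paste(need, collapse = ", ")))
  }
  unknown <- setdiff(unique(ffq$item), composition$item)
  if (length(unknown) > 0L) {
    stop_gsm("unknown_item",
             paste("items missing from the composition table:",
                   paste(sort(unknown), collapse = ", ")))
  }
  if (any(ffq$freq_per_day < 0, na.rm = TRUE) || any(ffq$portion_g < 0, na.rm = TRUE)) {
    stop_gsm("bad_argument", "frequencies and portions must be non-negative")
  }
  coef_cols <- setdiff(names(composition), "item")
  idx <- match(ffq$item, composition$item)
  grams <- ffq$freq_per_day * ffq$portion_g
  grams[is.na(grams)] <- 0  # missing items contribute zero intake
  ids <- sort(unique(ffq$participant_id))
  out <- data.frame(participant_id = ids, stringsAsFactors = FALSE)
  fid <- match(ffq$participant_id, ids)
  for (cc in coef_cols) {
    contrib <- grams * composition[[cc]][idx]
    s <- rep(0, length(ids))
    agg <- tapply(contrib, fid, sum)
    s[as.integer(names(agg))] <- as.numeric(agg)
    out[[cc]] <- s
  }
  out
}
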