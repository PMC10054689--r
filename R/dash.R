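#' DASH adherence scoring (Folsom-style 10-component score)
#'
#' Ten components: seven food groups (grains, vegetables, fruits, dairy,
#' meat/poultry/fish, nuts/seeds/legumes, sweets) plus three nutrients
#' (saturated fat, total fat, sodium). Each component scores 1 when the DASH
#' target is met, 0.5 when the intermediate threshold is met, else 0, so the
#' total runs 0-10 in steps of 0.5. Totals are grouped into the categories
#' `0-3.5`, `3.6-4.5`, `4.6-5.0` and `5.1+`.
#'
#' Component thresholds ship as an editable configuration
#' (`system.file("extdata", "dash_components.yaml", package = "carotidgsm")`);
#' defaults follow the DASH trial targets as adapted by Folsom-style scoring
#' and should be reviewed against the instrument in use. Nutrient components
#' may be expressed per day (`mg_per_day`, `g_per_day`), as percent of energy
#' (`percent_energy_fat`, 9 kcal/g) or as servings per day.
#'
#' @param profile data frame with one row per participant: `participant_id`,
#'   food-group servings/day (`serv_grains`, `serv_vegetables`, `serv_fruits`,
#'   `serv_dairy`, `serv_meat`, `serv_nuts_seeds_legumes`, `serv_sweets`),
#'   nutrient intakes (`saturated_fat_g`, `fat_g`, `sodium_mg`) and
#'   `energy_kcal`.
#' @param config component list as read from the YAML; `NULL` uses the
#'   shipped defaults.
#' @return Data frame with `participant_id`, the ten per-component scores
#'   (`dash_<component>`), `dash_total`, `dash_category` and `n_missing`
#'   (missing components score 0, conservatively, and are counted).
#' @export
score_dash <- function(profile, config = NULL) {
  if (is.null(config)) config <- dash_default_config()
  comps <- config$components
  n <- nrow(profile)
  out <- data.frame(participant_id = profile$participant_id, stringsAsFactors = FALSE)
  n_missing <- integer(n)
  total <- numeric(n)
  for (comp in comps) {
    value <- profile[[comp$variable]]
    if (is.null(value)) {
      stop_gsm("bad_argument", sprintf("profile lacks column '%s'", comp$variable))
    }
    if (identical(comp$unit, "percent_energy_fat")) {
      value <- 100 * value * 9 / profile$energy_kcal
    }
    s <- component_score(value, comp$direction, comp$target, comp$intermediate)
    miss <- is.na(s)
    n_missing <- n_missing + miss
    s[miss] <- 0
    out[[paste0("dash_", comp$name)]] <- s
    total <- total + s
  }
  out$dash_total <- total
  out$dash_category <- dash_category(total)
  out$n_missing <- n_missing
  out
}

component_score <- function(value, direction, target, intermediate) {
  if (direction == "ge") {
    ifelse(value >= target, 1, ifelse(value >= intermediate, 0.5, 0))
  } else {
    ifelse(value <= target, 1, ifelse(value <= intermediate, 0.5, 0))
  }
}

#' @rdname score_dash
#' @param total DASH totals (multiples of 0.5 in \[0, 10\]).
#' @export
dash_category <- function(total) {
  cut(total, breaks = c(-Inf, 3.5, 4.5, 5.0, Inf),
      labels = c("0-3.5", "3.6-4.5", "4.6-5.0", "5.1+"),
      ordered_result = TRUE)
}

dash_levels <- c("0-3.5", "3.6-4.5", "4.6-5.0", "5.1+")

#' @rdname score_dash
#' @export
dash_default_config <- function() {
  path <- system.file("extdata", "dash_components.yaml", package = "carotidgsm")
  yaml::read_yaml(path)
}
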