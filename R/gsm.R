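#' Gray-scale statistics of a plaque region
#'
#' Minimum, maximum, mean and median of the normalized gray values under the
#' plaque mask. The median of an even pixel count is the mean of the two
#' central order statistics.
#'
#' @param frame normalized [ultrasound_frame()] or gray matrix.
#' @param mask logical plaque mask.
#' @param frame_id,observer_id identifiers copied into the result.
#' @return One-row data frame with columns `frame_id`, `observer_id`,
#'   `n_pixels`, `gsm_min`, `gsm_max`, `gsm_mean`, `gsm_median`.
#' @export
compute_gsm_stats <- function(frame, mask, frame_id = NULL, observer_id = NA_character_) {
  px <- frame_pixels(frame)
  if (!any(mask)) stop_gsm("empty_region", "plaque mask is empty")
  if (is.null(frame_id)) {
    frame_id <- if (inherits(frame, "ultrasound_frame")) frame$frame_id else "frame"
  }
  v <- as.numeric(px[mask])
  data.frame(frame_id = frame_id,
             observer_id = observer_id,
             n_pixels = length(v),
             gsm_min = min(v),
             gsm_max = max(v),
             gsm_mean = mean(v),
             gsm_median = stats::median(v),
             stringsAsFactors = FALSE)
}

#' Measure one annotated frame end-to-end
#'
#' Pipeline for a single frame/observer pair: optional median-filter noise
#' reduction of the raw frame, anchored brightness normalization against the
#' annotated lumen/adventitia references, cropping to the plaque bounding box,
#' then plaque gray-scale statistics. Denoising precedes normalization; the
#' reference medians are robust to the order either way.
#'
#' @param frame raw [ultrasound_frame()].
#' @param annotation matching [annotation_set()].
#' @param denoise apply the 3x3 median filter first? Default `TRUE`.
#' @return One-row data frame as in [compute_gsm_stats()].
#' @export
measure_frame <- function(frame, annotation, denoise = TRUE) {
  px <- frame_pixels(frame)
  plaque_mask <- rasterize_polygon(annotation$plaque, dim(px))
  lumen_mask <- rasterize_polygon(annotation$lumen, dim(px))
  if (any(plaque_mask & lumen_mask)) {
    stop_gsm("bad_annotation", "plaque polygon overlaps the lumen reference region")
  }
  work <- if (denoise) denoise(frame) else frame
  norm <- normalize_brightness(work, annotation,
                               lumen_mask = lumen_mask)
  roi <- crop_to_roi(norm, plaque_mask)
  compute_gsm_stats(roi$frame, roi$mask,
                    frame_id = annotation$frame_id,
                    observer_id = annotation$observer_id)
}

#' Aggregate plaque measurements to a participant-level GSM
#'
#' The participant outcome is the flat arithmetic mean of the chosen per-plaque
#' statistic over all plaque-by-observer measurements: both observers'
#' segmentations of the same plaque contribute as separate measurements. A
#' `per_plaque` mode averages observers within each plaque first.
#'
#' @param results data frame of measurements with columns `participant_id`,
#'   `frame_id` and the statistic column.
#' @param value which statistic defines GSM; default `"gsm_median"`.
#' @param method `"flat"` (default) or `"per_plaque"`.
#' @return Data frame with `participant_id`, `gsm`, `n_measurements`.
#' @export
aggregate_participants <- function(results, value = "gsm_median",
                                   method = c("flat", "per_plaque")) {
  method <- match.arg(method)
  if (nrow(results) == 0L) stop_gsm("no_measurements", "no measurements to aggregate")
  if (!value %in% names(results)) {
    stop_gsm("no_measurements", sprintf("column '%s' not found in results", value))
  }
  v <- results[[value]]
  if (method == "per_plaque") {
    per <- stats::aggregate(v, by = list(participant_id = results$participant_id,
                                         frame_id = results$frame_id), FUN = mean)
    out <- stats::aggregate(per$x, by = list(participant_id = per$participant_id),
                            FUN = mean)
  } else {
    out <- stats::aggregate(v, by = list(participant_id = results$participant_id),
                            FUN = mean)
  }
  n <- stats::aggregate(seq_len(nrow(results)),
                        by = list(participant_id = results$participant_id),
                        FUN = length)
  data.frame(participant_id = out$participant_id,
             gsm = out$x,
             n_measurements = n$x[match(out$participant_id, n$participant_id)],
             stringsAsFactors = FALSE)
}
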