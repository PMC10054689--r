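#' Anchored two-point brightness normalization
#'
#' Rescales frame brightness so that the vessel lumen reference maps to gray
#' value 0 (total black) and the adventitia reference to 190, the standard
#' anchors used in gray-scale-median plaque analysis. The reference levels are
#' the medians of the raw gray values inside the lumen and adventitia regions
#' (medians are robust to small annotation slips). The map is linear,
#'
#'   g' = 190 * (g - L) / (A - L),
#'
#' rounded half-up to the nearest integer and clipped to \[0, 255\].
#'
#' @param frame an [ultrasound_frame()] or gray matrix.
#' @param annotation an [annotation_set()] providing `lumen` and `adventitia`
#'   polygons, or `NULL` when masks are supplied directly.
#' @param lumen_mask,adventitia_mask optional logical masks overriding the
#'   annotation polygons.
#' @return An `ultrasound_frame` of normalized pixels, with the reference
#'   levels attached as element `reference = c(lumen = L, adventitia = A)`.
#' @export
normalize_brightness <- function(frame, annotation = NULL,
                                 lumen_mask = NULL, adventitia_mask = NULL) {
  px <- frame_pixels(frame)
  if (is.null(lumen_mask)) {
    lumen_mask <- rasterize_polygon(annotation$lumen, dim(px))
  }
  if (is.null(adventitia_mask)) {
    adventitia_mask <- rasterize_polygon(annotation$adventitia, dim(px))
  }
  if (!any(lumen_mask) || !any(adventitia_mask)) {
    stop_gsm("empty_region", "reference masks must be non-empty")
  }
  L <- stats::median(px[lumen_mask])
  A <- stats::median(px[adventitia_mask])
  if (A <= L) {
    stop_gsm("bad_references",
             sprintf("adventitia reference (%.1f) must be brighter than lumen reference (%.1f)", A, L))
  }
  out <- normalize_gray(px, L, A)
  res <- structure(list(frame_id = if (inherits(frame, "ultrasound_frame")) frame$frame_id else "frame",
                        pixels = out,
                        reference = c(lumen = L, adventitia = A)),
                   class = "ultrasound_frame")
  res
}

# The bare linear map: round half-up, clip to [0, 255].
normalize_gray <- function(g, L, A) {
  out <- floor(190 * (g - L) / (A - L) + 0.5)
  out[out < 0] <- 0L
  out[out > 255] <- 255L
  storage.mode(out) <- "integer"
  out
}

#' Median-filter noise reduction
#'
#' Single-pass 3x3 median filter with half-sample symmetric (reflected)
#' borders: the pad row/column repeats the edge row/column. The output pixel
#' range is always a subset of the input range.
#'
#' @param frame an [ultrasound_frame()] or gray matrix.
#' @return Object of the same kind as the input, denoised.
#' @export
denoise <- function(frame) {
  px <- frame_pixels(frame)
  h <- nrow(px); w <- ncol(px)
  ri <- c(1L, seq_len(h), h)
  ci <- c(1L, seq_len(w), w)
  pad <- px[ri, ci]
  neigh <- matrix(0L, nrow = h * w, ncol = 9L)
  k <- 0L
  for (dy in 0:2) {
    for (dx in 0:2) {
      k <- k + 1L
      neigh[, k] <- as.vector(pad[dy + seq_len(h), dx + seq_len(w)])
    }
  }
  med <- median9(neigh)
  out <- matrix(as.integer(med), nrow = h, ncol = w)
  if (inherits(frame, "ultrasound_frame")) {
    structure(list(frame_id = frame$frame_id, pixels = out), class = "ultrasound_frame")
  } else {
    out
  }
}

# Row-wise median of a 9-column matrix via a selection network built from
# column sorts; avoids an R-level loop over pixels.
median9 <- function(m) {
  # Sort each row by repeatedly extracting the column-wise running minimum:
  # after 5 extractions the 5th minimum is the median of 9.
  work <- m
  med <- NULL
  for (r in 1:5) {
    idx <- max.col(-work, ties.method = "first")
    sel <- cbind(seq_len(nrow(work)), idx)
    med <- work[sel]
    work[sel] <- .Machine$integer.max
  }
  med
}

#' Crop a frame to the bounding box of a mask
#'
#' @param frame an [ultrasound_frame()] or gray matrix.
#' @param mask logical matrix of the same dimensions.
#' @return A list with `frame` (cropped), `mask` (cropped mask) and `offset`,
#'   the 0-based (row, col) coordinate of the crop origin in the source frame.
#' @export
crop_to_roi <- function(frame, mask) {
  px <- frame_pixels(frame)
  if (!any(mask)) stop_gsm("empty_region", "cannot crop to an empty mask")
  rows <- range(row(mask)[mask])
  cols <- range(col(mask)[mask])
  cropped <- px[rows[1]:rows[2], cols[1]:cols[2], drop = FALSE]
  out <- if (inherits(frame, "ultrasound_frame")) {
    structure(list(frame_id = frame$frame_id, pixels = cropped), class = "ultrasound_frame")
  } else {
    cropped
  }
  list(frame = out,
       mask = mask[rows[1]:rows[2], cols[1]:cols[2], drop = FALSE],
       offset = c(row = rows[1] - 1L, col = cols[1] - 1L))
}
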