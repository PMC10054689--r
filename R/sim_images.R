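#' Specification for a synthetic ultrasound-like frame
#'
#' Emulates the geometry relevant to plaque echogenicity measurement: a dark
#' vessel-lumen band, a bright adventitia band below it, and an elliptical
#' plaque of known mean gray sitting in the lumen against the far wall.
#' `target_gsm` is the desired plaque mean on the post-normalization scale
#' (lumen anchored at 0, adventitia at 190); the generator converts it to a
#' raw gray level given the band means. Additive Gaussian noise of standard
#' deviation `sigma` (raw gray units) is applied before 8-bit quantization
#' and clipping.
#'
#' @param width,height frame size in pixels.
#' @param background,lumen_value,adventitia_value raw band means.
#' @param target_gsm plaque mean on the normalized scale.
#' @param sigma Gaussian noise SD in raw gray units.
#' @return List of class `image_spec`.
#' @export
image_spec <- function(width = 192L, height = 160L,
                       background = 90, lumen_value = 25,
                       adventitia_value = 170, target_gsm = 56.5,
                       sigma = 6) {
  if (sigma < 0) stop_gsm("bad_spec", "sigma must be non-negative")
  if (!(lumen_value < adventitia_value)) {
    stop_gsm("bad_spec", "adventitia must be brighter than lumen")
  }
  raw_plaque <- round(lumen_value + target_gsm * (adventitia_value - lumen_value) / 190)
  if (!(raw_plaque > lumen_value && raw_plaque < adventitia_value)) {
    stop_gsm("bad_spec", "plaque mean must lie between lumen and adventitia means")
  }
  structure(list(width = as.integer(width), height = as.integer(height),
                 background = background, lumen_value = lumen_value,
                 adventitia_value = adventitia_value, target_gsm = target_gsm,
                 raw_plaque = raw_plaque, sigma = sigma,
                 lumen_band = c(40L, 99L), adventitia_band = c(100L, 119L),
                 plaque_center = c(x = 100, y = 80),
                 plaque_axes = c(a = 46, b = 14),
                 lumen_ref = c(x0 = 6, y0 = 44, x1 = 40, y1 = 60),
                 adventitia_ref = c(x0 = 10, y0 = 102, x1 = 180, y1 = 118)),
            class = "image_spec")
}

rect_polygon <- function(r) {
  cbind(x = c(r["x0"], r["x1"], r["x1"], r["x0"]),
        y = c(r["y0"], r["y0"], r["y1"], r["y1"]))
}

ellipse_polygon <- function(center, axes, n = 48L) {
  th <- seq(0, 2 * pi, length.out = n + 1L)[-(n + 1L)]
  cbind(x = center["x"] + axes["a"] * cos(th),
        y = center["y"] + axes["b"] * sin(th))
}

#' Generate a synthetic annotated frame with known plaque echogenicity
#'
#' Paints the bands and plaque of an [image_spec()], adds Gaussian noise,
#' quantizes to 8 bits, and returns the frame together with a consistent
#' annotation (plaque outline and lumen/adventitia reference rectangles) and
#' a ground-truth record. `ground_truth$gsm_mean` is the exact
#' post-normalization plaque mean implied by the painted (integer) raw plaque
#' value and the band anchors; at `sigma = 0` the measured plaque mean equals
#' it exactly.
#'
#' @param spec an [image_spec()].
#' @param seed integer seed; same seed gives a bit-identical frame.
#' @param frame_id,observer_id identifiers for the outputs.
#' @return List with `frame` ([ultrasound_frame()]), `annotation`
#'   ([annotation_set()]) and `ground_truth`.
#' @export
generate_image <- function(spec = image_spec(), seed = 1L,
                           frame_id = "synthetic", observer_id = "sim") {
  h <- spec$height; w <- spec$width
  base <- matrix(spec$background, nrow = h, ncol = w)
  lb <- spec$lumen_band; ab <- spec$adventitia_band
  base[(lb[1] + 1):(lb[2] + 1), ] <- spec$lumen_value
  base[(ab[1] + 1):(ab[2] + 1), ] <- spec$adventitia_value

  plaque_poly <- ellipse_polygon(spec$plaque_center, spec$plaque_axes)
  lumen_poly <- rect_polygon(spec$lumen_ref)
  adv_poly <- rect_polygon(spec$adventitia_ref)
  plaque_mask <- rasterize_polygon(plaque_poly, c(h, w))
  lumen_mask <- rasterize_polygon(lumen_poly, c(h, w))
  if (any(plaque_mask & lumen_mask)) {
    stop_gsm("bad_spec", "plaque region overlaps the lumen reference region")
  }
  base[plaque_mask] <- spec$raw_plaque

  if (!is.null(seed)) set.seed(seed)
  noisy <- base + if (spec$sigma > 0) stats::rnorm(h * w, 0, spec$sigma) else 0
  px <- round(noisy)
  px[px < 0] <- 0; px[px > 255] <- 255

  frame <- ultrasound_frame(px, frame_id = frame_id)
  annotation <- annotation_set(frame_id, observer_id,
                               plaque = plaque_poly, lumen = lumen_poly,
                               adventitia = adv_poly, frame_dims = c(h, w))
  gt_mean <- floor(190 * (spec$raw_plaque - spec$lumen_value) /
                     (spec$adventitia_value - spec$lumen_value) + 0.5)
  list(frame = frame,
       annotation = annotation,
       ground_truth = list(gsm_mean = gt_mean,
                           raw_plaque = spec$raw_plaque,
                           lumen_value = spec$lumen_value,
                           adventitia_value = spec$adventitia_value,
                           n_plaque_pixels = sum(plaque_mask),
                           sigma = spec$sigma))
}
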