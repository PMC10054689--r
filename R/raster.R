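#' Rasterize a polygon to a pixel mask
#'
#' Converts a polygon outline into the set of pixels whose centers fall inside
#' it, using the even-odd (ray-crossing parity) rule. Pixel (x, y) is 0-based
#' with its center at (x + 0.5, y + 0.5); the mask is a logical matrix with
#' the same row/column layout as the frame.
#'
#' @param polygon two-column (x, y) matrix of vertices, at least 3 rows.
#'   Vertices may be fractional.
#' @param dims frame dimensions `c(height, width)` (i.e. `dim(pixels)`).
#' @return Logical height x width matrix, `TRUE` for interior pixels.
#' @export
rasterize_polygon <- function(polygon, dims) {
  polygon <- as.matrix(polygon)
  if (nrow(polygon) < 3L) {
    stop_gsm("degenerate_polygon", "a polygon needs at least 3 vertices")
  }
  h <- as.integer(dims[1]); w <- as.integer(dims[2])
  cx <- rep(seq_len(w) - 0.5, each = h)
  cy <- rep(seq_len(h) - 0.5, times = w)
  mask <- matrix(point_in_polygon(cx, cy, polygon), nrow = h, ncol = w)
  if (!any(mask)) {
    stop_gsm("empty_region", "polygon contains no pixel centers")
  }
  mask
}

#' Even-odd point-in-polygon test
#'
#' Vectorized crossing-parity test: a point is inside when a leftward
#' horizontal ray crosses the polygon boundary an odd number of times.
#'
#' @param px,py point coordinates.
#' @param polygon two-column (x, y) vertex matrix.
#' @return Logical vector, one element per point.
#' @export
point_in_polygon <- function(px, py, polygon) {
  polygon <- as.matrix(polygon)
  n <- nrow(polygon)
  inside <- logical(length(px))
  j <- n
  for (i in seq_len(n)) {
    xi <- polygon[i, 1]; yi <- polygon[i, 2]
    xj <- polygon[j, 1]; yj <- polygon[j, 2]
    if (yi != yj) {
      crosses <- ((yi > py) != (yj > py)) &
        (px < (xj - xi) * (py - yi) / (yj - yi) + xi)
      inside <- xor(inside, crosses)
    }
    j <- i
  }
  inside
}
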