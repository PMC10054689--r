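#' Annotation sets
#'
#' An annotation set carries one observer's manual segmentation of a frame:
#' the plaque outline plus the two reference regions used to anchor brightness
#' normalization (a marker inside the vessel lumen and one in the adventitia).
#' Polygons are matrices with columns `x`, `y` in 0-based pixel coordinates.
#'
#' @param frame_id frame identifier the annotation belongs to.
#' @param observer_id identifier of the annotating observer.
#' @param plaque,lumen,adventitia polygons: two-column (x, y) matrices with at
#'   least 3 vertices each.
#' @param frame_dims optional `c(height, width)`; when given, vertices are
#'   checked to lie inside the frame bounds.
#' @return An object of class `annotation_set`.
#' @export
annotation_set <- function(frame_id, observer_id, plaque, lumen, adventitia,
                           frame_dims = NULL) {
  polys <- list(plaque = plaque, lumen = lumen, adventitia = adventitia)
  polys <- lapply(polys, function(p) {
    p <- as.matrix(p)
    colnames(p) <- c("x", "y")
    p
  })
  for (nm in names(polys)) {
    p <- polys[[nm]]
    if (nrow(p) < 3L) {
      stop_gsm("degenerate_polygon", sprintf("polygon '%s' has fewer than 3 vertices", nm))
    }
    if (!is.null(frame_dims)) {
      if (min(p) < 0 || max(p[, "x"]) > frame_dims[2] || max(p[, "y"]) > frame_dims[1]) {
        stop_gsm("bad_annotation", sprintf("polygon '%s' lies outside the frame bounds", nm))
      }
    }
  }
  structure(c(list(frame_id = frame_id, observer_id = observer_id), polys),
            class = "annotation_set")
}

#' Read and write annotation files
#'
#' One JSON file per frame and observer, holding the three named polygons as
#' vertex lists plus the observer id.
#'
#' @param path path to a JSON annotation file.
#' @return `read_annotation()` returns an [annotation_set()].
#' @export
read_annotation <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  annotation_set(frame_id = obj$frame_id, observer_id = obj$observer_id,
                 plaque = obj$plaque, lumen = obj$lumen,
                 adventitia = obj$adventitia)
}

#' @rdname read_annotation
#' @param annotation an [annotation_set()].
#' @export
write_annotation <- function(annotation, path) {
  obj <- list(frame_id = annotation$frame_id,
              observer_id = annotation$observer_id,
              plaque = unname(annotation$plaque),
              lumen = unname(annotation$lumen),
              adventitia = unname(annotation$adventitia))
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
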