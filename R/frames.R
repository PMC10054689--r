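#' Ultrasound frame objects
#'
#' An `ultrasound_frame` is an 8-bit grayscale raster: an integer matrix of
#' gray values in \[0, 255\] with rows as image rows (top row first) and
#' columns as image columns. Pixel coordinates are 0-based with the origin at
#' the top-left corner; pixel (x, y) occupies matrix cell `[y + 1, x + 1]` and
#' its center lies at (x + 0.5, y + 0.5).
#'
#' @param pixels integer matrix of gray values in \[0, 255\].
#' @param frame_id identifier for the frame.
#' @return An object of class `ultrasound_frame`: a list with elements
#'   `frame_id` and `pixels`.
#' @export
ultrasound_frame <- function(pixels, frame_id = "frame") {
  pixels <- as.matrix(pixels)
  storage.mode(pixels) <- "integer"
  if (nrow(pixels) < 16L || ncol(pixels) < 16L) {
    stop_gsm("bad_frame", "frame must be at least 16x16 pixels")
  }
  if (anyNA(pixels) || min(pixels) < 0L || max(pixels) > 255L) {
    stop_gsm("bad_frame", "pixel values must be integers in [0, 255]")
  }
  structure(list(frame_id = frame_id, pixels = pixels), class = "ultrasound_frame")
}

#' @export
print.ultrasound_frame <- function(x, ...) {
  cat(sprintf("<ultrasound_frame '%s': %d x %d px, gray range [%d, %d]>\n",
              x$frame_id, ncol(x$pixels), nrow(x$pixels),
              min(x$pixels), max(x$pixels)))
  invisible(x)
}

# Accept either a frame object or a bare matrix in image operations.
frame_pixels <- function(x) {
  if (inherits(x, "ultrasound_frame")) x$pixels else as.matrix(x)
}

#' Read and write 8-bit grayscale PNG frames
#'
#' Frames are exchanged as 8-bit grayscale PNG files. Color PNGs are collapsed
#' to grayscale by averaging the color channels.
#'
#' @param path path to a PNG file.
#' @param frame_id identifier; defaults to the file name without extension.
#' @return `read_frame()` returns an [ultrasound_frame()].
#' @export
read_frame <- function(path, frame_id = sub("\\.png$", "", basename(path))) {
  arr <- png::readPNG(path)
  if (length(dim(arr)) == 3L) {
    nchan <- min(dim(arr)[3], 3L)  # drop alpha
    arr <- apply(arr[, , seq_len(nchan), drop = FALSE], c(1, 2), mean)
  }
  ultrasound_frame(round(arr * 255), frame_id = frame_id)
}

#' @rdname read_frame
#' @param frame an [ultrasound_frame()].
#' @export
write_frame <- function(frame, path) {
  px <- frame_pixels(frame)
  png::writePNG(px / 255, target = path)
  invisible(path)
}
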