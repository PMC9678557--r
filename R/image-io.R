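# Raster I/O. PNG is the primary (lossless) format; TIFF is read when the
# tiff package is available. Pixels are stored as 0-255 integers in an
# H x W x 3 array.

#' Load a tongue image from disk
#'
#' Reads a PNG (or TIFF) file into a [tongue_image]: 8-bit RGB, grayscale
#' inputs promoted by channel replication, alpha discarded.
#'
#' @param path image file path.
#' @return A [tongue_image].
#' @export
load_image <- function(path) {
  if (!file.exists(path)) stop(sprintf("cannot read image: no such file '%s'", path), call. = FALSE)
  ext <- tolower(tools::file_ext(path))
  raw <- tryCatch({
    if (ext %in% c("tif", "tiff")) {
      if (!requireNamespace("tiff", quietly = TRUE)) {
        stop("the tiff package is required to read TIFF files")
      }
      tiff::readTIFF(path)
    } else {
      png::readPNG(path)
    }
  }, error = function(e) {
    stop(sprintf("cannot decode image '%s': %s", path, conditionMessage(e)), call. = FALSE)
  })
  if (length(dim(raw)) == 2L) raw <- array(rep(raw, 3), dim = c(dim(raw), 3))
  if (dim(raw)[3] > 3L) raw <- raw[, , 1:3, drop = FALSE]
  if (dim(raw)[3] == 2L) {  # gray + alpha
    raw <- array(rep(raw[, , 1], 3), dim = c(dim(raw)[1:2], 3))
  }
  if (prod(dim(raw)[1:2]) == 0L) stop(sprintf("zero-area image: '%s'", path), call. = FALSE)
  tongue_image(round(raw * 255), source_path = path)
}

#' Write an image or mask as PNG
#'
#' `write_image_png` writes the 8-bit RGB array losslessly; `write_mask_png`
#' writes a boolean mask as a single-channel 0/255 PNG; `load_mask` reads one
#' back (any nonzero pixel is `TRUE`).
#'
#' @param img a [tongue_image].
#' @param mask a logical matrix.
#' @param path destination / source file path.
#' @return The path, invisibly (`load_mask` returns the logical matrix).
#' @export
write_image_png <- function(img, path) {
  png::writePNG(unclass(img) / 255, path)
  invisible(path)
}

#' @rdname write_image_png
#' @export
write_mask_png <- function(mask, path) {
  png::writePNG(matrix(as.numeric(mask), nrow(mask), ncol(mask)), path)
  invisible(path)
}

#' @rdname write_image_png
#' @export
load_mask <- function(path) {
  raw <- png::readPNG(path)
  if (length(dim(raw)) == 3L) raw <- raw[, , 1]
  raw > 0
}
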