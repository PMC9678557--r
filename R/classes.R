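#' Construct a tongue image object
#'
#' An 8-bit RGB raster stored as an H x W x 3 numeric array in row-major
#' screen orientation (origin top-left), channel order R, G, B, values on the
#' integer grid 0-255.
#'
#' @param pixels numeric H x W x 3 array with values in \[0, 255\].
#' @param source_path optional provenance path recorded as an attribute.
#' @return An object of class `tongue_image`.
#' @export
tongue_image <- function(pixels, source_path = NA_character_) {
  if (!is.array(pixels) || length(dim(pixels)) != 3L || dim(pixels)[3] != 3L) {
    stop_field("pixels", "must be an H x W x 3 array")
  }
  d <- dim(pixels)
  if (d[1] < 16L || d[2] < 16L) stop_field("pixels", "image must be at least 16 x 16")
  if (anyNA(pixels) || min(pixels) < 0 || max(pixels) > 255) {
    stop_field("pixels", "intensities must lie in [0, 255]")
  }
  structure(pixels,
            source_path = source_path,
            color_space_tag = "sRGB-8bit",
            class = c("tongue_image", "array"))
}

#' Construct body/coating region masks
#'
#' The three masks share the image's H x W shape. `body` and `coating` must
#' partition `tongue`: they are disjoint and their union equals the tongue
#' mask.
#'
#' @param tongue,body,coating logical H x W matrices.
#' @return An object of class `region_masks` (a list of the three masks).
#' @export
region_masks <- function(tongue, body = NULL, coating = NULL) {
  if (!is.matrix(tongue) || !is.logical(tongue)) {
    stop_field("tongue", "must be a logical matrix")
  }
  if (is.null(body)) body <- matrix(FALSE, nrow(tongue), ncol(tongue))
  if (is.null(coating)) coating <- matrix(FALSE, nrow(tongue), ncol(tongue))
  if (!identical(dim(body), dim(tongue)) || !identical(dim(coating), dim(tongue))) {
    stop_field("body/coating", "mask shapes must match the tongue mask")
  }
  if (any(body & coating)) {
    stop_field("body/coating", "body and coating masks must be disjoint")
  }
  if (any(body & !tongue) || any(coating & !tongue)) {
    stop_field("body/coating", "body and coating must be subsets of the tongue mask")
  }
  if ((any(body) || any(coating)) && !identical(body | coating, tongue)) {
    stop_field("body/coating", "body and coating must partition the tongue mask")
  }
  structure(list(tongue = tongue, body = body, coating = coating),
            class = "region_masks")
}

#' @export
print.tongue_image <- function(x, ...) {
  d <- dim(x)
  cat(sprintf("<tongue_image> %d x %d sRGB-8bit (source: %s)\n",
              d[1], d[2], attr(x, "source_path")))
  invisible(x)
}

#' @export
print.region_masks <- function(x, ...) {
  cat(sprintf("<region_masks> tongue: %d px, body: %d px, coating: %d px\n",
              sum(x$tongue), sum(x$body), sum(x$coating)))
  invisible(x)
}
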