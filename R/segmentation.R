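# Tongue segmentation and the body/coating split. The study-style capture
# places a well-lit tongue on a dark background, so thresholding + largest
# connected component + morphological closing suffices; all quantitative
# feature tests can bypass segmentation entirely by supplying ground-truth
# masks.

#' Segmentation and splitting configurations
#'
#' `segment_config` controls tongue isolation: a pixel is a tongue candidate
#' when it is saturated and red (tongue body) or simply bright (pale
#' coating); the tongue is the largest connected candidate component after
#' morphological closing. `split_config` controls the body/coating rule: a
#' tongue pixel is coating when its saturation falls below
#' `coating_max_saturation` and its brightness exceeds
#' `coating_min_intensity` (coatings are whiter and paler than the body).
#'
#' @param min_saturation,min_red saturated-and-red criterion: S >=
#'   `min_saturation` and R >= `min_red` (gray levels).
#' @param min_intensity alternative brightness criterion, gray levels.
#' @param morph_radius radius (pixels) of the disc brush for closing.
#' @param coating_max_saturation saturation ceiling for coating pixels.
#' @param coating_min_intensity brightness floor (gray levels) for coating
#'   pixels.
#' @return A named list of thresholds.
#' @export
segment_config <- function(min_saturation = 0.08, min_red = 60,
                           min_intensity = 60, morph_radius = 3L) {
  list(min_saturation = min_saturation, min_red = min_red,
       min_intensity = min_intensity, morph_radius = as.integer(morph_radius))
}

#' @rdname segment_config
#' @export
split_config <- function(coating_max_saturation = 0.15,
                         coating_min_intensity = 140) {
  list(coating_max_saturation = coating_max_saturation,
       coating_min_intensity = coating_min_intensity)
}

.pixel_his <- function(img) {
  rgb_to_his(as.vector(img[, , 1]), as.vector(img[, , 2]), as.vector(img[, , 3]))
}

#' Isolate the tongue region
#'
#' Thresholds the image with the saturated-and-red / bright criterion,
#' applies a morphological closing (disc brush), and keeps the largest
#' connected component. Deterministic: the same image and configuration
#' always give the same mask.
#'
#' @param img a [tongue_image].
#' @param cfg a [segment_config()].
#' @return A [region_masks] with the tongue mask set and body/coating empty.
#' @export
segment_tongue <- function(img, cfg = segment_config()) {
  his <- .pixel_his(img)
  h <- dim(img)[1]; w <- dim(img)[2]
  red <- matrix(his$S >= cfg$min_saturation & as.vector(img[, , 1]) >= cfg$min_red, h, w)
  bright <- matrix(his$I >= cfg$min_intensity, h, w)
  cand <- red | bright
  if (!any(cand)) stop("no tongue region: no pixel passes the segmentation criterion", call. = FALSE)
  if (cfg$morph_radius > 0) {
    brush <- EBImage::makeBrush(2L * cfg$morph_radius + 1L, shape = "disc")
    cand <- EBImage::closing(cand * 1, brush) > 0
  }
  labels <- EBImage::bwlabel(cand * 1)
  tab <- tabulate(labels[labels > 0])
  tongue <- matrix(labels == which.max(tab), h, w)
  region_masks(tongue)
}

#' Split the tongue into body and coating
#'
#' Applies the pale-and-bright coating rule of [split_config()] to every
#' tongue pixel; each pixel lands in exactly one of body/coating. Supply
#' externally known masks directly to [region_masks()] to bypass the rule.
#'
#' @param img a [tongue_image].
#' @param tongue logical tongue mask (nonempty).
#' @param cfg a [split_config()].
#' @return A [region_masks] with the full tongue/body/coating partition.
#' @export
split_body_coating <- function(img, tongue, cfg = split_config()) {
  if (!any(tongue)) stop_field("tongue", "tongue mask is empty")
  his <- .pixel_his(img)
  h <- dim(img)[1]; w <- dim(img)[2]
  pale <- matrix(his$S < cfg$coating_max_saturation &
                   his$I > cfg$coating_min_intensity, h, w)
  coating <- tongue & pale
  region_masks(tongue, body = tongue & !coating, coating = coating)
}

#' Jaccard overlap of two masks
#'
#' @param a,b logical matrices of equal shape.
#' @return Intersection over union; 1 when both masks are empty.
#' @export
mask_jaccard <- function(a, b) {
  u <- sum(a | b)
  if (u == 0) return(1)
  sum(a & b) / u
}
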