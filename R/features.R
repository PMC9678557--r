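# One-call feature extraction: the 12 chromatic indexes plus the 4
# gray-difference texture statistics per region.

#' Extract the full feature record of an image
#'
#' Computes, for each nonempty region mask (body, coating), the chromatic
#' profile and the texture statistics, returning one row per region.
#'
#' @param img a [tongue_image].
#' @param masks a [region_masks] with the body/coating partition.
#' @param delta,m,gray passed to [gray_difference_histogram()].
#' @param mode,l_scale passed to [profile_region()].
#' @param ent_base passed to [texture_features()].
#' @return A data.frame with one row per region: `region`, the 12 chromatic
#'   indexes, `MEAN`, `CON`, `ASM`, `ENT`, and `n_pixels`.
#' @export
extract_features <- function(img, masks, delta = c(1L, 1L), m = 256L,
                             gray = "bt601", mode = "mean-rgb",
                             l_scale = "0-255", ent_base = 2) {
  rows <- lapply(c("body", "coating"), function(region) {
    mask <- masks[[region]]
    if (!any(mask)) return(NULL)
    prof <- profile_region(img, mask, region_label = region, mode = mode,
                           l_scale = l_scale)
    tex <- texture_features(
      gray_difference_histogram(img, mask, delta = delta, m = m, gray = gray,
                                region_label = region),
      ent_base = ent_base)
    cbind(data.frame(region = region, stringsAsFactors = FALSE),
          prof[, c("R", "G", "B", "H", "I", "S", "L_star", "a_star", "b_star",
                   "Y", "Cb", "Cr")],
          data.frame(MEAN = tex$MEAN, CON = tex$CON, ASM = tex$ASM,
                     ENT = tex$ENT, n_pixels = prof$n_pixels))
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Write a feature record as JSON
#'
#' @param features data.frame from [extract_features()].
#' @param path destination file.
#' @export
write_features_json <- function(features, path) {
  jsonlite::write_json(features, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
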