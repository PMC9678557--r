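# Chromatic index conversions. All converters are vectorised over equal-length
# R, G, B vectors of 8-bit intensities.

#' Convert RGB to hue / intensity (brightness) / saturation
#'
#' The geometric HSI transform used by computerized tongue diagnosis systems:
#' \deqn{I = (R + G + B) / 3}
#' \deqn{S = 1 - 3\,\min(R, G, B) / (R + G + B)}
#' \deqn{H = \arccos\frac{\tfrac12[(R-G) + (R-B)]}{\sqrt{(R-G)^2 + (R-B)(G-B)}}}
#' with the reflection H := 360 - H applied when B > G so that hue runs the
#' full colour wheel (red 0, green 120, blue 240 degrees). Achromatic pixels
#' (R = G = B, including pure black) return H = 0 and S = 0 by convention.
#'
#' @param r,g,b numeric vectors of intensities in \[0, 255\].
#' @return A data.frame with columns `H` (degrees in \[0, 360)), `I`
#'   (\[0, 255\]) and `S` (\[0, 1\]).
#' @examples
#' rgb_to_his(200, 100, 100)  # H = 0, I = 133.33, S = 0.25
#' @export
rgb_to_his <- function(r, g, b) {
  stopifnot(length(r) == length(g), length(g) == length(b))
  total <- r + g + b
  i <- total / 3
  s <- ifelse(total > 0, 1 - 3 * pmin(r, g, b) / total, 0)
  num <- 0.5 * ((r - g) + (r - b))
  den <- sqrt((r - g)^2 + (r - b) * (g - b))
  theta <- ifelse(den > 0, acos(clip(num / den, -1, 1)) * 180 / pi, 0)
  h <- ifelse(b > g, 360 - theta, theta)
  h <- ifelse(h >= 360, 0, h)
  data.frame(H = h, I = i, S = s)
}

# sRGB (IEC 61966-2-1) linearisation and the D65 RGB->XYZ matrix; the white
# point is taken as the matrix row sums so that (255,255,255) maps exactly to
# L* = 100, a* = b* = 0.
.srgb_xyz <- matrix(c(0.412456439089692, 0.357576077643909, 0.180437483266399,
                      0.212672851405623, 0.715152155287818, 0.072174993306560,
                      0.019333895582329, 0.119192025881303, 0.950304078536368),
                    nrow = 3, byrow = TRUE)

.srgb_linear <- function(v) ifelse(v <= 0.04045, v / 12.92, ((v + 0.055) / 1.055)^2.4)

#' Convert RGB to CIE L*a*b*
#'
#' Standard sRGB -> XYZ (D65, 2 degree observer) -> CIELAB. By default L* is
#' rescaled from its canonical 0-100 range to 0-255 (multiplied by 255/100),
#' the convention tongue-diagnosis systems use when reporting lightness
#' alongside 8-bit channels; a* and b* are left unshifted and sign-carrying.
#'
#' @param r,g,b numeric vectors of intensities in \[0, 255\].
#' @param l_scale `"0-255"` (default) or `"0-100"` for the canonical L* range.
#' @return A data.frame with columns `L_star`, `a_star`, `b_star`.
#' @export
rgb_to_lab <- function(r, g, b, l_scale = c("0-255", "0-100")) {
  stopifnot(length(r) == length(g), length(g) == length(b))
  l_scale <- match.arg(l_scale)
  rgb_lin <- rbind(.srgb_linear(r / 255), .srgb_linear(g / 255), .srgb_linear(b / 255))
  xyz <- .srgb_xyz %*% rgb_lin
  white <- rowSums(.srgb_xyz)
  t <- xyz / white
  eps <- (6 / 29)^3
  f <- ifelse(t > eps, t^(1 / 3), t / (3 * (6 / 29)^2) + 4 / 29)
  fx <- f[1, ]; fy <- f[2, ]; fz <- f[3, ]
  L <- 116 * fy - 16
  if (l_scale == "0-255") L <- L * 255 / 100
  data.frame(L_star = L, a_star = 500 * (fx - fy), b_star = 200 * (fy - fz))
}

#' Convert RGB to YCbCr (full-range BT.601)
#'
#' Full-range ITU-R BT.601 ("JPEG") coefficients: Y = 0.299R + 0.587G +
#' 0.114B; Cb and Cr are 128-centered chroma offsets. Outputs are clipped to
#' \[0, 255\] (the red/blue extremes overshoot by 0.5 before clipping).
#'
#' @param r,g,b numeric vectors of intensities in \[0, 255\].
#' @return A data.frame with columns `Y`, `Cb`, `Cr`.
#' @export
rgb_to_ycbcr <- function(r, g, b) {
  stopifnot(length(r) == length(g), length(g) == length(b))
  y <- 0.299 * r + 0.587 * g + 0.114 * b
  cb <- 128 - 0.168736 * r - 0.331264 * g + 0.5 * b
  cr <- 128 + 0.5 * r - 0.418688 * g - 0.081312 * b
  data.frame(Y = clip(y, 0, 255), Cb = clip(cb, 0, 255), Cr = clip(cr, 0, 255))
}

#' Chromatic profile of a masked image region
#'
#' Computes the twelve chromatic indexes (R, G, B, H, I, S, L*, a*, b*, Y, Cb,
#' Cr) over the pixels selected by `mask`. By default the region is summarised
#' by its mean RGB triple which is then converted once
#' (`mode = "mean-rgb"`) — circular quantities like hue have no well-defined
#' arithmetic mean over pixels, and one value per region is what group
#' comparisons consume. `mode = "per-pixel"` instead converts every pixel and
#' averages H, I and S (sensitivity analysis; L*a*b*/YCbCr are likewise
#' averaged per pixel in that mode). The two modes coincide on constant
#' regions.
#'
#' @param img a [tongue_image].
#' @param mask logical matrix matching the image, with at least one `TRUE`.
#' @param region_label label stored in the profile (e.g. "body", "coating").
#' @param mode `"mean-rgb"` (default) or `"per-pixel"`.
#' @param l_scale passed to [rgb_to_lab()].
#' @return An object of class `chromatic_profile`: a one-row data.frame with
#'   the 12 indexes plus `region_label` and `n_pixels`.
#' @export
profile_region <- function(img, mask, region_label = "region",
                           mode = c("mean-rgb", "per-pixel"),
                           l_scale = c("0-255", "0-100")) {
  mode <- match.arg(mode)
  l_scale <- match.arg(l_scale)
  if (!is.matrix(mask) || !identical(dim(mask), dim(img)[1:2])) {
    stop_field("mask", "must be a logical matrix matching the image shape")
  }
  n <- sum(mask)
  if (n < 1L) stop_field("mask", "region is empty")
  r <- img[, , 1][mask]; g <- img[, , 2][mask]; b <- img[, , 3][mask]
  if (mode == "mean-rgb") {
    his <- rgb_to_his(mean(r), mean(g), mean(b))
    lab <- rgb_to_lab(mean(r), mean(g), mean(b), l_scale = l_scale)
    ycc <- rgb_to_ycbcr(mean(r), mean(g), mean(b))
  } else {
    his <- colMeans(rgb_to_his(r, g, b))
    lab <- colMeans(rgb_to_lab(r, g, b, l_scale = l_scale))
    ycc <- colMeans(rgb_to_ycbcr(r, g, b))
    his <- as.data.frame(as.list(his)); lab <- as.data.frame(as.list(lab))
    ycc <- as.data.frame(as.list(ycc))
  }
  out <- data.frame(R = mean(r), G = mean(g), B = mean(b),
                    H = his$H, I = his$I, S = his$S,
                    L_star = lab$L_star, a_star = lab$a_star, b_star = lab$b_star,
                    Y = ycc$Y, Cb = ycc$Cb, Cr = ycc$Cr,
                    region_label = region_label, n_pixels = n,
                    stringsAsFactors = FALSE)
  class(out) <- c("chromatic_profile", "data.frame")
  out
}
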