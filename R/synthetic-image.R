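# Synthetic tongue images with known ground-truth body/coating masks.

#' Specification for a synthetic tongue image
#'
#' Describes an elliptical tongue on a dark background: a reddish body with a
#' paler, anterior-shifted coating patch covering `coating_fraction` of the
#' tongue pixels, plus a sinusoidal luminance modulation (controllable
#' texture) and additive gray-level noise. Defaults depict a light-red tongue
#' body with a whitish coating over roughly a third of the surface, mild
#' sensor noise, and a texture wavelength of 24 px.
#'
#' @param width,height image size in pixels (>= 16).
#' @param body_color,coating_color RGB triplets in \[0, 255\].
#' @param coating_fraction proportion of tongue pixels assigned to coating,
#'   in \[0, 1\].
#' @param noise_sd standard deviation (gray levels) of the i.i.d. additive
#'   noise; one draw per pixel, added to all three channels.
#' @param texture_period wavelength in pixels of the sinusoidal luminance
#'   modulation; `Inf` disables it.
#' @param texture_amp amplitude of the modulation in gray levels.
#' @param seed RNG seed; the generator is a pure function of the spec.
#' @return An object of class `image_spec`.
#' @export
image_spec <- function(width = 256L, height = 256L,
                       body_color = c(180, 90, 95),
                       coating_color = c(205, 195, 185),
                       coating_fraction = 0.35,
                       noise_sd = 5,
                       texture_period = 24,
                       texture_amp = 8,
                       seed = 1L) {
  assert_scalar_number(width, "width", lo = 16)
  assert_scalar_number(height, "height", lo = 16)
  assert_rgb_triplet(body_color, "body_color")
  assert_rgb_triplet(coating_color, "coating_color")
  assert_scalar_number(coating_fraction, "coating_fraction", lo = 0, hi = 1)
  assert_scalar_number(noise_sd, "noise_sd", lo = 0)
  if (!(is.numeric(texture_period) && length(texture_period) == 1L &&
        (is.infinite(texture_period) || texture_period > 0))) {
    stop_field("texture_period", "must be a positive number or Inf")
  }
  assert_scalar_number(texture_amp, "texture_amp", lo = 0)
  assert_scalar_number(seed, "seed")
  structure(list(width = as.integer(width), height = as.integer(height),
                 body_color = body_color, coating_color = coating_color,
                 coating_fraction = coating_fraction, noise_sd = noise_sd,
                 texture_period = texture_period, texture_amp = texture_amp,
                 seed = as.integer(seed)),
            class = "image_spec")
}

#' Generate a synthetic tongue image with ground-truth masks
#'
#' Renders the tongue as an axis-aligned ellipse (semi-axes 0.42 width, 0.45
#' height) on a dark background. The coating is the set of tongue pixels
#' closest, in elliptical distance, to a centre shifted 10% of the height
#' towards the anterior (top) edge, sized to exactly
#' `round(coating_fraction * n_tongue)` pixels (ties broken by pixel order,
#' so the patch is contiguous and deterministic). The sinusoidal modulation
#' `texture_amp * sin(2 pi (row + col) / texture_period)` and the gray noise
#' are added, then the image is clipped to \[0, 255\] and rounded to the
#' 8-bit grid. Identical specs (including seed) give bit-identical output.
#'
#' @param spec an [image_spec].
#' @return A list with `image` (a [tongue_image]) and `masks`
#'   (a [region_masks] with the ground-truth tongue/body/coating partition).
#' @export
generate_tongue_image <- function(spec) {
  if (!inherits(spec, "image_spec")) spec <- do.call(image_spec, spec)
  h <- spec$height; w <- spec$width
  row <- matrix(seq_len(h), h, w)
  col <- matrix(seq_len(w), h, w, byrow = TRUE)
  cx <- (w + 1) / 2; cy <- (h + 1) / 2
  ax <- 0.42 * w; ay <- 0.45 * h
  tongue <- ((col - cx) / ax)^2 + ((row - cy) / ay)^2 <= 1
  n_tongue <- sum(tongue)

  # coating: the coating_fraction quantile of elliptical distance to an
  # anterior-shifted centre, restricted to tongue pixels
  cy_coat <- cy - 0.10 * h
  dist <- ((col - cx) / ax)^2 + ((row - cy_coat) / ay)^2
  k <- round(spec$coating_fraction * n_tongue)
  coating <- matrix(FALSE, h, w)
  if (k > 0) {
    idx <- which(tongue)
    ord <- idx[order(dist[idx])]
    coating[ord[seq_len(k)]] <- TRUE
  }
  body <- tongue & !coating

  background <- c(15, 15, 15)
  px <- array(0, dim = c(h, w, 3))
  for (ch in 1:3) {
    plane <- matrix(background[ch], h, w)
    plane[body] <- spec$body_color[ch]
    plane[coating] <- spec$coating_color[ch]
    px[, , ch] <- plane
  }
  if (is.finite(spec$texture_period) && spec$texture_amp > 0) {
    wave <- spec$texture_amp * sin(2 * pi * (row + col) / spec$texture_period)
    wave[!tongue] <- 0
    for (ch in 1:3) px[, , ch] <- px[, , ch] + wave
  }
  if (spec$noise_sd > 0) {
    noise <- with_seed(spec$seed, matrix(stats::rnorm(h * w, sd = spec$noise_sd), h, w))
    for (ch in 1:3) px[, , ch] <- px[, , ch] + noise
  }
  px <- round(clip(px, 0, 255))
  list(image = tongue_image(px, source_path = "synthetic"),
       masks = region_masks(tongue, body, coating))
}
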