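# Gray-difference texture statistics: the histogram hg of absolute gray
# differences at a small pixel offset (delta_i, delta_j), and the four summary
# statistics MEAN, CON, ASM, ENT computed from it.

.gray_matrix <- function(img, m, gray) {
  f <- switch(gray,
              bt601 = 0.299 * img[, , 1] + 0.587 * img[, , 2] + 0.114 * img[, , 3],
              mean  = (img[, , 1] + img[, , 2] + img[, , 3]) / 3)
  # round half-to-even onto the m-level grid
  if (m == 256L) round(f) else round(f * (m - 1) / 255)
}

.offset_differences <- function(f, mask, delta) {
  di <- delta[1]; dj <- delta[2]
  h <- nrow(f); w <- ncol(f)
  i0 <- seq_len(h); j0 <- seq_len(w)
  ii <- i0 + di; jj <- j0 + dj
  keep_i <- i0[ii >= 1 & ii <= h]; keep_j <- j0[jj >= 1 & jj <= w]
  if (length(keep_i) == 0L || length(keep_j) == 0L) return(numeric(0))
  a <- f[keep_i, keep_j, drop = FALSE]
  b <- f[keep_i + di, keep_j + dj, drop = FALSE]
  ok <- mask[keep_i, keep_j, drop = FALSE] & mask[keep_i + di, keep_j + dj, drop = FALSE]
  abs(a[ok] - b[ok])
}

#' Gray-difference histogram of a masked region
#'
#' Converts the image to gray levels `0 ... m-1` (BT.601 luma by default,
#' rounded half-to-even), forms the difference `g(i,j) = f(i,j) -
#' f(i+di, j+dj)` over every pixel pair with both ends inside the mask, and
#' returns the normalised histogram `hg` of `|g|` over bins `0 ... m-1`.
#' `delta` may be a single `(di, dj)` offset or a matrix with one offset per
#' row, in which case the pairs from all offsets are pooled into one
#' histogram.
#'
#' @param img a [tongue_image].
#' @param mask logical matrix; the region of interest.
#' @param delta integer offset pair, default `c(1, 1)`; or an offset matrix
#'   such as `rbind(c(0,1), c(1,0), c(1,1), c(1,-1))`.
#' @param m number of gray levels (default 256).
#' @param gray `"bt601"` luma (default) or `"mean"` channel average.
#' @return An object of class `texture_profile` with `hg` (probabilities
#'   summing to 1), `m`, `delta`, `region_label` and unset statistics.
#' @export
gray_difference_histogram <- function(img, mask, delta = c(1L, 1L), m = 256L,
                                      gray = c("bt601", "mean"),
                                      region_label = "region") {
  gray <- match.arg(gray)
  if (!is.matrix(mask) || !identical(dim(mask), dim(img)[1:2])) {
    stop_field("mask", "must be a logical matrix matching the image shape")
  }
  if (!any(mask)) stop_field("mask", "region is empty")
  if (is.null(dim(delta))) delta <- matrix(delta, nrow = 1)
  if (ncol(delta) != 2L) stop_field("delta", "offsets must have two components")
  assert_scalar_number(m, "m", lo = 2)
  f <- .gray_matrix(img, as.integer(m), gray)
  diffs <- unlist(lapply(seq_len(nrow(delta)), function(k) {
    .offset_differences(f, mask, as.integer(delta[k, ]))
  }))
  if (length(diffs) == 0L) {
    stop("degenerate region: no pixel pair at the requested offset lies inside the mask",
         call. = FALSE)
  }
  hg <- tabulate(diffs + 1L, nbins = as.integer(m))
  hg <- hg / sum(hg)
  structure(list(hg = hg, m = as.integer(m), delta = delta, n_pairs = length(diffs),
                 region_label = region_label,
                 MEAN = NA_real_, CON = NA_real_, ASM = NA_real_, ENT = NA_real_),
            class = "texture_profile")
}

#' Texture statistics from a gray-difference histogram
#'
#' Completes a [gray_difference_histogram()] profile with the four summary
#' statistics:
#' \deqn{MEAN = \frac{1}{m}\sum_i i\, h_g(i)}
#' \deqn{CON = \sum_i i^2\, h_g(i)}
#' \deqn{ASM = \sum_i h_g(i)^2}
#' \deqn{ENT = -\sum_i h_g(i) \log_2 h_g(i)}
#' with the usual convention 0 log 0 = 0. A concentrated histogram gives high
#' ASM and low ENT/CON (smooth, homogeneous region); a spread histogram the
#' reverse.
#'
#' @param profile a `texture_profile` carrying a normalised `hg`.
#' @param ent_base logarithm base for the entropy (default 2, i.e. bits).
#' @return The completed `texture_profile`.
#' @export
texture_features <- function(profile, ent_base = 2) {
  hg <- profile$hg
  if (is.null(hg) || abs(sum(hg) - 1) > 1e-8 || any(hg < 0)) {
    stop_field("hg", "must be a normalised histogram (non-negative, summing to 1)")
  }
  i <- seq_along(hg) - 1
  pos <- hg > 0
  profile$MEAN <- sum(i * hg) / profile$m
  profile$CON <- sum(i^2 * hg)
  profile$ASM <- sum(hg^2)
  profile$ENT <- -sum(hg[pos] * log(hg[pos], base = ent_base))
  profile
}

#' Brute-force texture reference (testing oracle)
#'
#' Recomputes the gray-difference histogram and all four statistics with
#' explicit double loops over pixel coordinates, with no vectorisation or
#' shared code with the main path. Intended for small regions (<= 64 x 64) in
#' tests.
#'
#' @inheritParams gray_difference_histogram
#' @inheritParams texture_features
#' @return A completed `texture_profile`.
#' @export
texture_oracle <- function(img, mask, delta = c(1L, 1L), m = 256L,
                           gray = c("bt601", "mean"), ent_base = 2) {
  gray <- match.arg(gray)
  if (sum(mask) > 64 * 64) stop("texture_oracle is restricted to regions <= 64x64 pixels")
  if (is.null(dim(delta))) delta <- matrix(delta, nrow = 1)
  h <- dim(img)[1]; w <- dim(img)[2]
  f <- matrix(0, h, w)
  for (i in seq_len(h)) {
    for (j in seq_len(w)) {
      v <- switch(gray,
                  bt601 = 0.299 * img[i, j, 1] + 0.587 * img[i, j, 2] + 0.114 * img[i, j, 3],
                  mean  = (img[i, j, 1] + img[i, j, 2] + img[i, j, 3]) / 3)
      f[i, j] <- if (m == 256L) round(v) else round(v * (m - 1) / 255)
    }
  }
  counts <- numeric(m)
  n_pairs <- 0L
  for (k in seq_len(nrow(delta))) {
    di <- delta[k, 1]; dj <- delta[k, 2]
    for (i in seq_len(h)) {
      for (j in seq_len(w)) {
        i2 <- i + di; j2 <- j + dj
        if (i2 >= 1 && i2 <= h && j2 >= 1 && j2 <= w && mask[i, j] && mask[i2, j2]) {
          d <- abs(f[i, j] - f[i2, j2])
          counts[d + 1] <- counts[d + 1] + 1
          n_pairs <- n_pairs + 1L
        }
      }
    }
  }
  if (n_pairs == 0L) stop("degenerate region: no pixel pair", call. = FALSE)
  hg <- counts / sum(counts)
  mean_s <- 0; con <- 0; asm <- 0; ent <- 0
  for (i in seq_len(m)) {
    p <- hg[i]; v <- i - 1
    mean_s <- mean_s + v * p / m
    con <- con + v^2 * p
    asm <- asm + p * p
    if (p > 0) ent <- ent - p * log(p, base = ent_base)
  }
  structure(list(hg = hg, m = as.integer(m), delta = delta, n_pairs = n_pairs,
                 region_label = "oracle",
                 MEAN = mean_s, CON = con, ASM = asm, ENT = ent),
            class = "texture_profile")
}

#' @export
print.texture_profile <- function(x, ...) {
  cat(sprintf("<texture_profile> %s: m = %d, pairs = %d\n  MEAN = %.5f  CON = %.3f  ASM = %.4f  ENT = %.4f\n",
              x$region_label, x$m, x$n_pairs, x$MEAN, x$CON, x$ASM, x$ENT))
  invisible(x)
}
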