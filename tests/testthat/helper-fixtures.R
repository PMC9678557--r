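# Fixture builders shared across tests. Everything is generated in code.

# A gray 16x16 image with chosen values painted into the first rows; the rest
# is zero. Returns list(image, mask over the painted pixels).
gray_row_image <- function(values, m = 16L) {
  px <- array(0, dim = c(m, m, 3))
  mask <- matrix(FALSE, m, m)
  px[1, seq_along(values), ] <- rep(values, times = 3)
  mask[1, seq_along(values)] <- TRUE
  list(image = tongue_image(px), mask = mask)
}

random_test_image <- function(side = 16L) {
  tongue_image(array(sample(0:255, side * side * 3, replace = TRUE),
                     dim = c(side, side, 3)))
}

random_mask_with_pairs <- function(side = 16L, p = 0.7, delta = c(1L, 1L)) {
  repeat {
    mask <- matrix(stats::runif(side * side) < p, side, side)
    # need at least one in-mask pair at the offset
    ok <- mask[seq_len(side - abs(delta[1])), seq_len(side - abs(delta[2]))] &
      mask[seq_len(side - abs(delta[1])) + abs(delta[1]),
           seq_len(side - abs(delta[2])) + abs(delta[2])]
    if (any(ok)) return(mask)
  }
}

# 2x2 count tables from the study's printed feature counts
# (rows = exposure yes/no, columns = case/control)
greasy_table <- function() matrix(c(38, 6, 2, 34), 2)
thick_table <- function() matrix(c(34, 6, 5, 35), 2)
tooth_table <- function() matrix(c(15, 25, 6, 34), 2)
white_table <- function() matrix(c(32, 8, 7, 33), 2)

# A deterministic 40 + 40 cohort whose categorical marginals equal the
# printed study counts exactly (joint structure arbitrary: categories are
# assigned by subject position, which only marginal statistics consume).
exact_count_cohort <- function() {
  fill <- function(n, counts) rep(names(counts), times = counts)
  glm <- data.frame(
    subject_id = sprintf("G%02d", 1:40), group = "GLM",
    age = rep(c(30, 38), 20),
    tongue_shape = fill(40, c(fat = 13, moderate = 27)),
    body_color = fill(40, c(light_red = 40)),
    coating_color = fill(40, c(white = 32, yellow = 2, none = 6)),
    coating_thick = fill(40, c(thick = 34, thin = 6)),
    coating_greasy = fill(40, c(greasy = 38, normal = 2)),
    tooth_marked = fill(40, c(yes = 15, no = 25)),
    prick = "no",
    sublingual_vessel = fill(40, c(yes = 15, no = 25)),
    ecchymosis = "no",
    stringsAsFactors = FALSE)
  ctl <- data.frame(
    subject_id = sprintf("C%02d", 1:40), group = "control",
    age = rep(c(29, 37), 20),
    tongue_shape = fill(40, c(fat = 6, moderate = 25, small_thin = 9)),
    body_color = fill(40, c(light_red = 29, red = 11)),
    coating_color = fill(40, c(white = 7, yellow = 5, none = 28)),
    coating_thick = fill(40, c(thick = 5, thin = 35)),
    coating_greasy = fill(40, c(greasy = 6, normal = 34)),
    tooth_marked = fill(40, c(yes = 6, no = 34)),
    prick = "no",
    sublingual_vessel = "no",
    ecchymosis = "no",
    stringsAsFactors = FALSE)
  rec <- rbind(glm, ctl)
  for (mk in c("wbc", "plt", "crp", "il2", "il6", "tgfb")) {
    rec[[mk]] <- seq(1, 3, length.out = nrow(rec))
  }
  rec
}

# Brute-force Mann-Whitney oracle: enumerates every assignment of the pooled
# observations to the first sample and computes the symmetric two-sided
# exact p. Independent of the package's counting recursion.
mwu_enumeration_oracle <- function(x, y) {
  pooled <- c(x, y)
  n1 <- length(x); n <- length(pooled)
  r <- rank(pooled)
  u_obs <- sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2
  mu <- n1 * length(y) / 2
  combos <- utils::combn(n, n1)
  us <- apply(combos, 2, function(idx) sum(r[idx]) - n1 * (n1 + 1) / 2)
  mean(abs(us - mu) >= abs(u_obs - mu) - 1e-9)
}
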