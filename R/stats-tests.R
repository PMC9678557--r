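# Rank and contingency tests, authored directly from their defining formulas.
# Base distribution tails (pchisq, pnorm, pt) supply the p-value lookups.

.test_result <- function(statistic, p_value, method, ...) {
  structure(c(list(statistic = statistic, p_value = p_value, method = method),
              list(...)),
            class = "test_result")
}

#' @export
print.test_result <- function(x, ...) {
  cat(sprintf("%s: statistic = %.6g, p = %.4g\n", x$method, x$statistic, x$p_value))
  invisible(x)
}

.as_2x2 <- function(t) {
  if (is.data.frame(t)) t <- as.matrix(t)
  if (!is.matrix(t) || !all(dim(t) == c(2, 2))) stop_field("table", "must be 2 x 2")
  if (anyNA(t) || any(t < 0) || any(t != round(t))) {
    stop_field("table", "counts must be non-negative integers")
  }
  if (sum(t) <= 0) stop_field("table", "total count must be positive")
  t
}

#' Pearson chi-square test for a 2x2 table
#'
#' Uncorrected by default: \eqn{\chi^2 = n(ad - bc)^2 / ((a+b)(c+d)(a+c)(b+d))}
#' on one degree of freedom. The Yates continuity correction (subtracting
#' n/2 from |ad - bc|) is available but off by default, which is the variant
#' that case-control 2x2 comparisons of tongue features report.
#'
#' @param t 2x2 count matrix, rows = exposure yes/no, columns = case/control.
#' @param yates apply the continuity correction.
#' @return A `test_result` with the statistic, df = 1 and the upper-tail
#'   chi-square p-value.
#' @examples
#' chi_square_2x2(matrix(c(38, 6, 2, 34), 2))  # p = 6.41e-13
#' @export
chi_square_2x2 <- function(t, yates = FALSE) {
  t <- .as_2x2(t)
  a <- t[1, 1]; b <- t[1, 2]; c <- t[2, 1]; d <- t[2, 2]
  n <- a + b + c + d
  margins <- c(a + b, c + d, a + c, b + d)
  if (any(margins == 0)) stop("degenerate margin: a row or column total is zero", call. = FALSE)
  num <- abs(a * d - b * c)
  if (yates) num <- max(0, num - n / 2)
  stat <- n * num^2 / prod(margins)
  .test_result(stat, stats::pchisq(stat, df = 1, lower.tail = FALSE),
               if (yates) "Pearson chi-square (Yates)" else "Pearson chi-square",
               df = 1L, n = n)
}

#' Mann-Whitney U test (Wilcoxon rank-sum)
#'
#' U is computed from the summed midranks of the first sample:
#' \eqn{U = R_1 - n_1(n_1+1)/2}. When both samples are small
#' (\eqn{n_1 + n_2 \le 12}) and there are no ties, the two-sided p-value is
#' exact: \eqn{P(|U - n_1 n_2/2| \ge |u - n_1 n_2/2|)} under the symmetric
#' null distribution obtained by the counting recursion. Otherwise a normal
#' approximation with the midrank tie correction and a 0.5 continuity
#' correction is used.
#'
#' @param x,y numeric samples.
#' @param exact force (`TRUE`) or forbid (`FALSE`) the exact path; default
#'   `NULL` chooses it automatically.
#' @return A `test_result` with `statistic` = U (for `x`), sample sizes and
#'   the path used.
#' @export
mann_whitney_u <- function(x, y, exact = NULL) {
  if (length(x) < 1L || length(y) < 1L) stop_field("x/y", "samples must be non-empty")
  if (anyNA(x) || anyNA(y)) stop_field("x/y", "samples must not contain NA")
  n1 <- length(x); n2 <- length(y)
  r <- rank(c(x, y))
  u <- sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2
  ties <- any(duplicated(c(x, y)))
  use_exact <- if (is.null(exact)) (n1 + n2 <= 12 && !ties) else (exact && !ties)
  mu <- n1 * n2 / 2
  if (use_exact) {
    dist <- .mwu_distribution(n1, n2)
    dev <- abs(seq_along(dist) - 1 - mu)
    p <- sum(dist[dev >= abs(u - mu) - 1e-9])
    method <- "Mann-Whitney U (exact)"
  } else {
    nn <- n1 + n2
    tie_tab <- table(c(x, y))
    sigma2 <- n1 * n2 / 12 * ((nn + 1) - sum(tie_tab^3 - tie_tab) / (nn * (nn - 1)))
    if (sigma2 <= 0) {
      p <- 1
    } else {
      z <- (abs(u - mu) - 0.5) / sqrt(sigma2)
      p <- min(1, 2 * stats::pnorm(-max(0, z)))
    }
    method <- "Mann-Whitney U (normal approximation)"
  }
  .test_result(u, p, method, n1 = n1, n2 = n2)
}

# Exact null pmf of U over u = 0..n1*n2 (no ties), by the counting recursion
# N(u; m, n) = N(u - n; m - 1, n) + N(u; m, n - 1): conditioning on whether
# the largest rank belongs to the first sample (contributing n pairs) or the
# second. f[m + 1, u + 1] holds N(u; m, nn) as nn grows.
.mwu_distribution <- function(n1, n2) {
  maxu <- n1 * n2
  f <- matrix(0, nrow = n1 + 1, ncol = maxu + 1)
  f[, 1] <- 1  # n = 0: U is 0 whatever m
  for (nn in seq_len(n2)) {
    g <- matrix(0, nrow = n1 + 1, ncol = maxu + 1)
    g[1, 1] <- 1  # m = 0
    for (mm in seq_len(n1)) {
      for (u in 0:(mm * nn)) {
        take <- if (u >= nn) g[mm, u - nn + 1] else 0
        g[mm + 1, u + 1] <- take + f[mm + 1, u + 1]
      }
    }
    f <- g
  }
  f[n1 + 1, ] / choose(n1 + n2, n1)
}

#' Two-sample pooled-variance t test from summary statistics
#'
#' The two-tailed pooled t test on `df = n1 + n2 - 2` degrees of freedom,
#' callable from printed summary statistics (mean, SD, n per group) or, via
#' [two_sample_t_raw()], from raw data.
#'
#' @param mean1,sd1,n1 summary statistics of the first sample.
#' @param mean2,sd2,n2 summary statistics of the second sample.
#' @return A `test_result` with the t statistic and df.
#' @examples
#' two_sample_t(34.10, 11.03, 40, 33.13, 8.47, 40)  # p = 0.660
#' @export
two_sample_t <- function(mean1, sd1, n1, mean2, sd2, n2) {
  assert_scalar_number(n1, "n1", lo = 2); assert_scalar_number(n2, "n2", lo = 2)
  assert_scalar_number(sd1, "sd1", lo = 1e-300); assert_scalar_number(sd2, "sd2", lo = 1e-300)
  df <- n1 + n2 - 2
  sp2 <- ((n1 - 1) * sd1^2 + (n2 - 1) * sd2^2) / df
  t <- (mean1 - mean2) / sqrt(sp2 * (1 / n1 + 1 / n2))
  .test_result(t, 2 * stats::pt(-abs(t), df = df), "Two-sample t (pooled)", df = df)
}

#' @rdname two_sample_t
#' @param x,y raw numeric samples.
#' @export
two_sample_t_raw <- function(x, y) {
  two_sample_t(mean(x), stats::sd(x), length(x), mean(y), stats::sd(y), length(y))
}

#' Spearman rank correlation
#'
#' Midranks are assigned to each vector and r is the Pearson correlation of
#' the ranks, the definition that remains exact under ties. The p-value uses
#' the t approximation \eqn{t = r\sqrt{(n-2)/(1-r^2)}} on n - 2 degrees of
#' freedom.
#'
#' @param x,y paired numeric samples, length >= 3.
#' @return A `test_result` with `statistic` = r and `n`.
#' @export
spearman_cor <- function(x, y) {
  if (length(x) != length(y)) stop_field("x/y", "samples must be paired")
  ok <- !(is.na(x) | is.na(y))
  x <- x[ok]; y <- y[ok]
  n <- length(x)
  if (n < 3L) stop_field("x/y", "need at least 3 complete pairs")
  rx <- rank(x); ry <- rank(y)
  dx <- rx - mean(rx); dy <- ry - mean(ry)
  vx <- sum(dx^2); vy <- sum(dy^2)
  if (vx == 0 || vy == 0) stop("zero rank variance: an input vector is constant", call. = FALSE)
  r <- sum(dx * dy) / sqrt(vx * vy)
  if (abs(r) >= 1) {
    p <- 0
  } else {
    t <- r * sqrt((n - 2) / (1 - r^2))
    p <- 2 * stats::pt(-abs(t), df = n - 2)
  }
  .test_result(r, p, "Spearman rank correlation", n = n)
}
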