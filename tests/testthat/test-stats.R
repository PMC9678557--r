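test_that("chi-square reproduces the printed contingency p-values", {
  greasy <- chi_square_2x2(greasy_table())
  expect_equal(greasy$p_value, 6.410e-13, tolerance = 1e-3)
  thick <- chi_square_2x2(thick_table())
  expect_equal(thick$p_value, 8.779e-11, tolerance = 2e-4)
  tooth <- chi_square_2x2(tooth_table())
  expect_equal(tooth$p_value, 0.022, tolerance = 1e-2)
})

test_that("chi-square basics: independence, transposition, degenerate margins", {
  flat <- chi_square_2x2(matrix(10, 2, 2))
  expect_equal(flat$statistic, 0)
  expect_equal(flat$p_value, 1)
  t <- matrix(c(12, 5, 9, 20), 2)
  expect_equal(chi_square_2x2(t)$statistic, chi_square_2x2(t(t))$statistic)
  expect_error(chi_square_2x2(matrix(c(0, 0, 5, 5), 2)), "degenerate margin")
  expect_error(chi_square_2x2(matrix(c(1.5, 2, 3, 4), 2)), "integer")
})

test_that("chi-square agrees with the base-R implementation with and without Yates", {
  set.seed(31)
  for (i in 1:50) {
    t <- matrix(rpois(4, 12) + 1, 2)
    mine <- chi_square_2x2(t)
    ref <- suppressWarnings(chisq.test(t, correct = FALSE))
    expect_equal(mine$statistic, unname(ref$statistic), tolerance = 1e-12)
    expect_equal(mine$p_value, ref$p.value, tolerance = 1e-12)
    mine_y <- chi_square_2x2(t, yates = TRUE)
    ref_y <- suppressWarnings(chisq.test(t, correct = TRUE))
    expect_equal(mine_y$statistic, unname(ref_y$statistic), tolerance = 1e-12)
  }
})

test_that("univariate logistic reproduces the printed odds ratios and Wald CIs", {
  greasy <- logistic_univariate_2x2(greasy_table())
  expect_equal(unname(greasy$odds_ratios), 107.667, tolerance = 1e-5)
  expect_equal(unname(greasy$ci_low), 20.352, tolerance = 1e-4)
  expect_equal(unname(greasy$ci_high), 569.573, tolerance = 1e-4)
  expect_equal(unname(greasy$p_values), 3.688e-08, tolerance = 1e-3)
  white <- logistic_univariate_2x2(white_table())
  expect_equal(unname(white$odds_ratios), 18.857, tolerance = 1e-4)
  expect_equal(unname(white$ci_low), 6.123, tolerance = 1e-3)
  expect_equal(unname(white$ci_high), 58.079, tolerance = 1e-4)
})

test_that("univariate logistic: null table, zero-cell policy, OR identity", {
  null_fit <- logistic_univariate_2x2(matrix(10, 2, 2))
  expect_equal(unname(null_fit$coefficients), 0)
  expect_equal(unname(null_fit$odds_ratios), 1)
  expect_error(logistic_univariate_2x2(matrix(c(10, 0, 3, 7), 2)), "separation")
  h <- logistic_univariate_2x2(matrix(c(10, 0, 3, 7), 2), haldane = TRUE)
  expect_equal(unname(h$odds_ratios), (10.5 * 7.5) / (0.5 * 3.5))
  set.seed(61)
  t <- matrix(rpois(4, 20) + 1, 2)
  fit <- logistic_univariate_2x2(t)
  expect_equal(unname(fit$odds_ratios), exp(unname(fit$coefficients)))
  expect_true(fit$ci_low < fit$odds_ratios && fit$odds_ratios < fit$ci_high)
})

test_that("IRLS logistic equals the closed 2x2 form on the saturated model", {
  y <- c(rep(1, 40), rep(0, 40))
  x <- c(rep(1, 38), rep(0, 2), rep(1, 6), rep(0, 34))
  irls <- logistic_fit(y, cbind(intercept = 1, exposure = x))
  closed <- logistic_univariate_2x2(greasy_table())
  expect_true(irls$converged)
  expect_equal(unname(irls$coefficients["exposure"]),
               unname(closed$coefficients), tolerance = 1e-8)
  expect_equal(unname(irls$standard_errors["exposure"]),
               unname(closed$standard_errors), tolerance = 1e-8)
})

test_that("IRLS logistic matches glm and recovers known coefficients", {
  set.seed(71)
  n <- 800
  X <- cbind(1, rnorm(n), rbinom(n, 1, 0.4))
  y <- rbinom(n, 1, plogis(drop(X %*% c(-0.5, 1.2, -0.8))))
  mine <- logistic_fit(y, X)
  ref <- glm(y ~ X[, 2] + X[, 3], family = binomial)
  expect_equal(unname(mine$coefficients), unname(coef(ref)), tolerance = 1e-6)
  expect_equal(unname(mine$standard_errors),
               unname(summary(ref)$coefficients[, 2]), tolerance = 1e-4)

  set.seed(72)
  xr <- rnorm(5000)
  yr <- rbinom(5000, 1, plogis(-1 + 1.5 * xr))
  fit <- logistic_fit(yr, cbind(1, xr))
  expect_lt(abs(fit$coefficients[1] - (-1)), 0.1)
  expect_lt(abs(fit$coefficients[2] - 1.5), 0.1)
})

test_that("IRLS logistic flags perfect separation instead of erroring", {
  y <- c(rep(0, 10), rep(1, 10))
  x <- c(rep(0, 10), rep(1, 10))
  fit <- logistic_fit(y, cbind(1, x))
  expect_false(fit$converged)
  expect_error(logistic_fit(rep(1, 10), cbind(1, rnorm(10))), "both classes")
})

test_that("Mann-Whitney: trivial and hand-enumerated cases", {
  same <- mann_whitney_u(c(1, 2, 3, 4), c(1, 2, 3, 4))
  expect_equal(same$statistic, 8)  # n1*n2/2
  expect_gt(same$p_value, 0.9)
  sep <- mann_whitney_u(c(1, 2, 3), c(4, 5, 6))
  expect_equal(sep$statistic, 0)
  expect_equal(sep$p_value, 0.1)  # 2 / choose(6, 3)
  expect_error(mann_whitney_u(numeric(0), 1:3), "non-empty")
})

test_that("Mann-Whitney exact path equals the enumeration oracle", {
  set.seed(83)
  for (i in 1:60) {
    n1 <- sample(2:6, 1); n2 <- sample(2:6, 1)
    repeat {
      x <- round(rnorm(n1, sd = 5), 3)
      y <- round(rnorm(n2, sd = 5), 3)
      if (!any(duplicated(c(x, y)))) break
    }
    mine <- mann_whitney_u(x, y)
    expect_match(mine$method, "exact")
    expect_equal(mine$p_value, mwu_enumeration_oracle(x, y), tolerance = 1e-12)
  }
})

test_that("Mann-Whitney normal approximation tracks the base-R test under ties", {
  set.seed(89)
  for (i in 1:25) {
    x <- sample(1:8, 20, replace = TRUE)
    y <- sample(2:9, 25, replace = TRUE)
    mine <- mann_whitney_u(x, y)
    ref <- suppressWarnings(wilcox.test(x, y, exact = FALSE, correct = TRUE))
    expect_equal(mine$statistic, unname(ref$statistic), tolerance = 1e-12)
    expect_equal(mine$p_value, ref$p.value, tolerance = 1e-9)
  }
})

test_that("pooled t test reproduces the printed age comparison", {
  ages <- two_sample_t(34.10, 11.03, 40, 33.13, 8.47, 40)
  expect_equal(ages$p_value, 0.660, tolerance = 1e-3)
  expect_equal(ages$df, 78)
  eq <- two_sample_t(5, 1, 10, 5, 2, 12)
  expect_equal(eq$statistic, 0)
  expect_equal(eq$p_value, 1)
})

test_that("t test agrees with base-R on raw data and a hand-computed case", {
  set.seed(97)
  x <- rnorm(15, 10, 2); y <- rnorm(20, 11, 2)
  mine <- two_sample_t_raw(x, y)
  ref <- t.test(x, y, var.equal = TRUE)
  expect_equal(mine$statistic, unname(ref$statistic), tolerance = 1e-12)
  expect_equal(mine$p_value, ref$p.value, tolerance = 1e-12)
  # hand case: means 10 vs 12, sd 2 both, n 8 both -> sp = 2, t = -2
  hand <- two_sample_t(10, 2, 8, 12, 2, 8)
  expect_equal(hand$statistic, -2)
  expect_equal(hand$p_value, 2 * pt(-2, 14))
})

test_that("Spearman equals the rank-then-Pearson oracle, including ties", {
  expect_equal(spearman_cor(1:10, (1:10)^3)$statistic, 1)
  expect_equal(spearman_cor(1:10, -(1:10))$statistic, -1)
  set.seed(103)
  for (i in 1:50) {
    x <- sample(1:8, 20, replace = TRUE)
    y <- x + sample(-3:3, 20, replace = TRUE)
    mine <- spearman_cor(x, y)
    expect_equal(mine$statistic, cor(rank(x), rank(y)), tolerance = 1e-12)
    ref <- suppressWarnings(cor.test(x, y, method = "spearman"))
    expect_equal(mine$statistic, unname(ref$estimate), tolerance = 1e-12)
  }
  expect_error(spearman_cor(rep(1, 5), 1:5), "zero rank variance")
})

test_that("binary-marker AUC reproduces the printed values and their null tests", {
  greasy <- roc_auc_binary(38, 40, 6, 40)
  expect_equal(greasy$auc, 0.900, tolerance = 1e-9)
  expect_equal(greasy$p_value, 7.350e-10, tolerance = 1e-3)
  thick <- roc_auc_binary(34, 40, 5, 40)
  expect_equal(thick$auc, 0.8625, tolerance = 1e-9)
  expect_equal(thick$p_value, 2.388e-08, tolerance = 2e-3)
  flat <- roc_auc_binary(10, 40, 10, 40)
  expect_equal(flat$auc, 0.5)
})

test_that("rank AUC: perfect marker, binary reduction, complement identity", {
  labels <- c(rep(1, 15), rep(0, 25))
  expect_equal(roc_auc(labels, labels)$auc, 1)
  scores01 <- c(rep(1, 38), rep(0, 2), rep(1, 6), rep(0, 34))
  labels80 <- c(rep(1, 40), rep(0, 40))
  expect_equal(roc_auc(scores01, labels80)$auc, roc_auc_binary(38, 40, 6, 40)$auc)
  set.seed(107)
  sc <- rnorm(40)
  expect_equal(roc_auc(sc, labels)$auc + roc_auc(-sc, labels)$auc, 1, tolerance = 1e-12)
  expect_error(roc_auc(rnorm(5), rep(1, 5)), "both classes")
})
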