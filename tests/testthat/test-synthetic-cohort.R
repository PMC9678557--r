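test_that("large cohorts reproduce the default categorical marginals", {
  rec <- generate_cohort(cohort_spec(n_glm = 4000, n_control = 4000, seed = 21))
  glm <- rec[rec$group == "GLM", ]
  ctl <- rec[rec$group == "control", ]
  expect_lt(abs(mean(glm$coating_greasy == "greasy") - 0.95), 0.02)
  expect_lt(abs(mean(ctl$coating_greasy == "greasy") - 0.15), 0.02)
  # every simulated proportion within 3 binomial SEs of its spec probability
  probs <- default_category_probs()
  n <- 4000
  check <- function(observed, p) {
    if (p %in% c(0, 1)) expect_equal(observed, p)
    else expect_lt(abs(observed - p), 3 * sqrt(p * (1 - p) / n) + 1e-12)
  }
  for (feat in c("tongue_shape", "body_color", "coating_color")) {
    for (grp in c("GLM", "control")) {
      sub <- rec[rec$group == grp, ]
      for (lev in names(probs[[feat]][[grp]])) {
        check(mean(sub[[feat]] == lev), probs[[feat]][[grp]][[lev]])
      }
    }
  }
  check(mean(glm$coating_thick == "thick"), 0.85)
  check(mean(ctl$tooth_marked == "yes"), 0.15)
  check(mean(glm$sublingual_vessel == "yes"), 0.375)
  check(mean(ctl$sublingual_vessel == "yes"), 0)
})

test_that("zero category probability yields zero records", {
  spec <- cohort_spec(n_glm = 200, n_control = 200, seed = 5,
                      category_probs = list(coating_greasy = list(GLM = 0, control = 0)))
  rec <- generate_cohort(spec)
  expect_equal(sum(rec$coating_greasy == "greasy"), 0)
})

test_that("markers are right-skewed, confined to their ranges, median-anchored", {
  rec <- generate_cohort(cohort_spec(n_glm = 3000, n_control = 3000, seed = 33))
  params <- default_marker_params()
  for (mk in names(params)) {
    for (grp in c("GLM", "control")) {
      x <- rec[[mk]][rec$group == grp]
      p <- params[[mk]][[grp]]
      expect_true(all(x >= p$range[1] & x <= p$range[2]))
      # median anchoring, within sampling noise of the n = 3000 empirical
      # median (heavy-tailed markers like CRP have a wide median SE)
      expect_lt(abs(median(x) - p$median) / p$median, 0.10)
      expect_true(all(x > 0))
    }
  }
  # right skew where the printed envelope is strongly asymmetric
  crp <- rec$crp[rec$group == "GLM"]
  expect_gt(mean(crp), median(crp))
})

test_that("copula correlation targets induce the requested Spearman correlation", {
  spec <- cohort_spec(n_glm = 5000, n_control = 5000, seed = 44,
                      correlation_targets = list(
                        list(marker = "wbc", feature = "coating_CON", rho = -0.32)))
  rec <- generate_cohort(spec)
  glm <- rec[rec$group == "GLM", ]
  mine <- spearman_cor(glm$wbc, glm$coating_CON)$statistic
  oracle <- cor(rank(glm$wbc), rank(glm$coating_CON))
  expect_equal(mine, oracle, tolerance = 1e-12)
  expect_lt(abs(mine - (-0.32)), 0.05)
  # markers still live inside the printed envelope after the copula transform
  p <- default_marker_params()$wbc$GLM
  expect_true(all(glm$wbc >= p$range[1] & glm$wbc <= p$range[2]))
})

test_that("generation is deterministic and validates probability vectors", {
  spec <- cohort_spec(n_glm = 50, n_control = 50, seed = 9)
  expect_identical(generate_cohort(spec), generate_cohort(spec))
  expect_error(cohort_spec(category_probs = list(
    coating_color = list(GLM = c(none = 0.5, white = 0.2, yellow = 0.2),
                         control = c(none = 0.7, white = 0.175, yellow = 0.125)))),
    "sum to 1")
  expect_error(cohort_spec(category_probs = list(
    coating_greasy = list(GLM = 1.2, control = 0.1))), "\\[0, 1\\]")
})

test_that("cohort CSV round trip preserves the table; schema errors name columns", {
  rec <- generate_cohort(cohort_spec(n_glm = 10, n_control = 10, seed = 3))
  path <- tempfile(fileext = ".csv")
  write_cohort_csv(rec, path)
  back <- read_cohort_csv(path)
  expect_equal(back$coating_greasy, rec$coating_greasy)
  expect_equal(back$wbc, rec$wbc, tolerance = 1e-12)
  bad <- rec[, setdiff(names(rec), "wbc")]
  path2 <- tempfile(fileext = ".csv")
  utils::write.csv(bad, path2, row.names = FALSE)
  expect_error(read_cohort_csv(path2), "wbc")
})
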