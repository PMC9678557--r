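test_that("constant region gives the degenerate histogram", {
  px <- array(42, dim = c(16, 16, 3))
  img <- tongue_image(px)
  prof <- texture_features(gray_difference_histogram(img, matrix(TRUE, 16, 16)))
  expect_equal(prof$hg[1], 1)
  expect_equal(sum(prof$hg), 1)
  expect_equal(prof$MEAN, 0)
  expect_equal(prof$CON, 0)
  expect_equal(prof$ASM, 1)
  expect_equal(prof$ENT, 0)
})

test_that("hand-enumerated 1x3 gray row [10, 20, 10] at offset (0,1)", {
  fx <- gray_row_image(c(10, 20, 10))
  prof <- gray_difference_histogram(fx$image, fx$mask, delta = c(0L, 1L))
  # two pairs: (10,20) and (20,10) -> |g| = 10 for both
  expect_equal(prof$n_pairs, 2L)
  expect_equal(prof$hg[11], 1)
  expect_equal(sum(prof$hg), 1)
  done <- texture_features(prof)
  expect_equal(done$MEAN, 10 / 256)
  expect_equal(done$CON, 100)
  expect_equal(done$ASM, 1)
  expect_equal(done$ENT, 0)
})

test_that("period-2 vertical stripes of 0/255 concentrate hg at 255", {
  px <- array(0, dim = c(16, 16, 3))
  px[, seq(2, 16, by = 2), ] <- 255
  img <- tongue_image(px)
  prof <- gray_difference_histogram(img, matrix(TRUE, 16, 16), delta = c(0L, 1L))
  expect_equal(prof$hg[256], 1)
})

test_that("texture statistics evaluate closed-form histograms", {
  base <- gray_difference_histogram(tongue_image(array(0, c(16, 16, 3))),
                                    matrix(TRUE, 16, 16))
  # uniform over difference values {0, 1, 2, 3}
  base$hg <- c(rep(0.25, 4), rep(0, 252))
  u <- texture_features(base)
  expect_equal(u$MEAN, (0 + 1 + 2 + 3) / (4 * 256))
  expect_equal(u$CON, 3.5)
  expect_equal(u$ASM, 0.25)
  expect_equal(u$ENT, 2)
  # single occupied bin at 5
  base$hg <- c(rep(0, 5), 1, rep(0, 250))
  s <- texture_features(base)
  expect_equal(s$MEAN, 5 / 256)
  expect_equal(s$CON, 25)
  expect_equal(s$ASM, 1)
  expect_equal(s$ENT, 0)
})

test_that("unnormalised histograms are rejected", {
  prof <- gray_difference_histogram(tongue_image(array(0, c(16, 16, 3))),
                                    matrix(TRUE, 16, 16))
  prof$hg <- prof$hg * 2
  expect_error(texture_features(prof), "normalised")
})

test_that("main path matches the brute-force oracle on random masked images", {
  set.seed(101)
  deltas <- list(c(1L, 1L), c(0L, 1L), c(1L, 0L), c(1L, -1L))
  for (i in 1:25) {
    delta <- deltas[[(i %% 4) + 1]]
    img <- random_test_image()
    mask <- random_mask_with_pairs(delta = delta)
    main <- texture_features(gray_difference_histogram(img, mask, delta = delta))
    oracle <- texture_oracle(img, mask, delta = delta)
    expect_equal(main$hg, oracle$hg, tolerance = 1e-14)
    expect_equal(main$n_pairs, oracle$n_pairs)
    expect_equal(main$MEAN, oracle$MEAN, tolerance = 1e-12)
    expect_equal(main$CON, oracle$CON, tolerance = 1e-12)
    expect_equal(main$ASM, oracle$ASM, tolerance = 1e-12)
    expect_equal(main$ENT, oracle$ENT, tolerance = 1e-12)
  }
})

test_that("pooling the four standard offsets matches the oracle pair set", {
  set.seed(55)
  offsets <- rbind(c(0, 1), c(1, 0), c(1, 1), c(1, -1))
  img <- random_test_image()
  mask <- random_mask_with_pairs()
  main <- texture_features(gray_difference_histogram(img, mask, delta = offsets))
  oracle <- texture_oracle(img, mask, delta = offsets)
  expect_equal(main$hg, oracle$hg, tolerance = 1e-14)
  expect_equal(main$n_pairs, oracle$n_pairs)
})

test_that("hg sums to one and is shift-invariant", {
  set.seed(17)
  for (i in 1:10) {
    img <- random_test_image()
    mask <- random_mask_with_pairs()
    prof <- gray_difference_histogram(img, mask)
    expect_equal(sum(prof$hg), 1, tolerance = 1e-12)
    # add a constant without clipping: differences unchanged (a gray image
    # keeps the luma on the integer grid, so rounding cannot interfere)
    gray <- matrix(sample(0:180, 256, replace = TRUE), 16, 16)
    base <- tongue_image(array(rep(gray, 3), dim = c(16, 16, 3)))
    p1 <- gray_difference_histogram(base, mask)
    bumped <- tongue_image(unclass(base) + 37)
    p2 <- gray_difference_histogram(bumped, mask)
    expect_equal(p1$hg, p2$hg)
  }
})

test_that("entropy and ASM respect occupancy bounds; CON grows under spread", {
  set.seed(23)
  for (i in 1:10) {
    img <- random_test_image()
    mask <- random_mask_with_pairs()
    prof <- texture_features(gray_difference_histogram(img, mask))
    k <- sum(prof$hg > 0)
    expect_gte(prof$ASM, 1 / k - 1e-12)
    expect_lte(prof$ENT, log2(k) + 1e-12)
    expect_true(prof$ASM > 0 && prof$ASM <= 1)
    expect_gte(prof$CON, 0)
  }
  # mean-preserving spread: mass at {4} vs spread to {2, 6}
  base <- gray_difference_histogram(tongue_image(array(0, c(16, 16, 3))),
                                    matrix(TRUE, 16, 16))
  concentrated <- base; concentrated$hg <- replace(rep(0, 256), 5, 1)
  spread <- base; spread$hg <- replace(rep(0, 256), c(3, 7), 0.5)
  expect_gt(texture_features(spread)$CON, texture_features(concentrated)$CON)
})

test_that("degenerate regions raise an error", {
  img <- random_test_image()
  mask <- matrix(FALSE, 16, 16); mask[1, 1] <- TRUE
  expect_error(gray_difference_histogram(img, mask, delta = c(1L, 1L)), "degenerate")
})
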