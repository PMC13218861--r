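test_that("confusion counts partition the samples", {
  cc <- confusion(c(1, 1, 0), c(1, 1, 0))
  expect_equal(c(cc$TP, cc$TN, cc$FP, cc$FN), c(2, 1, 0, 0))
  cc2 <- confusion(c(1, 0, 1), c(0, 1, 0))
  expect_equal(cc2$TP + cc2$TN, 0)
  for (i in 1:20) {
    n <- 5 + i
    p <- slicemapr:::with_seed(i, rbinom(n, 1, 0.4))
    t <- slicemapr:::with_seed(i + 100, rbinom(n, 1, 0.6))
    cc <- confusion(p, t)
    expect_equal(cc$TP + cc$FP + cc$TN + cc$FN, n)
  }
  expect_error(confusion(c(1, 0), c(1)), "lengths differ")
  expect_error(confusion(c(2, 0), c(1, 0)), "binary")
})

test_that("mcc matches hand-computed and degenerate cases", {
  expect_equal(mcc(structure(list(TP = 50, TN = 50, FP = 0, FN = 0),
                             class = "confusion_counts")), 1.0)
  expect_equal(mcc(structure(list(TP = 25, TN = 25, FP = 25, FN = 25),
                             class = "confusion_counts")), 0.0)
  # TP=90 FN=10 TN=80 FP=20: (90*80-20*10)/sqrt(110*100*100*90)
  cc <- structure(list(TP = 90, FN = 10, TN = 80, FP = 20),
                  class = "confusion_counts")
  expect_equal(mcc(cc), 0.70353, tolerance = 1e-4)
  expect_equal(accuracy(cc), 0.85)
  expect_equal(precision(cc), 90 / 110)
  # zero-denominator convention
  expect_equal(mcc(structure(list(TP = 5, FP = 0, TN = 0, FN = 0),
                             class = "confusion_counts")), 0)
  expect_true(is.na(precision(structure(list(TP = 0, FP = 0, TN = 3, FN = 2),
                                        class = "confusion_counts"))))
})

test_that("mcc equals the Pearson correlation of the label vectors", {
  # property: 1000 random confusion tables, equality to 1e-12
  set.seed(7)
  for (i in 1:1000) {
    k <- sample(0:20, 4, replace = TRUE)
    if (sum(k) < 2) next
    truth <- c(rep(1, k[1]), rep(0, k[2]), rep(0, k[3]), rep(1, k[4]))
    pred <- c(rep(1, k[1]), rep(1, k[2]), rep(0, k[3]), rep(0, k[4]))
    cc <- confusion(pred, truth)
    r <- suppressWarnings(cor(pred, truth))
    expect_equal(mcc(cc), if (is.na(r)) 0 else r, tolerance = 1e-12)
  }
})

test_that("dual_threshold retains, flags and never crashes", {
  probs <- c(0.99, 0.98, 0.02, 0.01); labels <- c(1, 1, 0, 0)
  row <- dual_threshold(probs, labels, cbind(0.05, 0.95))
  expect_equal(row$retained_fraction, 1)
  expect_equal(row$mcc, 1)
  row2 <- dual_threshold(probs, labels, cbind(0.5, 0.5))
  expect_equal(row2$retained_fraction, 1)     # every sample classified
  row3 <- dual_threshold(rep(0.6, 5), c(1, 0, 1, 0, 1), cbind(0.05, 0.95))
  expect_equal(row3$n_retained, 0)
  expect_true(is.na(row3$mcc))
  expect_error(dual_threshold(probs, labels, cbind(0.9, 0.1)), "exceeds")
  # retention is non-increasing as the pair tightens toward (0, 1)
  set.seed(21)
  for (rep in 1:10) {
    p <- runif(60); y <- rbinom(60, 1, 0.5)
    curve <- dual_threshold(p, y)
    expect_true(all(diff(curve$retained_fraction) <= 1e-12))
  }
})

test_that("two_sample_ttest handles degenerate and separated samples", {
  a <- c(0.5, 0.6, 0.55)
  r <- two_sample_ttest(a, a)
  expect_equal(r$t, 0)
  expect_equal(r$p, 1)
  set.seed(3)
  x <- rnorm(10, 0.6, 0.01); y <- rnorm(10, 0.0, 0.01)
  expect_lt(two_sample_ttest(x, y)$p, 1e-10)
  expect_error(two_sample_ttest(1, 2), "at least 2")
})

test_that("energy distance: closed form, power, and input checks", {
  # univariate point masses at a and b: statistic is exactly 2|a - b|
  r <- energy_distance_test(rep(2, 5), rep(5.5, 5), n_permutations = 19)
  expect_equal(r$statistic, 2 * 3.5)
  set.seed(9)
  r2 <- energy_distance_test(rnorm(50, 0), rnorm(50, 2), n_permutations = 999,
                             seed = 4)
  expect_lte(r2$p, 0.005)
  expect_error(energy_distance_test(matrix(1:6, 2), matrix(1:8, 2)),
               "different lengths")
  # null behavior: same distribution, p rarely small
  rejections <- 0
  for (i in 1:40) {
    z <- slicemapr:::with_seed(1000 + i, matrix(rnorm(60 * 3), 60))
    r3 <- energy_distance_test(z[1:30, ], z[31:60, ], n_permutations = 199,
                               seed = i)
    rejections <- rejections + (r3$p <= 0.05)
  }
  expect_lte(rejections / 40, 0.10)
})

test_that("pearson_r matches hand computation and flags zero variance", {
  expect_equal(pearson_r(1:10, 2 * (1:10) + 1)$r, 1.0)
  expect_equal(pearson_r(1:10, -(1:10))$r, -1.0)
  expect_equal(pearson_r(c(1, 2, 3, 4), c(1, 3, 2, 4))$r, 0.8)
  expect_true(is.na(pearson_r(c(1, 1, 1), c(1, 2, 3))$r))
  expect_error(pearson_r(1:2, 1:2), ">= 3")
})
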