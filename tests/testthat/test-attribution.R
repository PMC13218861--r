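test_that("neutral_reference picks the logit closest to zero, ties low", {
  imgs <- array(seq_len(3 * 4 * 3), c(3, 4, 3))
  nr <- neutral_reference(NULL, imgs, logits = c(-2.0, 0.1, 3.0))
  expect_equal(nr$index, 2)
  nr2 <- neutral_reference(NULL, imgs[, , 1:2], logits = c(-0.1, 0.1))
  expect_equal(nr2$index, 1)
  nr3 <- neutral_reference(NULL, imgs[, , 1, drop = FALSE], logits = 0.7)
  expect_equal(nr3$index, 1)
  expect_equal(nr3$image, imgs[, , 1])
  expect_error(neutral_reference(NULL, array(0, c(3, 4, 0))), "empty")
})

test_that("occlusion scores match the brute-force oracle", {
  cfg <- occlusion_config(window = 5L, stride = 3L)
  img <- slicemapr:::with_seed(1, matrix(rnorm(32 * 32), 32))
  neu <- slicemapr:::with_seed(2, matrix(rnorm(32 * 32), 32))
  # linear pixel-sum model
  f_lin <- function(batch) apply(batch, 3, sum)
  got <- occlusion_scores(f_lin, img, neu, cfg)
  want <- brute_occlusion(f_lin, img, neu, cfg$window, cfg$stride)
  expect_equal(got, want, tolerance = 1e-9)
  # constant model: identically zero map
  f_const <- function(batch) rep(1.23, dim(batch)[3])
  expect_equal(occlusion_scores(f_const, img, neu, cfg), matrix(0, 32, 32))
  # a real (untrained) CNN against the same oracle
  m <- build_cnn2d(c(32, 32), seed = 3)
  f_cnn <- function(batch) predict_logits(m, batch)
  expect_equal(occlusion_scores(f_cnn, img, neu, cfg),
               brute_occlusion(f_cnn, img, neu, cfg$window, cfg$stride),
               tolerance = 1e-5)
  expect_error(occlusion_scores(f_lin, img, neu[1:16, 1:16], cfg), "shape")
})

test_that("coverage counts follow the window/stride geometry", {
  # 64x64, window 15, stride 5: pixel (30, 30) covered by offsets {20,25,30}
  # per axis -> 9 patches
  starts <- slicemapr:::occlusion_starts(64L, 15L, 5L)
  covering <- function(p) sum(starts <= p & starts + 14L >= p)
  expect_equal(covering(30L) * covering(30L), 9)
  # every pixel is covered at least once (flush-to-border position)
  expect_true(all(vapply(0:63, covering, numeric(1)) >= 1))
})

test_that("sign adjustment and subject thresholds follow the conventions", {
  raw <- matrix(c(-0.7, 0.2, 0.5, -0.1), 2)
  expect_identical(sign_adjust(raw, 1L), raw)
  expect_identical(sign_adjust(raw, 0L), -raw)
  expect_identical(sign_adjust(matrix(0, 2, 2), 0L), matrix(0, 2, 2))
  # 400 distinct values: exactly 20 pixels at or above the 5% threshold
  g <- matrix(slicemapr:::with_seed(4, sample(1:400)), 20)
  th <- subject_threshold(g, 0.05)
  expect_equal(sum(th$indicator), 20)
  expect_equal(th$tau, 381)
  # constant grid: ties retain everything
  thc <- subject_threshold(matrix(2, 5, 5))
  expect_equal(sum(thc$indicator), 25)
  # tie rule implies at least ceil(0.05 * P) retained
  for (i in 1:10) {
    g2 <- matrix(slicemapr:::with_seed(i, sample(1:8, 64, TRUE)), 8)
    expect_gte(sum(subject_threshold(g2)$indicator), ceiling(0.05 * 64))
  }
})

test_that("frequency maps aggregate indicators and stay in [0, 1]", {
  i1 <- matrix(c(1, 0, 0, 0), 2); i2 <- matrix(c(0, 0, 0, 1), 2)
  fm1 <- frequency_map(list(i1), sigma = 0)
  expect_equal(fm1$values, i1)
  fm2 <- frequency_map(list(i1, i2), sigma = 0)
  expect_true(all(fm2$values %in% c(0, 0.5)))
  ones <- matrix(1, 6, 6)
  fm3 <- frequency_map(list(ones, ones, ones), sigma = 1)
  expect_equal(fm3$values, ones)
  expect_equal(fm3$smoothed, ones, tolerance = 1e-9)  # smoothing of constant
  expect_true(all(fm3$values >= 0 & fm3$values <= 1))
  expect_error(frequency_map(list(i1, matrix(0, 3, 3))), "share a shape")
})

test_that("label swap with logit negation leaves the frequency map unchanged", {
  set.seed(6)
  raws <- lapply(1:8, function(i) matrix(rnorm(100), 10))
  labels <- rep(c(1L, 0L), 4)
  ind <- function(r, l) subject_threshold(sign_adjust(r, l))$indicator
  f1 <- frequency_map(mapply(ind, raws, labels, SIMPLIFY = FALSE))
  # negating all logits negates every raw map; swapping labels then yields
  # identical adjusted maps
  f2 <- frequency_map(mapply(ind, lapply(raws, function(r) -r), 1L - labels,
                             SIMPLIFY = FALSE))
  expect_identical(f1$values, f2$values)
})

test_that("slice occlusion summary is the mean of per-subject maxima", {
  a <- matrix(c(0.1, 0.9, 0, 0.2), 2)
  expect_equal(slice_occlusion_summary(list(a)), 0.9)
  expect_equal(slice_occlusion_summary(list(matrix(0, 2, 2), matrix(0, 2, 2))), 0)
  b <- matrix(c(0.5, 0, 0, 0), 2)
  expect_equal(slice_occlusion_summary(list(a, b)),
               slice_occlusion_summary(list(b, a)))
})

test_that("gaussian smoothing preserves mass and symmetry", {
  imp <- matrix(0, 11, 11); imp[6, 6] <- 1
  sm <- gaussian_smooth(imp, 1.0)
  expect_equal(sum(sm), 1, tolerance = 1e-9)
  expect_equal(sm, sm[11:1, ], tolerance = 1e-12)
  expect_equal(sm, t(sm), tolerance = 1e-12)
  expect_gt(sm[6, 6], sm[5, 6])
})
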