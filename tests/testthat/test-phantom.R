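test_that("phantom_spec validates its stated world", {
  expect_error(phantom_spec(volume_shape = c(0, 64, 64)), "positive")
  expect_error(phantom_spec(n_subjects = 1), ">= 2")
  expect_error(phantom_spec(class_balance = 1.2), "\\(0, 1\\)")
  expect_error(phantom_spec(n_subjects = 3, class_balance = 0.01), "empty")
  expect_error(phantom_spec(noise_sd = 0), "positive")
})

test_that("cohort generation is seed-deterministic with both classes", {
  spec <- phantom_spec(c(20, 20, 20), n_subjects = 6, seed = 9)
  a <- generate_cohort(spec)
  b <- generate_cohort(spec)
  for (i in seq_along(a)) expect_identical(a[[i]]$voxels, b[[i]]$voxels)
  expect_setequal(unique(cohort_labels(a)), c(0L, 1L))
  # different seed, different cohort
  c2 <- generate_cohort(phantom_spec(c(20, 20, 20), n_subjects = 6, seed = 10))
  expect_false(identical(a[[1]]$voxels, c2[[1]]$voxels))
  # ellipsoidal foreground on zero background
  expect_true(any(a[[1]]$voxels == 0))
  expect_true(all(a[[1]]$voxels[1, 1, 1] == 0))
})

test_that("injection replaces only target-class voxels inside the region", {
  co <- tiny_cohort(n = 4, shape = 20)
  box <- region_box(c(6, 6, 6), c(11, 11, 11))
  inj <- injection_spec(box, target_class = 0L, seed = 3)
  out <- inject_signal(co, inj)
  idx <- 7:12
  for (i in seq_along(co)) {
    d <- out[[i]]$voxels - co[[i]]$voxels
    if (co[[i]]$label == 0L) {
      expect_true(all(d[idx, idx, idx] != 0))
      d[idx, idx, idx] <- 0
      expect_true(all(d == 0))            # L0 locality
    } else {
      expect_identical(out[[i]]$voxels, co[[i]]$voxels)
    }
  }
  # determinism of the injection stream
  out2 <- inject_signal(co, inj)
  for (i in seq_along(co)) expect_identical(out[[i]]$voxels, out2[[i]]$voxels)
  # out-of-bounds region
  expect_error(inject_signal(co, injection_spec(region_box(c(15, 0, 0), c(22, 5, 5)))),
               "outside the volume")
})

test_that("replacement draws follow N(mean_multiplier * v, sd)", {
  # constant-valued volume: every replacement draw has mean 2 * 3 = 6, sd 1
  shape <- c(22, 22, 22)
  v <- labeled_volume(array(3, shape), "s1", 0L)
  co <- structure(list(v), class = "volume_cohort")
  box <- region_box(c(0, 0, 0), shape - 1L)
  out <- inject_signal(co, injection_spec(box, target_class = 0L, seed = 5))
  draws <- as.vector(out[[1]]$voxels)      # 10,648 draws
  expect_lt(abs(mean(draws) - 6.0), 0.05)
  expect_lt(abs(sd(draws) - 1.0), 0.05)
})

test_that("normalize_intensity z-scores the foreground only", {
  v <- array(0, c(3, 3, 3))
  v[1, 1, 1:3] <- c(1, 2, 3)
  n <- normalize_intensity(v)
  expect_equal(n[1, 1, 1:3], c(-1, 0, 1) * sqrt(3 / 2), tolerance = 1e-9)
  expect_true(all(n[-1, , ] == 0))
  # idempotence (random foreground: no value lands exactly on zero)
  w <- array(0, c(4, 4, 4))
  w[2:3, 2:3, 2:3] <- slicemapr:::with_seed(3, rnorm(8, 5, 1))
  w1 <- normalize_intensity(w)
  expect_equal(normalize_intensity(w1), w1, tolerance = 1e-9)
  expect_error(normalize_intensity(array(0, c(2, 2, 2))), "all-zero")
  const <- array(0, c(2, 2, 2)); const[1, 1, 1:2] <- 5
  expect_error(normalize_intensity(const), "constant foreground")
})

test_that("injection is detectable by the energy test, null is quiet", {
  spec <- phantom_spec(c(24, 24, 24), n_subjects = 100,
                       diffuse_effect_size = 0, seed = 21)
  co <- normalize_cohort(generate_cohort(spec))
  box <- region_box(c(9, 9, 9), c(14, 14, 14))
  labels <- cohort_labels(co)
  vecs <- function(cc) t(vapply(cc, function(v)
    as.vector(v$voxels[10:15, 10:15, 10:15]), numeric(216)))
  before <- vecs(co)
  r0 <- energy_distance_test(before[labels == 1, ], before[labels == 0, ],
                             n_permutations = 199, seed = 1)
  expect_gt(r0$p, 0.05)
  after <- vecs(inject_signal(co, injection_spec(box, seed = 2)))
  r1 <- energy_distance_test(after[labels == 1, ], after[labels == 0, ],
                             n_permutations = 199, seed = 1)
  expect_lt(r1$p, 0.05)
})
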