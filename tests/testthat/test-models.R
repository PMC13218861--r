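test_that("architecture geometry and validation match the contract", {
  # 64x64 -> 32 -> 16 -> 8 after three poolings: flattened dim = 32 * 8 * 8
  m <- build_cnn2d(c(64, 64), seed = 1)
  expect_equal(dim(m$params$head$W1), c(128L, 32L * 8L * 8L))
  expect_error(build_cnn2d(c(4, 4)), "collapses")
  # 24^3 -> 12 -> 6 -> 3: flattened dim = 32 * 27
  m3 <- build_cnn3d_patch()
  expect_equal(dim(m3$params$head$W1), c(128L, 32L * 27L))
  expect_error(build_cnn3d_patch(c(12, 24, 24)), "at least 16")
  m3b <- build_cnn3d_patch(c(16, 20, 24))   # non-cubic but all sides >= 16
  expect_equal(m3b$kind, "3d")
  expect_error(build_fusion(list(c(16, 16), c(16, 16))), "exactly 3")
  expect_error(cnn2d_spec(channels = c(8, 8, 16)), "increasing")
  expect_error(train_config(max_epochs = 0), ">= 1")
})

test_that("initialization and forward passes are seed-deterministic", {
  a <- build_cnn2d(c(16, 16), seed = 7)
  b <- build_cnn2d(c(16, 16), seed = 7)
  expect_identical(a$params, b$params)
  c_ <- build_cnn2d(c(16, 16), seed = 8)
  expect_false(identical(a$params$trunks[[1]][[1]]$W,
                         c_$params$trunks[[1]][[1]]$W))
  x <- slicemapr:::with_seed(1, array(rnorm(16 * 16 * 5), c(16, 16, 5)))
  expect_length(predict_logits(a, x), 5)
  expect_identical(predict_logits(a, x), predict_logits(b, x))
})

test_that("training separates a separable task and checkpoints by val loss", {
  d <- make_blob_data(n = 160, H = 16, effect = 3, seed = 2)
  mccs <- vapply(1:2, function(s) {
    res <- train_model(d$x[, , d$tr], d$y[d$tr], d$x[, , d$va], d$y[d$va],
                       d$x[, , d$te], d$y[d$te], cfg = tiny_cfg(), seed = s)
    expect_equal(res$best_epoch, which.min(res$val_loss))
    slicemapr:::prediction_metrics(res$test)$mcc
  }, numeric(1))
  expect_true(all(mccs >= 0.95))
})

test_that("label shuffling destroys the signal", {
  d <- make_blob_data(n = 240, H = 16, effect = 3, seed = 4)
  mccs <- vapply(1:5, function(s) {
    y_perm <- slicemapr:::with_seed(100 + s, sample(d$y))
    res <- train_model(d$x[, , d$tr], y_perm[d$tr], d$x[, , d$va], y_perm[d$va],
                       d$x[, , d$te], y_perm[d$te], cfg = tiny_cfg(), seed = s)
    slicemapr:::prediction_metrics(res$test)$mcc
  }, numeric(1))
  expect_lte(abs(mean(mccs)), 0.15)
})

test_that("training is deterministic and guards its preconditions", {
  d <- make_blob_data(n = 80, H = 16, effect = 2, seed = 5)
  run <- function() train_model(d$x[, , d$tr], d$y[d$tr], d$x[, , d$va],
                                d$y[d$va], d$x[, , d$te], d$y[d$te],
                                cfg = tiny_cfg(max_epochs = 5L), seed = 11)
  r1 <- run(); r2 <- run()
  expect_identical(r1$test$logit, r2$test$logit)
  expect_identical(r1$model$params, r2$model$params)
  expect_error(train_model(d$x[, , 1:4], rep(1, 4), d$x[, , d$va], d$y[d$va],
                           cfg = tiny_cfg()), "single class")
})

test_that("the test set never influences training (no leakage)", {
  d <- make_blob_data(n = 80, H = 16, effect = 2, seed = 9)
  with_test <- train_model(d$x[, , d$tr], d$y[d$tr], d$x[, , d$va], d$y[d$va],
                           d$x[, , d$te], d$y[d$te],
                           cfg = tiny_cfg(max_epochs = 5L), seed = 4)
  without <- train_model(d$x[, , d$tr], d$y[d$tr], d$x[, , d$va], d$y[d$va],
                         x_test = NULL, cfg = tiny_cfg(max_epochs = 5L), seed = 4)
  expect_identical(with_test$model$params, without$model$params)
})

test_that("fusion model fuses three trunks into one logit", {
  d1 <- make_blob_data(n = 80, H = 16, effect = 3, seed = 6)
  x3 <- list(d1$x, d1$x * 0.5, d1$x)   # three correlated views
  tr <- lapply(x3, function(a) a[, , d1$tr])
  va <- lapply(x3, function(a) a[, , d1$va])
  te <- lapply(x3, function(a) a[, , d1$te])
  res <- train_model(tr, d1$y[d1$tr], va, d1$y[d1$va], te, d1$y[d1$te],
                     cfg = tiny_cfg(), seed = 2)
  expect_equal(nrow(res$test), length(d1$te))
  expect_gte(slicemapr:::prediction_metrics(res$test)$mcc, 0.9)
  # fusion dominance: with the signal visible in every view, fusion is not
  # worse than a single-view model beyond noise
  single <- train_model(d1$x[, , d1$tr], d1$y[d1$tr], d1$x[, , d1$va],
                        d1$y[d1$va], d1$x[, , d1$te], d1$y[d1$te],
                        cfg = tiny_cfg(), seed = 2)
  expect_gte(slicemapr:::prediction_metrics(res$test)$mcc,
             slicemapr:::prediction_metrics(single$test)$mcc - 0.05)
  # all-zero inputs: logits constant, |MCC| small
  z <- lapply(1:3, function(i) array(0, c(16, 16, 40)))
  yz <- rep(c(0L, 1L), 20)
  rz <- train_model(z, yz, lapply(z, function(a) a[, , 1:10]), yz[1:10],
                    z, yz, cfg = tiny_cfg(max_epochs = 3L), seed = 3)
  expect_lt(diff(range(rz$test$logit)), 1e-5)
  expect_lte(abs(slicemapr:::prediction_metrics(rz$test)$mcc), 0.15)
})

test_that("hyperparameter search ranks configurations by mean MCC", {
  expect_error(run_hyperparameter_search(data.frame(), 1, 1, 1, 1, 1, 1), "empty")
  g <- default_hyper_grid()
  expect_setequal(unique(g$weight_decay), c(0.1, 0.01, 0.001))
  expect_setequal(unique(g$scheduler_step), c(5L, 10L, 15L, 0L))
  expect_setequal(unique(g$use_batch_norm), c(TRUE, FALSE))
  expect_equal(nrow(g), 24)
  d <- make_blob_data(n = 80, H = 16, effect = 3, seed = 8)
  out <- run_hyperparameter_search(
    data.frame(weight_decay = c(0.1, 0.1), scheduler_step = c(10L, 0L),
               use_batch_norm = c(TRUE, FALSE)),
    d$x[, , d$tr], d$y[d$tr], d$x[, , d$va], d$y[d$va],
    d$x[, , d$te], d$y[d$te], cfg = tiny_cfg(max_epochs = 6L), n_repeats = 2)
  expect_equal(nrow(out$table), 2)
  expect_true(all(diff(out$table$mean_mcc) <= 0))
  expect_equal(out$best$mean_mcc, max(out$table$mean_mcc))
  # single-config grid returns that config with its mean/sd
  out1 <- run_hyperparameter_search(
    data.frame(weight_decay = 0.1, scheduler_step = 10L, use_batch_norm = TRUE),
    d$x[, , d$tr], d$y[d$tr], d$x[, , d$va], d$y[d$va],
    d$x[, , d$te], d$y[d$te], cfg = tiny_cfg(max_epochs = 4L), n_repeats = 2)
  expect_equal(nrow(out1$table), 1)
  expect_false(is.na(out1$table$sd_mcc))
})
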