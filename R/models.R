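#' 2D slice-classifier architecture specification
#'
#' Three convolutional blocks (3x3 kernels, "same" padding, channels
#' 8/16/32), each followed by optional batch normalization, ReLU and 2x2
#' max-pooling with stride 2; then a 128-unit fully connected layer with
#' layer normalization, ReLU and dropout, and a final linear layer giving a
#' single logit.
#'
#' @param use_batch_norm Include batch normalization after each convolution.
#' @param channels Feature-map counts per block (strictly increasing).
#' @param fc_hidden Hidden units of the fully connected layer.
#' @param dropout_rate Dropout rate in [0, 1).
#' @return An object of class `cnn_spec`.
#' @export
cnn2d_spec <- function(use_batch_norm = TRUE, channels = c(8L, 16L, 32L),
                       fc_hidden = 128L, dropout_rate = 0.5) {
  if (any(diff(channels) <= 0)) stop_param("channels must be strictly increasing")
  if (dropout_rate < 0 || dropout_rate >= 1) stop_param("dropout_rate must be in [0, 1)")
  structure(list(use_batch_norm = isTRUE(use_batch_norm),
                 channels = as.integer(channels),
                 fc_hidden = as.integer(fc_hidden),
                 dropout_rate = dropout_rate),
            class = "cnn_spec")
}

# assemble the C++ net spec; dims is a list of per-trunk spatial extents
net_spec_cpp <- function(dims, spec) {
  n_pool <- length(spec$channels)
  for (d in dims) {
    if (any(floor(d / 2^n_pool) < 1))
      stop_param("input of shape ", paste(d, collapse = "x"),
                 " collapses below 1x1 after ", n_pool, " poolings")
    if (length(d) == 3L && any(d < 16L))
      stop_param("3D patches must be at least 16 voxels per side")
  }
  list(dims = lapply(dims, as.integer), use_bn = spec$use_batch_norm,
       channels = spec$channels, fc_hidden = spec$fc_hidden,
       dropout = spec$dropout_rate)
}

#' Build an untrained slice classifier
#'
#' @param input_shape 2D image shape (both sides must survive three 2x
#'   poolings, i.e. be at least 8).
#' @param spec A [cnn2d_spec()].
#' @param seed Initialization seed; identical seeds give identical
#'   initial parameters.
#' @return An object of class `slicemap_model` (net spec + parameters).
#' @export
build_cnn2d <- function(input_shape, spec = cnn2d_spec(), seed = 1L) {
  ns <- net_spec_cpp(list(input_shape), spec)
  structure(list(net_spec = ns, params = cpp_init_params(ns, as.integer(seed)),
                 kind = "2d"), class = "slicemap_model")
}

#' Build an untrained lightweight 3D patch classifier
#'
#' The 3D analogue of the slice model: 3x3x3 kernels, channels 8/16/32,
#' 2x2x2 pooling, identical dense head.
#'
#' @param input_shape Patch shape, all sides at least 16 (default 24^3).
#' @param spec A [cnn2d_spec()] (reused for the 3D trunk).
#' @param seed Initialization seed.
#' @return A `slicemap_model`.
#' @export
build_cnn3d_patch <- function(input_shape = c(24L, 24L, 24L),
                              spec = cnn2d_spec(), seed = 1L) {
  if (length(input_shape) != 3L) stop_param("input_shape must be a 3D extent")
  ns <- net_spec_cpp(list(input_shape), spec)
  structure(list(net_spec = ns, params = cpp_init_params(ns, as.integer(seed)),
                 kind = "3d"), class = "slicemap_model")
}

#' Build an untrained three-slice fusion classifier
#'
#' Three parallel 2D convolutional trunks (shared architecture, unshared
#' weights), one per plane's best slice; their flattened features are
#' concatenated and fed to a shared dense head producing a single logit.
#'
#' @param input_shapes List of three 2D image shapes.
#' @param spec A [cnn2d_spec()].
#' @param seed Initialization seed.
#' @return A `slicemap_model`.
#' @export
build_fusion <- function(input_shapes, spec = cnn2d_spec(), seed = 1L) {
  if (length(input_shapes) != 3L) stop_param("fusion model needs exactly 3 inputs")
  ns <- net_spec_cpp(input_shapes, spec)
  structure(list(net_spec = ns, params = cpp_init_params(ns, as.integer(seed)),
                 kind = "fusion"), class = "slicemap_model")
}

#' Predict logits with a (trained or untrained) model
#'
#' @param model A `slicemap_model`.
#' @param images For 2D/3D models an array whose last dimension indexes
#'   samples (a single image/patch is promoted to a batch of 1); for fusion
#'   a list of three such arrays.
#' @return Numeric vector of logits, one per sample.
#' @export
predict_logits <- function(model, images) {
  stopifnot(inherits(model, "slicemap_model"))
  xs <- if (model$kind == "fusion") images else list(images)
  xs <- lapply(seq_along(xs), function(t) {
    x <- xs[[t]]
    want <- length(model$net_spec$dims[[t]])
    if (length(dim(x)) == want || is.null(dim(x)) && want == 1)
      dim(x) <- c(dim(x), 1L)
    if (length(dim(x)) != want + 1L)
      stop_param("input rank does not match the model")
    x
  })
  cpp_predict(model$params, xs, model$net_spec)
}

#' Training configuration
#'
#' Defaults follow the reference training recipe: AdamW with decoupled
#' weight decay 0.1, initial learning rate 5e-5, batch size 64, binary
#' cross-entropy on logits, StepLR halving every 10 epochs, up to 200
#' epochs with per-epoch checkpoints, evaluation at the checkpoint of
#' lowest validation loss, 10 repeats. See [desk_train_config()] for the
#' scaled-down profile used in tests and examples.
#'
#' @param lr Initial learning rate (> 0).
#' @param batch_size Minibatch size.
#' @param max_epochs Maximum training epochs (>= 1).
#' @param weight_decay Decoupled weight decay (grid values 0.1/0.01/0.001).
#' @param scheduler_step StepLR period in epochs; 0 disables scheduling.
#' @param scheduler_gamma StepLR decay factor.
#' @param patience Early-stop patience in epochs without validation
#'   improvement; 0 disables early stopping.
#' @param val_loss_floor Stop once the best validation loss falls below this
#'   value (the classes are then essentially separated and further epochs
#'   cannot change the selected checkpoint's test behavior); 0 disables.
#' @param n_repeats Default number of repeated runs (different seeds).
#' @param seed Base seed.
#' @return An object of class `train_config`.
#' @export
train_config <- function(lr = 5e-5, batch_size = 64L, max_epochs = 200L,
                         weight_decay = 0.1, scheduler_step = 10L,
                         scheduler_gamma = 0.5, patience = 0L,
                         val_loss_floor = 0, n_repeats = 10L, seed = 1L) {
  if (lr <= 0) stop_param("lr must be positive")
  if (max_epochs < 1L) stop_param("max_epochs must be >= 1")
  if (batch_size < 1L) stop_param("batch_size must be >= 1")
  structure(list(lr = lr, batch_size = as.integer(batch_size),
                 max_epochs = as.integer(max_epochs),
                 weight_decay = weight_decay,
                 scheduler_step = as.integer(scheduler_step),
                 scheduler_gamma = scheduler_gamma,
                 patience = as.integer(patience),
                 val_loss_floor = val_loss_floor,
                 n_repeats = as.integer(n_repeats), seed = as.integer(seed)),
            class = "train_config")
}

#' Desk-scale training configuration
#'
#' The reference learning rate (5e-5) is tuned for thousands of training
#' images over 200 epochs; at desk scale (a few hundred phantom subjects,
#' one CPU) that provides too few optimizer steps to converge within any
#' reasonable budget. This profile keeps the optimizer, batch size, weight
#' decay, scheduler and checkpoint rule, but raises the learning rate to
#' 1e-3 and caps epochs at 40 with early stopping (patience 12, validation
#' loss floor 0.02).
#'
#' @param ... Overrides passed to [train_config()].
#' @return A `train_config`.
#' @export
desk_train_config <- function(...) {
  args <- list(lr = 1e-3, max_epochs = 40L, patience = 12L,
               val_loss_floor = 0.02, n_repeats = 3L)
  args[names(list(...))] <- list(...)
  do.call(train_config, args)
}

cfg_cpp <- function(cfg) {
  list(lr = cfg$lr, batch_size = cfg$batch_size, max_epochs = cfg$max_epochs,
       weight_decay = cfg$weight_decay, step_size = cfg$scheduler_step,
       gamma = cfg$scheduler_gamma, patience = cfg$patience,
       val_loss_floor = if (is.null(cfg$val_loss_floor)) 0 else cfg$val_loss_floor)
}

as_batch <- function(x, kind) {
  xs <- if (kind == "fusion") x else list(x)
  lapply(xs, function(a) { stopifnot(!is.null(dim(a))); a })
}

#' Train a classifier
#'
#' Trains with AdamW + BCE-with-logits, saving a checkpoint every epoch and
#' returning the model at the epoch of minimum validation loss; the test
#' inputs are only ever touched by the final evaluation.
#'
#' @param x_train,x_val,x_test Sample arrays (last dimension = samples), or
#'   lists of three arrays for fusion models; `x_test` may be `NULL`.
#' @param y_train,y_val,y_test Binary label vectors.
#' @param cfg A [train_config()].
#' @param spec A [cnn2d_spec()] describing the architecture.
#' @param seed Seed controlling initialization, shuffling and dropout.
#' @param subject_ids_test Optional IDs carried into the prediction set.
#' @return An object of class `train_result`: `best_epoch`, loss histories,
#'   `model` (a `slicemap_model` at the best checkpoint), and `test` (a
#'   prediction-set data frame with subject_id, logit, prob, label) when
#'   test data were supplied.
#' @export
train_model <- function(x_train, y_train, x_val, y_val,
                        x_test = NULL, y_test = NULL, cfg = desk_train_config(),
                        spec = cnn2d_spec(), seed = cfg$seed,
                        subject_ids_test = NULL) {
  kind <- if (is.list(x_train) && !is.data.frame(x_train)) "fusion"
          else if (length(dim(x_train)) == 4L) "3d" else "2d"
  xs_tr <- as_batch(x_train, kind)
  xs_va <- as_batch(x_val, kind)
  xs_te <- if (is.null(x_test)) list() else as_batch(x_test, kind)
  dims <- lapply(xs_tr, function(a) dim(a)[-length(dim(a))])
  ns <- net_spec_cpp(dims, spec)
  if (length(unique(y_train)) < 2L)
    stop_param("training set contains a single class")
  if (length(y_val) < 1L || length(y_train) < 1L)
    stop_param("train and validation sets must be nonempty")
  fit <- cpp_train(xs_tr, as.double(y_train), xs_va, as.double(y_val),
                   xs_te, ns, cfg_cpp(cfg), as.integer(seed))
  model <- structure(list(net_spec = ns, params = fit$params, kind = kind),
                     class = "slicemap_model")
  test <- NULL
  if (!is.null(x_test)) {
    logit <- as.numeric(fit$test_logits)
    test <- data.frame(
      subject_id = if (is.null(subject_ids_test)) sprintf("s%04d", seq_along(logit))
                   else subject_ids_test,
      logit = logit, prob = 1 / (1 + exp(-logit)),
      label = as.integer(y_test), stringsAsFactors = FALSE)
  }
  structure(list(best_epoch = fit$best_epoch, epochs_run = fit$epochs_run,
                 train_loss = fit$train_loss, val_loss = fit$val_loss,
                 best_val_loss = fit$best_val_loss,
                 model = model, test = test, seed = as.integer(seed)),
            class = "train_result")
}

#' Train a slice classifier from a cohort and a subject split
#'
#' @param cohort A `volume_cohort` (already intensity-normalized if desired).
#' @param sspec A [slice_spec()].
#' @param split A [split_subjects()] result.
#' @param cfg A [train_config()].
#' @param spec A [cnn2d_spec()].
#' @param seed Training seed (defaults to `cfg$seed`).
#' @return A `train_result` (see [train_model()]) whose `test` field holds
#'   the held-out prediction set.
#' @export
train_slice_model <- function(cohort, sspec, split, cfg = desk_train_config(),
                              spec = cnn2d_spec(), seed = cfg$seed) {
  tr <- slice_dataset(cohort, sspec, split, "train")
  va <- slice_dataset(cohort, sspec, split, "val")
  te <- slice_dataset(cohort, sspec, split, "test")
  train_model(tr$images, tr$labels, va$images, va$labels, te$images, te$labels,
              cfg = cfg, spec = spec, seed = seed,
              subject_ids_test = te$subject_ids)
}

#' Repeat slice training and summarize test metrics
#'
#' @inheritParams train_slice_model
#' @param n_repeats Number of repeated runs with different seeds.
#' @return List with `runs` (per-repeat mcc/accuracy/precision data frame),
#'   `mean_mcc`, `sd_mcc`, and the last `train_result`.
#' @export
train_slice_repeats <- function(cohort, sspec, split, cfg = desk_train_config(),
                                spec = cnn2d_spec(), n_repeats = cfg$n_repeats) {
  runs <- vector("list", n_repeats)
  last <- NULL
  for (r in seq_len(n_repeats)) {
    res <- train_slice_model(cohort, sspec, split, cfg, spec,
                             seed = derive_seed(cfg$seed, plane_axis(sspec$plane),
                                                sspec$index, r))
    m <- prediction_metrics(res$test)
    runs[[r]] <- data.frame(repeat_id = r, mcc = m$mcc, accuracy = m$accuracy,
                            precision = m$precision, best_epoch = res$best_epoch)
    last <- res
  }
  runs <- do.call(rbind, runs)
  list(runs = runs, mean_mcc = mean(runs$mcc), sd_mcc = sd(runs$mcc),
       last_result = last)
}

#' Grid search over training hyperparameters
#'
#' Trains every configuration of the grid `n_repeats` times on identical
#' data splits (repeats differ only in seed) and ranks configurations by
#' mean test MCC, mirroring the reference grid weight decay {0.1, 0.01,
#' 0.001} x StepLR step {5, 10, 15, none} x batch norm {on, off}.
#'
#' @param grid Data frame with columns `weight_decay`, `scheduler_step`
#'   (0 = none) and `use_batch_norm`.
#' @param x_train,y_train,x_val,y_val,x_test,y_test Data as in
#'   [train_model()].
#' @param cfg Base [train_config()] supplying all other settings.
#' @param n_repeats Repeats per configuration.
#' @return List with `table` (per-config mean/sd MCC, ranked) and `best`
#'   (the winning row).
#' @export
run_hyperparameter_search <- function(grid, x_train, y_train, x_val, y_val,
                                      x_test, y_test, cfg = desk_train_config(),
                                      n_repeats = cfg$n_repeats) {
  if (is.null(grid) || nrow(grid) == 0L) stop_param("hyperparameter grid is empty")
  rows <- lapply(seq_len(nrow(grid)), function(i) {
    cfg_i <- cfg
    cfg_i$weight_decay <- grid$weight_decay[i]
    cfg_i$scheduler_step <- as.integer(grid$scheduler_step[i])
    spec_i <- cnn2d_spec(use_batch_norm = grid$use_batch_norm[i])
    mccs <- vapply(seq_len(n_repeats), function(r) {
      res <- train_model(x_train, y_train, x_val, y_val, x_test, y_test,
                         cfg = cfg_i, spec = spec_i,
                         seed = derive_seed(cfg$seed, i, r))
      prediction_metrics(res$test)$mcc
    }, numeric(1))
    cbind(grid[i, , drop = FALSE],
          data.frame(mean_mcc = mean(mccs), sd_mcc = sd(mccs)))
  })
  table <- do.call(rbind, rows)
  table <- table[order(-table$mean_mcc), ]
  rownames(table) <- NULL
  list(table = table, best = table[1, , drop = FALSE])
}

#' Reference hyperparameter grid
#' @return Data frame spanning weight decay {0.1, 0.01, 0.001} x scheduler
#'   step {5, 10, 15, 0 = none} x batch norm {TRUE, FALSE}.
#' @export
default_hyper_grid <- function() {
  expand.grid(weight_decay = c(0.1, 0.01, 0.001),
              scheduler_step = c(5L, 10L, 15L, 0L),
              use_batch_norm = c(TRUE, FALSE))
}
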