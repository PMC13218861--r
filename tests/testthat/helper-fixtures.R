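# Shared fixtures, all generated in code at test time.

# Two-class 2D image set: smooth noise plus (for class 1) a Gaussian blob of
# given standardized amplitude. Returns images (H x W x n), labels, and a
# train/val/test index partition.
make_blob_data <- function(n = 160, H = 16, effect = 3, seed = 1) {
  stopifnot(n %% 4 == 0)
  withr_seed <- function(expr) slicemapr:::with_seed(seed, expr)
  y <- rep(c(1L, 0L), n / 2)
  ctr <- (H + 1) / 2
  blob <- exp(-(outer((seq_len(H) - ctr)^2, (seq_len(H) - ctr)^2, "+")) / (2 * (H / 6)^2))
  x <- withr_seed({
    a <- array(rnorm(H * H * n), dim = c(H, H, n))
    for (i in which(y == 1L)) a[, , i] <- a[, , i] + effect * blob
    a
  })
  idx <- slicemapr:::with_seed(seed + 1, sample(n))
  n_tr <- round(0.64 * n); n_va <- round(0.16 * n)
  list(x = x, y = y,
       tr = idx[seq_len(n_tr)],
       va = idx[(n_tr + 1):(n_tr + n_va)],
       te = idx[(n_tr + n_va + 1):n])
}

# quick config for small-image unit tests
tiny_cfg <- function(...) desk_train_config(n_repeats = 2L, ...)

# small phantom cohort for IO/bookkeeping tests
tiny_cohort <- function(n = 8, shape = 24, seed = 42, effect = 1) {
  generate_cohort(phantom_spec(rep(shape, 3), n, diffuse_effect_size = effect,
                               seed = seed))
}

cohort_ids <- function(co) vapply(co, `[[`, character(1), "subject_id")
cohort_labels <- function(co) vapply(co, `[[`, integer(1), "label")

# Independent brute-force occlusion oracle: enumerates patch positions and
# per-pixel coverage sets from first principles (no shared code with the
# implementation beyond the model evaluation function).
brute_occlusion <- function(f, image, neutral, window, stride) {
  H <- nrow(image); W <- ncol(image)
  starts <- function(extent) {
    s <- seq(1L, extent - window + 1L, by = stride)
    if (!(extent - window + 1L) %in% s) s <- c(s, extent - window + 1L)
    s
  }
  f0 <- f(array(image, c(H, W, 1)))
  acc <- matrix(0, H, W); cnt <- matrix(0, H, W)
  for (sx in starts(H)) for (sy in starts(W)) {
    xr <- sx:(sx + window - 1L); yr <- sy:(sy + window - 1L)
    img2 <- image
    img2[xr, yr] <- neutral[xr, yr]
    drop <- f0 - f(array(img2, c(H, W, 1)))
    acc[xr, yr] <- acc[xr, yr] + drop
    cnt[xr, yr] <- cnt[xr, yr] + 1
  }
  acc / cnt
}
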