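#' Occlusion configuration
#'
#' @param window Square occlusion window side in pixels (reference 15).
#' @param stride Step of the sliding window in pixels (reference 5).
#' @param top_fraction Fraction of highest sign-adjusted scores retained
#'   per subject (reference 0.05).
#' @param smoothing_sigma Gaussian sigma for frequency-map smoothing
#'   (reference 1.0).
#' @return An object of class `occlusion_config`.
#' @export
occlusion_config <- function(window = 15L, stride = 5L, top_fraction = 0.05,
                             smoothing_sigma = 1.0) {
  window <- as.integer(window); stride <- as.integer(stride)
  if (stride < 1L || window < stride)
    stop_param("need window >= stride >= 1")
  if (top_fraction <= 0 || top_fraction >= 1)
    stop_param("top_fraction must lie in (0, 1)")
  structure(list(window = window, stride = stride, top_fraction = top_fraction,
                 smoothing_sigma = smoothing_sigma),
            class = "occlusion_config")
}

#' Select the neutral reference image
#'
#' The occlusion replacement content is taken from the candidate whose
#' predicted logit is closest to zero; ties are broken by the lowest
#' candidate index.
#'
#' @param model A trained `slicemap_model`, or a function mapping an
#'   H x W x N image batch to a logit vector.
#' @param images Candidate pool, H x W x N array.
#' @param logits Optional precomputed logits for the pool (skips the model).
#' @return List with `image`, `index` (into the pool) and `logit`.
#' @export
neutral_reference <- function(model, images, logits = NULL) {
  if (is.null(dim(images)) || length(dim(images)) == 2L)
    dim(images) <- c(dim(images), 1L)
  n <- dim(images)[3]
  if (n < 1L) stop_param("empty neutral-candidate pool")
  if (is.null(logits)) logits <- model_logits(model, images)
  idx <- which.min(abs(logits))   # first minimum = lowest index on ties
  list(image = images[, , idx], index = idx, logit = logits[idx])
}

# accept either a trained model or a plain batch -> logits function
model_logits <- function(model, batch) {
  if (is.function(model)) as.numeric(model(batch)) else predict_logits(model, batch)
}

# 0-based patch start offsets: stride grid plus a final flush-to-border
# position so every pixel is covered by at least one patch.
occlusion_starts <- function(extent, window, stride) {
  if (extent < window) stop_param("image smaller than occlusion window")
  s <- seq.int(0L, extent - window, by = stride)
  if (s[length(s)] != extent - window) s <- c(s, extent - window)
  s
}

#' Raw occlusion score map for one image
#'
#' Slides the occlusion window over the image on the stride grid (plus a
#' flush-to-border position per axis), replaces each patch with the
#' corresponding pixels of the neutral image, re-evaluates the fixed model
#' and records the logit drop. The raw score at a pixel is the mean drop
#' over all patches covering it.
#'
#' @param model Trained `slicemap_model` (parameters are never modified), or
#'   a function mapping an image batch to logits (useful for closed-form
#'   reference models).
#' @param image Numeric matrix, at least the window size in each dimension.
#' @param neutral Neutral reference image of identical shape.
#' @param cfg An [occlusion_config()].
#' @return Numeric matrix of raw occlusion scores, same shape as `image`.
#' @export
occlusion_scores <- function(model, image, neutral, cfg = occlusion_config()) {
  if (!all(dim(image) == dim(neutral)))
    stop_param("image and neutral image must share a shape")
  H <- nrow(image); W <- ncol(image)
  sx <- occlusion_starts(H, cfg$window, cfg$stride)
  sy <- occlusion_starts(W, cfg$window, cfg$stride)
  pos <- expand.grid(x = sx, y = sy)
  np <- nrow(pos)
  batch <- array(rep(image, np + 1L), dim = c(H, W, np + 1L))
  for (p in seq_len(np)) {
    rx <- (pos$x[p] + 1L):(pos$x[p] + cfg$window)
    ry <- (pos$y[p] + 1L):(pos$y[p] + cfg$window)
    batch[rx, ry, p + 1L] <- neutral[rx, ry]
  }
  logits <- model_logits(model, batch)
  f0 <- logits[1]
  drops <- f0 - logits[-1]
  acc <- matrix(0, H, W); cnt <- matrix(0L, H, W)
  for (p in seq_len(np)) {
    rx <- (pos$x[p] + 1L):(pos$x[p] + cfg$window)
    ry <- (pos$y[p] + 1L):(pos$y[p] + cfg$window)
    acc[rx, ry] <- acc[rx, ry] + drops[p]
    cnt[rx, ry] <- cnt[rx, ry] + 1L
  }
  acc / cnt
}

#' Sign-adjust a raw occlusion map
#'
#' Raw drops are kept for positive-class subjects and negated for
#' negative-class subjects, so positive adjusted scores consistently mark
#' regions supporting correct classification.
#'
#' @param raw Raw occlusion score matrix.
#' @param label Binary subject label.
#' @return Adjusted score matrix.
#' @export
sign_adjust <- function(raw, label) {
  if (!label %in% c(0L, 1L)) stop_param("label must be 0 or 1")
  if (label == 1L) raw else -raw
}

#' Subject-specific top-fraction threshold and indicator
#'
#' The threshold tau is the k-th largest adjusted score with
#' k = ceiling(top_fraction * n_pixels) (the empirical upper quantile);
#' the indicator marks all pixels with adjusted score >= tau, so ties at
#' tau are all retained and at least k pixels are always set.
#'
#' @param adjusted Sign-adjusted score matrix.
#' @param top_fraction Retained fraction (default 0.05).
#' @return List with `tau` and `indicator` (0/1 matrix).
#' @export
subject_threshold <- function(adjusted, top_fraction = 0.05) {
  if (length(adjusted) < 1L) stop_param("empty score grid")
  k <- max(1L, ceiling(top_fraction * length(adjusted)))
  tau <- sort(as.vector(adjusted), decreasing = TRUE)[k]
  list(tau = tau, indicator = (adjusted >= tau) * 1)
}

#' Group-level attribution frequency map
#'
#' The frequency map is the per-pixel fraction of subjects whose
#' sign-adjusted occlusion score reaches their subject-specific threshold;
#' a Gaussian-smoothed variant (reflective boundary) is stored alongside
#' for peak finding and display. Thresholding happens before smoothing.
#'
#' @param indicators List of 0/1 indicator matrices (one per subject), or a
#'   3D array with subjects along the last dimension.
#' @param sigma Smoothing sigma in pixels.
#' @return An object of class `frequency_map` with `values`, `smoothed`,
#'   `n_subjects`, `sigma`.
#' @export
frequency_map <- function(indicators, sigma = 1.0) {
  if (is.list(indicators)) {
    d <- dim(indicators[[1]])
    if (!all(vapply(indicators, function(m) all(dim(m) == d), logical(1))))
      stop_param("indicator grids must share a shape")
    indicators <- array(unlist(indicators, use.names = FALSE),
                        dim = c(d, length(indicators)))
  }
  n <- dim(indicators)[3]
  if (is.na(n) || n < 1L) stop_param("need at least one indicator grid")
  values <- apply(indicators, c(1, 2), mean)
  structure(list(values = values,
                 smoothed = gaussian_smooth(values, sigma),
                 n_subjects = n, sigma = sigma),
            class = "frequency_map")
}

#' Per-slice occlusion summary
#'
#' The slice-level occlusion score used for comparison with slice MCC
#' profiles: mean over subjects of each subject's maximum sign-adjusted
#' occlusion value (only the single most salient local region counts).
#'
#' @param adjusted List of sign-adjusted score matrices.
#' @return Scalar summary.
#' @export
slice_occlusion_summary <- function(adjusted) {
  if (length(adjusted) < 1L) stop_param("need at least one subject map")
  mean(vapply(adjusted, max, numeric(1)))
}

#' Occlusion attribution for every test subject of a slice
#'
#' Runs the full per-subject occlusion pipeline on the test split: neutral
#' reference selection from the test pool, raw scores, sign adjustment,
#' subject thresholds, and the group frequency map.
#'
#' @param model Trained `slicemap_model` for this slice.
#' @param dataset A test-split [slice_dataset()].
#' @param cfg An [occlusion_config()].
#' @return List with `maps` (per-subject list: raw, adjusted, tau,
#'   indicator, subject_id, label), `freq` (a [frequency_map()]), `summary`
#'   (the [slice_occlusion_summary()]), and `neutral`.
#' @export
occlusion_analysis <- function(model, dataset, cfg = occlusion_config()) {
  stopifnot(inherits(dataset, "slice_dataset"))
  neut <- neutral_reference(model, dataset$images)
  n <- dim(dataset$images)[3]
  maps <- vector("list", n)
  for (i in seq_len(n)) {
    raw <- occlusion_scores(model, dataset$images[, , i], neut$image, cfg)
    adj <- sign_adjust(raw, dataset$labels[i])
    th <- subject_threshold(adj, cfg$top_fraction)
    maps[[i]] <- list(raw = raw, adjusted = adj, tau = th$tau,
                      indicator = th$indicator,
                      subject_id = dataset$subject_ids[i],
                      label = dataset$labels[i])
  }
  freq <- frequency_map(lapply(maps, `[[`, "indicator"), cfg$smoothing_sigma)
  list(maps = maps, freq = freq,
       summary = slice_occlusion_summary(lapply(maps, `[[`, "adjusted")),
       neutral = neut)
}
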