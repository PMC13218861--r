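#' Confusion counts for binary predictions
#'
#' @param pred,truth Equal-length binary (0/1) vectors.
#' @return An object of class `confusion_counts` with fields TP, FP, TN, FN.
#' @export
confusion <- function(pred, truth) {
  if (length(pred) != length(truth)) stop_param("pred and truth lengths differ")
  if (length(pred) < 1L) stop_param("need at least one sample")
  if (!all(pred %in% c(0, 1)) || !all(truth %in% c(0, 1)))
    stop_param("entries must be binary 0/1")
  structure(list(TP = sum(pred == 1 & truth == 1),
                 FP = sum(pred == 1 & truth == 0),
                 TN = sum(pred == 0 & truth == 0),
                 FN = sum(pred == 0 & truth == 1)),
            class = "confusion_counts")
}

#' Matthews correlation coefficient
#'
#' MCC = (TP*TN - FP*FN) / sqrt((TP+FP)(TP+FN)(TN+FP)(TN+FN)), the primary
#' evaluation metric of the pipeline; it equals the Pearson correlation of
#' the observed and predicted binary label vectors. When any denominator
#' factor is zero the value is 0/0; the documented convention here returns 0.
#'
#' @param c A `confusion_counts` object.
#' @return Scalar in [-1, 1].
#' @export
mcc <- function(c) {
  stopifnot(inherits(c, "confusion_counts"))
  num <- as.double(c$TP) * c$TN - as.double(c$FP) * c$FN
  den <- sqrt((c$TP + c$FP)) * sqrt((c$TP + c$FN)) *
    sqrt((c$TN + c$FP)) * sqrt((c$TN + c$FN))
  if (den == 0) return(0)
  num / den
}

#' Classification accuracy
#' @param c A `confusion_counts` object.
#' @return (TP + TN) / n.
#' @export
accuracy <- function(c) {
  stopifnot(inherits(c, "confusion_counts"))
  n <- c$TP + c$FP + c$TN + c$FN
  (c$TP + c$TN) / n
}

#' Precision (positive predictive value)
#' @param c A `confusion_counts` object.
#' @return TP / (TP + FP), or `NA` when no positive predictions were made.
#' @export
precision <- function(c) {
  stopifnot(inherits(c, "confusion_counts"))
  if (c$TP + c$FP == 0) return(NA_real_)
  c$TP / (c$TP + c$FP)
}

# metrics of a prediction set at the 0.5 probability / 0 logit cut
prediction_metrics <- function(preds) {
  cc <- confusion(as.integer(preds$prob >= 0.5), preds$label)
  list(mcc = mcc(cc), accuracy = accuracy(cc), precision = precision(cc))
}

#' Dual-threshold (selective prediction) analysis
#'
#' For each (lower, upper) pair, predictions with probability at most
#' `lower` are classified negative, those at least `upper` positive, and
#' intermediate-confidence samples are ignored; MCC is computed on the
#' retained samples and the retained fraction recorded. Rows retaining no
#' samples are flagged with `NA` MCC rather than failing.
#'
#' @param probs Predicted probabilities in (0, 1) (or a prediction-set
#'   data frame with columns `prob` and `label`).
#' @param labels True binary labels (ignored when `probs` is a data frame).
#' @param threshold_pairs Two-column matrix or data frame of (lower, upper)
#'   pairs; defaults to the symmetric grid (t, 1 - t), t = 0.50, 0.45, ..., 0.05.
#' @return A `data.frame` with columns lower, upper, n_retained,
#'   retained_fraction, mcc.
#' @export
dual_threshold <- function(probs, labels = NULL, threshold_pairs = NULL) {
  if (is.data.frame(probs)) { labels <- probs$label; probs <- probs$prob }
  if (is.null(threshold_pairs)) {
    t <- seq(0.50, 0.05, by = -0.05)
    threshold_pairs <- cbind(lower = t, upper = 1 - t)
  }
  threshold_pairs <- as.matrix(threshold_pairs)
  if (any(threshold_pairs[, 1] > threshold_pairs[, 2]))
    stop_param("lower threshold exceeds upper threshold")
  n <- length(probs)
  rows <- lapply(seq_len(nrow(threshold_pairs)), function(i) {
    lo <- threshold_pairs[i, 1]; up <- threshold_pairs[i, 2]
    keep <- probs <= lo | probs >= up
    m <- if (any(keep)) mcc(confusion(as.integer(probs[keep] >= up), labels[keep]))
         else NA_real_
    data.frame(lower = lo, upper = up, n_retained = sum(keep),
               retained_fraction = sum(keep) / n, mcc = m)
  })
  do.call(rbind, rows)
}

#' Welch two-sample t-test comparison report
#'
#' Compares two samples of a metric (e.g. MCC over repeated runs under true
#' vs permuted labels). Degenerate input where both groups are the same
#' constant returns t = 0, p = 1 by convention.
#'
#' @param samples_a,samples_b Numeric vectors with at least 2 values each.
#' @return An object of class `comparison_report`: group means/sds, Welch t
#'   statistic, two-sided p, and the raw samples.
#' @export
two_sample_ttest <- function(samples_a, samples_b) {
  if (length(samples_a) < 2L || length(samples_b) < 2L)
    stop_param("need at least 2 samples per group")
  if (sd(samples_a) == 0 && sd(samples_b) == 0 &&
      samples_a[1] == samples_b[1]) {
    t_stat <- 0; p <- 1
  } else if (sd(samples_a) == 0 && sd(samples_b) == 0) {
    t_stat <- sign(mean(samples_a) - mean(samples_b)) * Inf; p <- 0
  } else {
    tt <- t.test(samples_a, samples_b, var.equal = FALSE)
    t_stat <- unname(tt$statistic); p <- tt$p.value
  }
  structure(list(mean_a = mean(samples_a), sd_a = sd(samples_a),
                 mean_b = mean(samples_b), sd_b = sd(samples_b),
                 t = t_stat, p = p,
                 samples_a = samples_a, samples_b = samples_b),
            class = "comparison_report")
}

#' Energy-distance two-sample permutation test
#'
#' Energy statistic E = 2 mean||x - y|| - mean||x - x'|| - mean||y - y'||
#' (V-statistic form; zero iff the distributions coincide), with a
#' label-permutation null and the add-one p-value estimator
#' p = (1 + #\{E_perm >= E_obs\}) / (1 + n_permutations).
#'
#' @param x_samples,y_samples Numeric matrices (rows = samples) or vectors;
#'   the two groups must share the vector length.
#' @param n_permutations Number of label shuffles (default 999).
#' @param seed Integer seed for the permutation stream.
#' @return List with `statistic` and `p`.
#' @export
energy_distance_test <- function(x_samples, y_samples, n_permutations = 999L,
                                 seed = 1L) {
  if (is.null(dim(x_samples))) x_samples <- matrix(x_samples, ncol = 1)
  if (is.null(dim(y_samples))) y_samples <- matrix(y_samples, ncol = 1)
  if (ncol(x_samples) != ncol(y_samples))
    stop_param("sample vectors of the two groups have different lengths")
  n <- nrow(x_samples); m <- nrow(y_samples)
  if (n < 2L || m < 2L) stop_param("need at least 2 samples per group")
  D <- as.matrix(dist(rbind(x_samples, y_samples)))
  estat <- function(ix) {
    iy <- setdiff(seq_len(n + m), ix)
    2 * mean(D[ix, iy]) - mean(D[ix, ix]) - mean(D[iy, iy])
  }
  e_obs <- estat(seq_len(n))
  perms <- with_seed(seed, replicate(n_permutations, sample(n + m, n)))
  e_perm <- apply(matrix(perms, nrow = n), 2, estat)
  list(statistic = e_obs,
       p = (1 + sum(e_perm >= e_obs)) / (1 + n_permutations))
}

#' Pearson correlation with two-sided p-value
#'
#' @param x,y Paired numeric vectors, length >= 3.
#' @return List with `r` and `p`; zero-variance input yields `NA` values.
#' @export
pearson_r <- function(x, y) {
  if (length(x) != length(y) || length(x) < 3L)
    stop_param("need >= 3 paired values")
  if (sd(x) == 0 || sd(y) == 0) return(list(r = NA_real_, p = NA_real_))
  ct <- cor.test(x, y, method = "pearson")
  list(r = unname(ct$estimate), p = ct$p.value)
}
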