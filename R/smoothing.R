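# Separable Gaussian smoothing with reflective ("repeat edge") boundary,
# vectorized as shifted-slab sums. Used for the phantom's low-frequency
# texture (3D) and for frequency-map smoothing (2D).

gaussian_kernel1d <- function(sigma, truncate = 4) {
  r <- max(1L, as.integer(ceiling(truncate * sigma)))
  w <- exp(-0.5 * ((-r:r) / sigma)^2)
  w / sum(w)
}

#' Gaussian-smooth a 2D or 3D array
#'
#' Separable Gaussian filter with reflective boundary handling (edge sample
#' repeated, as in the common image-processing convention).
#'
#' @param a Numeric 2D or 3D array.
#' @param sigma Kernel standard deviation in pixels/voxels.
#' @param truncate Kernel radius in units of `sigma`.
#' @return Array of the same shape.
#' @export
gaussian_smooth <- function(a, sigma, truncate = 4) {
  if (sigma <= 0) return(a)
  w <- gaussian_kernel1d(sigma, truncate)
  r <- (length(w) - 1L) / 2L
  nd <- length(dim(a))
  if (!nd %in% c(2L, 3L)) stop_param("gaussian_smooth expects a 2D or 3D array")
  for (ax in seq_len(nd)) {
    L <- dim(a)[ax]
    pad <- c(pmin(r, L):1, 1:L, L:pmax(1L, L - r + 1L))
    # clamp reflection for tiny axes
    if (length(pad) != L + 2 * r) {
      refl <- function(i) { i <- abs(i - 1L) %% (2L * L); ifelse(i >= L, 2L * L - 1L - i, i) + 1L }
      pad <- refl((1L - r):(L + r))
    }
    ap <- switch(paste0(nd, ".", ax),
      "2.1" = a[pad, , drop = FALSE],
      "2.2" = a[, pad, drop = FALSE],
      "3.1" = a[pad, , , drop = FALSE],
      "3.2" = a[, pad, , drop = FALSE],
      "3.3" = a[, , pad, drop = FALSE])
    out <- array(0, dim(a))
    for (k in seq_along(w)) {
      sl <- k:(k + L - 1L)
      out <- out + w[k] * switch(paste0(nd, ".", ax),
        "2.1" = ap[sl, , drop = FALSE],
        "2.2" = ap[, sl, drop = FALSE],
        "3.1" = ap[sl, , , drop = FALSE],
        "3.2" = ap[, sl, , drop = FALSE],
        "3.3" = ap[, , sl, drop = FALSE])
    }
    a <- out
  }
  a
}
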