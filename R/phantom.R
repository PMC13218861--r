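#' Phantom cohort specification
#'
#' Describes a synthetic cohort of class-labeled 3D volumes used as a
#' stand-in for a registered, skull-stripped structural MRI cohort. Each
#' volume is a smooth ellipsoidal "brain" foreground on a zero background,
#' carrying low-frequency Gaussian-filtered noise texture plus an optional
#' diffuse class-correlated intensity pattern concentrated toward the
#' volume center (so central slices carry more signal than peripheral ones,
#' as in real slice-wise classification profiles).
#'
#' @param volume_shape Integer triple of voxel extents.
#' @param n_subjects Number of subjects (one scan each).
#' @param class_balance Fraction of subjects in the positive class (label 1).
#' @param diffuse_effect_size Standardized mean shift of the class-correlated
#'   texture component, in units of the texture standard deviation. 0 means
#'   no class signal.
#' @param noise_sd Standard deviation of the low-frequency texture relative
#'   to the unit foreground intensity.
#' @param seed Integer seed; identical seeds give bit-identical cohorts.
#' @return An object of class `phantom_spec`.
#' @export
phantom_spec <- function(volume_shape = c(64L, 64L, 64L), n_subjects = 200L,
                         class_balance = 0.5, diffuse_effect_size = 1.0,
                         noise_sd = 0.1, seed = 1L) {
  volume_shape <- as.integer(volume_shape)
  if (length(volume_shape) != 3L || any(volume_shape < 1L))
    stop_param("volume_shape must be three strictly positive integers")
  if (n_subjects < 2L) stop_param("n_subjects must be >= 2 (both classes needed)")
  if (class_balance <= 0 || class_balance >= 1)
    stop_param("class_balance must lie in (0, 1)")
  n_pos <- round(n_subjects * class_balance)
  if (n_pos < 1L || n_pos > n_subjects - 1L)
    stop_param("class_balance leaves one class empty at this n_subjects")
  if (diffuse_effect_size < 0) stop_param("diffuse_effect_size must be nonnegative")
  if (noise_sd <= 0) stop_param("noise_sd must be positive")
  structure(list(volume_shape = volume_shape, n_subjects = as.integer(n_subjects),
                 class_balance = class_balance,
                 diffuse_effect_size = diffuse_effect_size,
                 noise_sd = noise_sd, seed = as.integer(seed)),
            class = "phantom_spec")
}

# Ellipsoid foreground mask shared by all subjects (registration assumed).
phantom_mask <- function(shape, semi_frac = 0.42) {
  ctr <- (shape - 1) / 2
  ax <- semi_frac * shape
  x <- ((seq_len(shape[1]) - 1 - ctr[1]) / ax[1])^2
  y <- ((seq_len(shape[2]) - 1 - ctr[2]) / ax[2])^2
  z <- ((seq_len(shape[3]) - 1 - ctr[3]) / ax[3])^2
  outer(outer(x, y, "+"), z, "+") <= 1
}

# Central Gaussian bump (max 1) weighting the diffuse class effect.
phantom_effect_pattern <- function(shape, width_frac = 0.25) {
  ctr <- (shape - 1) / 2
  w <- width_frac * min(shape)
  x <- (seq_len(shape[1]) - 1 - ctr[1])^2
  y <- (seq_len(shape[2]) - 1 - ctr[2])^2
  z <- (seq_len(shape[3]) - 1 - ctr[3])^2
  exp(-outer(outer(x, y, "+"), z, "+") / (2 * w^2))
}

#' Generate a synthetic labeled cohort
#'
#' @param spec A [phantom_spec()].
#' @return A `volume_cohort`: list of `labeled_volume` objects (fields
#'   `voxels`, `subject_id`, `label`, `scan_id`), with the generating spec
#'   attached as an attribute.
#' @export
generate_cohort <- function(spec) {
  stopifnot(inherits(spec, "phantom_spec"))
  shape <- spec$volume_shape
  n <- spec$n_subjects
  n_pos <- round(n * spec$class_balance)
  labels <- c(rep(1L, n_pos), rep(0L, n - n_pos))
  mask <- phantom_mask(shape)
  g <- phantom_effect_pattern(shape)
  vols <- vector("list", n)
  for (i in seq_len(n)) {
    tex <- with_seed(derive_seed(spec$seed, 101L, i), {
      raw <- array(rnorm(prod(shape)), dim = shape)
      gaussian_smooth(raw, sigma = 2, truncate = 3)
    })
    s <- sd(tex[mask])
    tex <- tex / s * spec$noise_sd
    vox <- array(0, dim = shape)
    shift <- labels[i] * spec$diffuse_effect_size * spec$noise_sd
    vox[mask] <- 1 + tex[mask] + shift * g[mask]
    vols[[i]] <- labeled_volume(vox, subject_id = sprintf("sub%04d", i),
                                label = labels[i],
                                scan_id = sprintf("sub%04d_scan1", i))
  }
  structure(vols, class = "volume_cohort", spec = spec)
}

#' Signal-injection specification
#'
#' Defines the localized corruption rule: inside `region`, every voxel value
#' `v` of a target-class volume is replaced by an independent Gaussian draw
#' with mean `mean_multiplier * v` and standard deviation `sd`; all other
#' voxels, and all volumes of the other class, are left untouched.
#'
#' @param region A [region_box()] fully inside the volumes.
#' @param target_class Binary label whose volumes are modified (default 0,
#'   the negative class, mirroring modification of one class only).
#' @param mean_multiplier Multiplier applied to the original voxel value to
#'   form the replacement mean (reference value 2).
#' @param sd Standard deviation of the replacement draws (reference value 1).
#' @param seed Seed for the injection stream, independent of cohort
#'   generation randomness.
#' @return An object of class `injection_spec`.
#' @export
injection_spec <- function(region = region_box(c(25, 25, 25), c(34, 34, 34)),
                           target_class = 0L, mean_multiplier = 2, sd = 1,
                           seed = 1L) {
  stopifnot(inherits(region, "region_box"))
  if (!target_class %in% c(0L, 1L)) stop_param("target_class must be 0 or 1")
  if (!is.finite(mean_multiplier) || !is.finite(sd) || sd <= 0)
    stop_param("mean_multiplier and sd must be finite, sd > 0")
  structure(list(region = region, target_class = as.integer(target_class),
                 mean_multiplier = mean_multiplier, sd = sd,
                 seed = as.integer(seed)),
            class = "injection_spec")
}

#' Inject a localized signal into one class of a cohort
#'
#' @param cohort A `volume_cohort` (or plain list of `labeled_volume`s).
#' @param injection An [injection_spec()].
#' @return The cohort with target-class volumes modified inside the region.
#' @export
inject_signal <- function(cohort, injection) {
  stopifnot(inherits(injection, "injection_spec"))
  box <- injection$region
  for (v in cohort) {
    if (any(box$lo < 0) || any(box$hi > dim(v$voxels) - 1L))
      stop_param("injection region lies outside the volume bounds")
  }
  idx <- lapply(1:3, function(d) (box$lo[d]:box$hi[d]) + 1L)
  out <- cohort
  for (i in seq_along(out)) {
    v <- out[[i]]
    if (v$label != injection$target_class) next
    orig <- v$voxels[idx[[1]], idx[[2]], idx[[3]]]
    repl <- with_seed(derive_seed(injection$seed, 202L, i),
                      rnorm(length(orig), mean = injection$mean_multiplier * orig,
                            sd = injection$sd))
    v$voxels[idx[[1]], idx[[2]], idx[[3]]] <- repl
    out[[i]] <- v
  }
  out
}

#' Z-score a volume over its nonzero foreground
#'
#' Foreground (nonzero) voxel intensities are standardized to mean 0 and
#' standard deviation 1; background zeros are preserved. This is the
#' package's reference intensity-normalization dialect.
#'
#' @param x A numeric 3D array or a `labeled_volume`.
#' @return Same type as `x`.
#' @export
normalize_intensity <- function(x) {
  if (inherits(x, "labeled_volume")) {
    x$voxels <- normalize_intensity(x$voxels)
    return(x)
  }
  fg <- x != 0
  if (!any(fg)) stop_param("degenerate input: all-zero volume")
  mu <- mean(x[fg])
  s <- sqrt(mean((x[fg] - mu)^2))   # population sd (image-normalization dialect)
  if (s == 0) stop_param("degenerate input: constant foreground")
  x[fg] <- (x[fg] - mu) / s
  x
}

#' Normalize every volume of a cohort
#' @param cohort A `volume_cohort`.
#' @return The cohort with each volume passed through [normalize_intensity()].
#' @export
normalize_cohort <- function(cohort) {
  out <- cohort
  for (i in seq_along(out)) out[[i]] <- normalize_intensity(out[[i]])
  out
}

#' Write a cohort to disk as NIfTI plus a CSV manifest
#'
#' @param cohort A `volume_cohort`.
#' @param dir Output directory (created if needed).
#' @param split Optional [split_subjects()] result used to tag each row.
#' @param compress Write `.nii.gz` (default) or plain `.nii`.
#' @return Path to the manifest CSV, invisibly.
#' @export
write_cohort <- function(cohort, dir, split = NULL, compress = TRUE) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  ext <- if (compress) ".nii.gz" else ".nii"
  rows <- lapply(cohort, function(v) {
    path <- file.path(dir, paste0(v$scan_id, ext))
    write_nifti(v$voxels, path)
    sp <- if (is.null(split)) NA_character_ else split_of(split, v$subject_id)
    data.frame(subject_id = v$subject_id, scan_id = v$scan_id,
               label = v$label, path = path, split = sp,
               stringsAsFactors = FALSE)
  })
  manifest <- do.call(rbind, rows)
  mpath <- file.path(dir, "manifest.csv")
  write.csv(manifest, mpath, row.names = FALSE)
  invisible(mpath)
}

#' Read a cohort written by [write_cohort()]
#' @param manifest Path to a manifest CSV (or a directory containing one).
#' @return A `volume_cohort`.
#' @export
read_cohort <- function(manifest) {
  if (dir.exists(manifest)) manifest <- file.path(manifest, "manifest.csv")
  m <- read.csv(manifest, stringsAsFactors = FALSE)
  need <- c("subject_id", "scan_id", "label", "path")
  if (!all(need %in% names(m))) stop_param("manifest lacks columns: ",
                                           paste(setdiff(need, names(m)), collapse = ", "))
  vols <- lapply(seq_len(nrow(m)), function(i) {
    labeled_volume(read_nifti(m$path[i]), subject_id = m$subject_id[i],
                   label = m$label[i], scan_id = m$scan_id[i])
  })
  structure(vols, class = "volume_cohort")
}
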