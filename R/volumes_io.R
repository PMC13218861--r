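#' Labeled 3D volume
#'
#' One subject scan: a 3D intensity grid with a subject ID, a binary label
#' and a scan ID (multiple scans per subject are supported; splitting is
#' always done at the subject level).
#'
#' @param voxels Numeric 3D array of finite intensities.
#' @param subject_id,scan_id Character identifiers.
#' @param label Binary label (1 = positive class).
#' @return An object of class `labeled_volume`.
#' @export
labeled_volume <- function(voxels, subject_id, label, scan_id = subject_id) {
  if (length(dim(voxels)) != 3L) stop_param("voxels must be a 3D array")
  if (!all(is.finite(voxels))) stop_param("voxels must be finite")
  if (!label %in% c(0L, 1L)) stop_param("label must be 0 or 1")
  structure(list(voxels = voxels, subject_id = as.character(subject_id),
                 label = as.integer(label), scan_id = as.character(scan_id)),
            class = "labeled_volume")
}

PLANES <- c("sagittal", "coronal", "axial")

plane_axis <- function(plane) match(match.arg(plane, PLANES), PLANES)

#' Slice specification
#'
#' Names a 2D slice of a 3D volume: the anatomical plane fixes one axis
#' (sagittal = dim0, coronal = dim1, axial = dim2, i.e. left-right,
#' front-back, superior-inferior) and `index` is the 0-based coordinate
#' along that axis. All slice indices and region coordinates in this
#' package are 0-based, matching the coordinate convention used when
#' reporting voxel ranges.
#'
#' @param plane One of `"sagittal"`, `"coronal"`, `"axial"`.
#' @param index Nonnegative 0-based slice index.
#' @return An object of class `slice_spec`.
#' @export
slice_spec <- function(plane, index) {
  plane <- match.arg(plane, PLANES)
  index <- as.integer(index)
  if (is.na(index) || index < 0L) stop_param("slice index must be a nonnegative integer")
  structure(list(plane = plane, index = index), class = "slice_spec")
}

#' Extract a 2D slice from a volume
#'
#' The returned image preserves the order of the two remaining axes.
#'
#' @param volume A `labeled_volume` or numeric 3D array.
#' @param spec A [slice_spec()].
#' @return A numeric matrix.
#' @export
extract_slice <- function(volume, spec) {
  vox <- if (inherits(volume, "labeled_volume")) volume$voxels else volume
  stopifnot(inherits(spec, "slice_spec"))
  ax <- plane_axis(spec$plane)
  if (spec$index >= dim(vox)[ax])
    stop_param("slice index ", spec$index, " out of range for axis extent ",
               dim(vox)[ax])
  i <- spec$index + 1L
  switch(ax, vox[i, , ], vox[, i, ], vox[, , i])
}

#' Stack slices back into a volume
#'
#' Inverse of slicing a whole volume plane-wise: `stack_slices(slices, plane)`
#' reconstructs the 3D array when `slices` holds every slice of the plane in
#' index order.
#'
#' @param slices List of equally shaped matrices.
#' @param plane Anatomical plane the slices came from.
#' @return A numeric 3D array.
#' @export
stack_slices <- function(slices, plane) {
  ax <- plane_axis(plane)
  s2 <- dim(slices[[1]])
  n <- length(slices)
  out <- array(NA_real_, switch(ax, c(n, s2), c(s2[1], n, s2[2]), c(s2, n)))
  for (i in seq_len(n)) {
    switch(ax,
           out[i, , ] <- slices[[i]],
           out[, i, ] <- slices[[i]],
           out[, , i] <- slices[[i]])
  }
  out
}

#' Deterministic slice-index sampling with denser mid-range coverage
#'
#' Produces roughly `target_count` strictly increasing 0-based indices
#' spanning `[margin, axis_extent - 1 - margin]`, with the sampling stride
#' in the central half of the axis set to half the peripheral stride
#' (denser sampling near the mid-slice, where structural detail is richer).
#'
#' @param axis_extent Length of the axis being sampled.
#' @param target_count Approximate number of indices wanted (default 40).
#' @param fallback `"error"` (default) rejects infeasible requests;
#'   `"full"` returns every index in range instead.
#' @return Integer vector of 0-based slice indices.
#' @export
sample_slice_indices <- function(axis_extent, target_count = 40L,
                                 fallback = c("error", "full")) {
  fallback <- match.arg(fallback)
  axis_extent <- as.integer(axis_extent)
  target_count <- as.integer(target_count)
  if (target_count < 3L) stop_param("target_count must be >= 3")
  if (axis_extent < target_count)
    stop_param("axis_extent must be >= target_count")
  margin <- max(2L, floor(0.04 * axis_extent))
  lo <- margin; hi <- axis_extent - 1L - margin
  span <- hi - lo + 1L
  if (span < target_count) {
    if (fallback == "full") return(seq.int(0L, axis_extent - 1L))
    stop_param("margins leave fewer than target_count indices; ",
               "use fallback = 'full' for degenerate extents")
  }
  c_lo <- axis_extent / 4; c_hi <- 3 * axis_extent / 4   # central half
  len_c <- min(hi, c_hi) - max(lo, c_lo)
  len_p <- span - len_c
  stride_c <- max(1, (len_c + len_p / 2) / target_count)
  cur <- lo; out <- integer(0)
  while (cur <= hi) {
    out <- c(out, cur)
    step <- if (cur >= c_lo && cur < c_hi) stride_c else 2 * stride_c
    cur <- as.integer(round(cur + step))
  }
  unique(out)
}

#' Leakage-safe subject-level split
#'
#' Subjects (not scans) are randomly partitioned into train/validation/test
#' sets; every scan of a subject inherits that subject's assignment, so
#' scan-level leakage is impossible by construction. Set sizes follow
#' largest-remainder rounding of `n * ratios`.
#'
#' @param subject_ids Character vector of unique subject IDs.
#' @param ratios Train/validation/test fractions summing to 1.
#' @param seed Integer seed.
#' @return An object of class `subject_split` with `train_ids`, `val_ids`,
#'   `test_ids` and the seed.
#' @export
split_subjects <- function(subject_ids, ratios = c(0.64, 0.16, 0.20), seed = 1L) {
  subject_ids <- unique(as.character(subject_ids))
  n <- length(subject_ids)
  if (n < 3L) stop_param("need at least 3 subjects to split")
  if (length(ratios) != 3L || any(ratios < 0) || abs(sum(ratios) - 1) > 1e-9)
    stop_param("ratios must be three nonnegative numbers summing to 1")
  sizes <- largest_remainder(n * ratios, n)
  perm <- with_seed(seed, sample(subject_ids))
  cuts <- cumsum(sizes)
  structure(list(train_ids = sort(perm[seq_len(sizes[1])]),
                 val_ids = sort(perm[(cuts[1] + 1):cuts[2]]),
                 test_ids = sort(perm[(cuts[2] + 1):cuts[3]]),
                 seed = as.integer(seed)),
            class = "subject_split")
}

largest_remainder <- function(x, total) {
  fl <- floor(x)
  rem <- as.integer(total - sum(fl))
  if (rem > 0) {
    extra <- order(x - fl, decreasing = TRUE)[seq_len(rem)]
    fl[extra] <- fl[extra] + 1
  }
  as.integer(fl)
}

# split tag ("train"/"val"/"test") of one subject
split_of <- function(split, subject_id) {
  if (subject_id %in% split$train_ids) return("train")
  if (subject_id %in% split$val_ids) return("val")
  if (subject_id %in% split$test_ids) return("test")
  NA_character_
}

#' Build a slice dataset from a cohort
#'
#' Extracts one (plane, index) slice per scan, optionally restricted to one
#' side of a subject-level split.
#'
#' @param cohort A `volume_cohort` or list of `labeled_volume`s.
#' @param spec A [slice_spec()].
#' @param split Optional [split_subjects()] result.
#' @param which_split `"train"`, `"val"` or `"test"` (used with `split`).
#' @return An object of class `slice_dataset`: `images` (H x W x N array),
#'   `labels`, `subject_ids`, `slice_spec`, `split` tag.
#' @export
slice_dataset <- function(cohort, spec, split = NULL, which_split = NA_character_) {
  vols <- cohort
  if (!is.null(split)) {
    ids <- switch(which_split, train = split$train_ids, val = split$val_ids,
                  test = split$test_ids,
                  stop_param("which_split must be train/val/test when split given"))
    vols <- Filter(function(v) v$subject_id %in% ids, vols)
  }
  if (length(vols) == 0L) stop_param("no volumes selected for slice dataset")
  imgs <- lapply(vols, extract_slice, spec = spec)
  d2 <- dim(imgs[[1]])
  images <- array(unlist(imgs, use.names = FALSE), dim = c(d2, length(imgs)))
  structure(list(images = images,
                 labels = vapply(vols, `[[`, integer(1), "label"),
                 subject_ids = vapply(vols, `[[`, character(1), "subject_id"),
                 slice_spec = spec, split = which_split),
            class = "slice_dataset")
}

#' Extract cubic patches at a region for every scan
#'
#' @param cohort A `volume_cohort`.
#' @param box A [region_box()].
#' @param split,which_split As in [slice_dataset()].
#' @return List with `patches` (d1 x d2 x d3 x N array), `labels`,
#'   `subject_ids`.
#' @export
patch_dataset <- function(cohort, box, split = NULL, which_split = NA_character_) {
  vols <- cohort
  if (!is.null(split)) {
    ids <- switch(which_split, train = split$train_ids, val = split$val_ids,
                  test = split$test_ids,
                  stop_param("which_split must be train/val/test when split given"))
    vols <- Filter(function(v) v$subject_id %in% ids, vols)
  }
  if (length(vols) == 0L) stop_param("no volumes selected for patch dataset")
  idx <- lapply(1:3, function(d) (box$lo[d]:box$hi[d]) + 1L)
  side <- box$hi - box$lo + 1L
  patches <- array(NA_real_, c(side, length(vols)))
  for (i in seq_along(vols)) {
    if (any(box$hi > dim(vols[[i]]$voxels) - 1L) || any(box$lo < 0))
      stop_param("region box out of volume bounds")
    patches[, , , i] <- vols[[i]]$voxels[idx[[1]], idx[[2]], idx[[3]]]
  }
  list(patches = patches,
       labels = vapply(vols, `[[`, integer(1), "label"),
       subject_ids = vapply(vols, `[[`, character(1), "subject_id"))
}
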