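#' Axis-aligned 3D region (inclusive 0-based voxel ranges)
#'
#' @param lo,hi Integer triples of inclusive 0-based bounds, `hi >= lo`.
#'   Printed ranges such as "dim0: 78-101" are inclusive, so a side of 24
#'   voxels spans lo..lo+23.
#' @return An object of class `region_box`.
#' @export
region_box <- function(lo, hi) {
  lo <- as.integer(lo); hi <- as.integer(hi)
  if (length(lo) != 3L || length(hi) != 3L) stop_param("lo and hi must be triples")
  if (any(lo < 0L) || any(hi < lo)) stop_param("need 0 <= lo <= hi on every axis")
  structure(list(lo = lo, hi = hi), class = "region_box")
}

box_sides <- function(box) box$hi - box$lo + 1L

boxes_disjoint <- function(a, b) {
  any(a$hi < b$lo | b$hi < a$lo)
}

#' Intersection-over-union of two region boxes
#' @param a,b [region_box()] objects.
#' @return Scalar in [0, 1].
#' @export
box_iou <- function(a, b) {
  ilo <- pmax(a$lo, b$lo); ihi <- pmin(a$hi, b$hi)
  inter <- prod(pmax(0L, ihi - ilo + 1L))
  va <- prod(box_sides(a)); vb <- prod(box_sides(b))
  inter / (va + vb - inter)
}

#' Serialize / deserialize a region box as JSON
#'
#' The JSON records the inclusive 0-based coordinate convention explicitly.
#'
#' @param box A [region_box()].
#' @param path Output/input JSON path.
#' @return `write_region_box` returns `path` invisibly; `read_region_box`
#'   returns a [region_box()].
#' @export
write_region_box <- function(box, path) {
  stopifnot(inherits(box, "region_box"))
  jsonlite::write_json(list(lo = box$lo, hi = box$hi,
                            convention = "0-based inclusive voxel ranges"),
                       path, auto_unbox = FALSE)
  invisible(path)
}

#' @rdname write_region_box
#' @export
read_region_box <- function(path) {
  j <- jsonlite::read_json(path, simplifyVector = TRUE)
  region_box(j$lo, j$hi)
}

#' Re-center a box to a new side length
#'
#' Builds a cube of side `side` sharing the box's center, clamped to the
#' volume bounds (used e.g. to grow a localized candidate up to the 3D
#' classifier's minimum input size).
#'
#' @param box A [region_box()].
#' @param side New cube side.
#' @param volume_shape Integer triple bounding the result.
#' @return A [region_box()].
#' @export
box_recenter <- function(box, side, volume_shape) {
  if (any(side > volume_shape)) stop_param("side exceeds the volume extent")
  ctr <- (box$lo + box$hi) / 2
  lo <- round(ctr - (side - 1) / 2)
  lo <- pmax(0, pmin(lo, volume_shape - side))
  region_box(lo, lo + side - 1L)
}

#' Best-performing slice of a plane
#'
#' @param sweep A slice-sweep data frame with columns `plane`, `slice`,
#'   `mean_mcc` (as produced by [run_slice_sweep()]).
#' @param plane Plane to select within.
#' @return The 0-based slice index with the highest mean MCC; ties break to
#'   the lowest index.
#' @export
best_slice <- function(sweep, plane) {
  rows <- sweep[sweep$plane == plane, , drop = FALSE]
  if (nrow(rows) == 0L) stop_param("no sweep rows for plane ", plane)
  rows <- rows[order(rows$slice), , drop = FALSE]
  rows$slice[which.max(rows$mean_mcc)]
}

# map a 2D in-plane peak (0-based i, j over the two free axes) plus the
# plane's fixed slice index to full 3D coordinates (dim0, dim1, dim2)
peak_to_3d <- function(plane, i, j, slice_index) {
  switch(plane,
         sagittal = c(slice_index, i, j),
         coronal = c(i, slice_index, j),
         axial = c(i, j, slice_index))
}

# per-axis positions of the two free (peak-derived) coordinates of a plane
free_axes <- function(plane) switch(plane, sagittal = c(2L, 3L),
                                    coronal = c(1L, 3L), axial = c(1L, 2L))

#' Define the candidate 3D ROI from cross-plane attribution consensus
#'
#' Each plane's smoothed frequency map contributes a 2D attribution peak
#' (peripheral bands excluded, since they tend to reflect skull or
#' background rather than brain structure); the peak plus the plane's best
#' slice index gives a 3D coordinate. Every volume axis is the free axis of
#' exactly two planes, and the candidate center on that axis is the average
#' of those two independent peak estimates. A cube of side `roi_side` is
#' centered there and clamped to the volume bounds.
#'
#' @param freq_maps Named list (`sagittal`, `coronal`, `axial`) of
#'   [frequency_map()] objects computed on each plane's best slice.
#' @param best_slices Named integer vector of best 0-based slice indices.
#' @param volume_shape Integer triple.
#' @param roi_side Cube side in voxels (reference 24).
#' @param peripheral_margin Fraction of each map axis masked out at both
#'   ends before peak finding (default 0.1).
#' @return A [region_box()].
#' @export
define_candidate_roi <- function(freq_maps, best_slices, volume_shape,
                                 roi_side = 24L, peripheral_margin = 0.1) {
  if (any(roi_side > volume_shape))
    stop_param("roi_side exceeds the volume extent")
  est <- matrix(NA_real_, nrow = 3, ncol = 2)  # per axis, two estimates
  filled <- c(0L, 0L, 0L)
  for (plane in PLANES) {
    fm <- freq_maps[[plane]]
    if (is.null(fm)) stop_param("missing frequency map for plane ", plane)
    m <- fm$smoothed
    mh <- floor(peripheral_margin * nrow(m)); mw <- floor(peripheral_margin * ncol(m))
    sub <- m[(mh + 1):(nrow(m) - mh), (mw + 1):(ncol(m) - mw), drop = FALSE]
    if (max(sub) - min(sub) < 1e-9)
      stop_param("no consensus: attribution map for plane ", plane,
                 " is flat inside the peripheral mask")
    pk <- which(sub == max(sub), arr.ind = TRUE)[1, ]  # ties: lowest index
    i <- pk[1] - 1L + mh; j <- pk[2] - 1L + mw         # back to 0-based map coords
    ax <- free_axes(plane)
    for (k in 1:2) {
      coord <- c(i, j)[k]
      filled[ax[k]] <- filled[ax[k]] + 1L
      est[ax[k], filled[ax[k]]] <- coord
    }
  }
  center <- rowMeans(est)
  lo <- round(center - (roi_side - 1) / 2)
  lo <- pmax(0, pmin(lo, volume_shape - roi_side))
  region_box(lo, lo + roi_side - 1L)
}

#' Select a size-matched low-attribution negative control region
#'
#' Scans a stride-`stride` grid of candidate placements of a box with the
#' ROI's side lengths, keeping placements whose center lies inside the
#' brain mask and which are disjoint from the ROI, and returns the one
#' minimizing the mean smoothed attribution over its three plane-projected
#' 2D footprints.
#'
#' @param freq_maps Named list of [frequency_map()] objects as in
#'   [define_candidate_roi()].
#' @param roi The candidate [region_box()].
#' @param brain_mask Logical 3D array of in-brain voxels.
#' @param stride Candidate-grid stride in voxels (default 4).
#' @return A [region_box()] disjoint from `roi`.
#' @export
select_negative_control <- function(freq_maps, roi, brain_mask, stride = 4L) {
  shape <- dim(brain_mask)
  sides <- box_sides(roi)
  grid_axis <- function(d) unique(c(seq.int(0L, shape[d] - sides[d], by = stride),
                                    shape[d] - sides[d]))
  best <- NULL; best_score <- Inf
  for (x in grid_axis(1)) for (y in grid_axis(2)) for (z in grid_axis(3)) {
    lo <- c(x, y, z); hi <- lo + sides - 1L
    cand <- list(lo = lo, hi = hi)
    ctr <- floor((lo + hi) / 2) + 1L
    if (!brain_mask[ctr[1], ctr[2], ctr[3]]) next
    if (!boxes_disjoint(cand, roi)) next
    score <- 0
    for (plane in PLANES) {
      ax <- free_axes(plane)
      m <- freq_maps[[plane]]$smoothed
      ri <- (lo[ax[1]]:hi[ax[1]]) + 1L
      rj <- (lo[ax[2]]:hi[ax[2]]) + 1L
      ri <- ri[ri <= nrow(m)]; rj <- rj[rj <= ncol(m)]
      score <- score + mean(m[ri, rj])
    }
    score <- score / 3
    if (score < best_score) { best_score <- score; best <- cand }
  }
  if (is.null(best))
    stop_param("no feasible negative-control placement (mask too small or ",
               "ROI covers the whole grid)")
  structure(best, class = "region_box")
}

#' Validate the candidate ROI against the negative control
#'
#' Trains the lightweight 3D patch classifier independently on patches from
#' the ROI and from the control region under identical architecture,
#' training settings and data splits, over `n_repeats` seeded runs, and
#' compares the two MCC samples with a Welch t-test.
#'
#' @param cohort A `volume_cohort` (normalized as used for slice training).
#' @param split A [split_subjects()] result.
#' @param roi,control [region_box()] objects of identical side lengths.
#' @param cfg A [train_config()].
#' @param spec A [cnn2d_spec()] reused for the 3D trunk.
#' @param n_repeats Repeated runs per region.
#' @return List with per-region MCC samples, means/sds, the
#'   [two_sample_ttest()] report, and a `degenerate` flag marking regions
#'   whose patches are constant for every subject.
#' @export
roi_validation <- function(cohort, split, roi, control,
                           cfg = desk_train_config(), spec = cnn2d_spec(),
                           n_repeats = 3L) {
  if (!all(box_sides(roi) == box_sides(control)))
    stop_param("roi and control must have identical side lengths")
  run_region <- function(box, tag) {
    tr <- patch_dataset(cohort, box, split, "train")
    va <- patch_dataset(cohort, box, split, "val")
    te <- patch_dataset(cohort, box, split, "test")
    degenerate <- sd(tr$patches) == 0
    mccs <- vapply(seq_len(n_repeats), function(r) {
      res <- train_model(tr$patches, tr$labels, va$patches, va$labels,
                         te$patches, te$labels, cfg = cfg, spec = spec,
                         seed = derive_seed(cfg$seed, match(tag, c("roi", "control")), r),
                         subject_ids_test = te$subject_ids)
      prediction_metrics(res$test)$mcc
    }, numeric(1))
    list(mccs = mccs, degenerate = degenerate)
  }
  r <- run_region(roi, "roi")
  c_ <- run_region(control, "control")
  list(roi_mcc = r$mccs, control_mcc = c_$mccs,
       roi_mean = mean(r$mccs), roi_sd = sd(r$mccs),
       control_mean = mean(c_$mccs), control_sd = sd(c_$mccs),
       report = if (n_repeats >= 2L) two_sample_ttest(r$mccs, c_$mccs) else NULL,
       degenerate = c(roi = r$degenerate, control = c_$degenerate))
}
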