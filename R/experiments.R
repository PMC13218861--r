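# Provenance stamp attached to every experiment result: enough to re-run
# bit-identically on one platform.
run_provenance <- function(cfg) {
  list(config_hash = paste(vapply(cfg, function(v) paste(format(v), collapse = ","),
                                  character(1)), collapse = "|"),
       seed = cfg$seed,
       package_version = as.character(utils::packageVersion("slicemapr")),
       r_version = R.version.string)
}

#' Slice-wise performance sweep
#'
#' Trains an independent slice classifier for every (plane, slice index,
#' repeat) combination and tabulates mean and sd of test MCC, accuracy and
#' precision.
#'
#' @param cohort A (normalized) `volume_cohort`.
#' @param split A [split_subjects()] result.
#' @param slice_indices Named list per plane of 0-based indices, or `NULL`
#'   to use [sample_slice_indices()] with `target_count`.
#' @param cfg A [train_config()].
#' @param spec A [cnn2d_spec()].
#' @param n_repeats Repeats per slice.
#' @param target_count Approximate slices per plane when `slice_indices`
#'   is `NULL` (desk default 20; reference scale ~40).
#' @param planes Planes to sweep.
#' @return Data frame: plane, slice, mean_mcc, sd_mcc, mean_accuracy,
#'   sd_accuracy, mean_precision, sd_precision, n_repeats.
#' @export
run_slice_sweep <- function(cohort, split, slice_indices = NULL,
                            cfg = desk_train_config(), spec = cnn2d_spec(),
                            n_repeats = cfg$n_repeats, target_count = 20L,
                            planes = PLANES) {
  shape <- dim(cohort[[1]]$voxels)
  rows <- list()
  for (plane in planes) {
    idxs <- if (is.null(slice_indices)) {
      sample_slice_indices(shape[plane_axis(plane)], target_count)
    } else slice_indices[[plane]]
    for (s in idxs) {
      rep_res <- train_slice_repeats(cohort, slice_spec(plane, s), split,
                                     cfg, spec, n_repeats)
      runs <- rep_res$runs
      rows[[length(rows) + 1L]] <- data.frame(
        plane = plane, slice = s,
        mean_mcc = mean(runs$mcc), sd_mcc = sd(runs$mcc),
        mean_accuracy = mean(runs$accuracy), sd_accuracy = sd(runs$accuracy),
        mean_precision = mean(runs$precision), sd_precision = sd(runs$precision),
        n_repeats = n_repeats, stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  attr(out, "provenance") <- run_provenance(cfg)
  out
}

#' Signal-injection simulation study
#'
#' Applies identical training and evaluation to the original cohort and to
#' a copy with the localized signal injected, over slices spanning the
#' injected region and its flanks, and runs the energy-distance test on the
#' region's voxels before and after injection.
#'
#' @param cohort The original (unnormalized) `volume_cohort`.
#' @param injection An [injection_spec()].
#' @param split A [split_subjects()] result.
#' @param slice_indices Named list per plane (or single vector reused for
#'   all planes) of 0-based indices to evaluate.
#' @param cfg,spec,n_repeats Training settings as in [run_slice_sweep()].
#' @param injection_order `"normalize_then_inject"` (default) applies the
#'   corruption to modeling-ready (z-scored) intensities, so the change is
#'   strictly local to the region; `"inject_then_normalize"` corrupts raw
#'   intensities first, which lets the region's inflated statistics leak
#'   into every voxel through the per-volume z-score and makes off-region
#'   slices separable too.
#' @param energy_permutations Permutations for the energy-distance test.
#' @return List with `curves` (per plane/slice/condition mean and sd MCC),
#'   `energy_before`, `energy_after`.
#' @export
run_simulation_study <- function(cohort, injection, split, slice_indices,
                                 cfg = desk_train_config(), spec = cnn2d_spec(),
                                 n_repeats = cfg$n_repeats,
                                 injection_order = c("normalize_then_inject",
                                                     "inject_then_normalize"),
                                 energy_permutations = 499L) {
  injection_order <- match.arg(injection_order)
  if (injection_order == "normalize_then_inject") {
    cohort <- normalize_cohort(cohort)
    injected <- inject_signal(cohort, injection)
  } else {
    injected <- normalize_cohort(inject_signal(cohort, injection))
    cohort <- normalize_cohort(cohort)
  }
  region_vectors <- function(co) {
    box <- injection$region
    idx <- lapply(1:3, function(d) (box$lo[d]:box$hi[d]) + 1L)
    t(vapply(co, function(v) as.vector(v$voxels[idx[[1]], idx[[2]], idx[[3]]]),
             numeric(prod(box_sides(box)))))
  }
  labels <- vapply(cohort, `[[`, integer(1), "label")
  vb <- region_vectors(cohort); va <- region_vectors(injected)
  energy_before <- energy_distance_test(vb[labels == 1, ], vb[labels == 0, ],
                                        energy_permutations,
                                        seed = derive_seed(cfg$seed, 71L))
  energy_after <- energy_distance_test(va[labels == 1, ], va[labels == 0, ],
                                       energy_permutations,
                                       seed = derive_seed(cfg$seed, 72L))
  if (!is.list(slice_indices))
    slice_indices <- stats::setNames(rep(list(slice_indices), 3), PLANES)
  curves <- list()
  for (cond in c("original", "injected")) {
    co <- if (cond == "original") cohort else injected
    sw <- run_slice_sweep(co, split, slice_indices, cfg, spec, n_repeats)
    sw$condition <- cond
    curves[[cond]] <- sw
  }
  list(curves = do.call(rbind, curves),
       energy_before = energy_before, energy_after = energy_after,
       injection = injection, provenance = run_provenance(cfg))
}

#' Permute labels at the subject level
#'
#' Shuffles the binary labels across subjects (every scan of a subject
#' receives the subject's permuted label), preserving label counts exactly.
#'
#' @param cohort A `volume_cohort`.
#' @param seed Permutation seed.
#' @return The cohort with permuted labels.
#' @export
permute_labels <- function(cohort, seed = 1L) {
  ids <- unique(vapply(cohort, `[[`, character(1), "subject_id"))
  lab_of <- vapply(ids, function(id) {
    cohort[[match(id, vapply(cohort, `[[`, character(1), "subject_id"))]]$label
  }, integer(1))
  perm <- with_seed(seed, sample(lab_of))
  names(perm) <- ids
  out <- cohort
  for (i in seq_along(out)) out[[i]]$label <- perm[[out[[i]]$subject_id]]
  out
}

#' Label-permutation null study
#'
#' For each plane, retrains the slice classifier with subject-level
#' permuted labels under otherwise identical settings and compares the MCC
#' distribution over repeats against true-label training with a Welch
#' t-test; optionally repeats the comparison within each dual-threshold bin.
#'
#' @param cohort A (normalized) `volume_cohort`.
#' @param split A [split_subjects()] result.
#' @param slices Named vector of 0-based slice indices per plane (typically
#'   each plane's best slice).
#' @param cfg,spec Training settings.
#' @param n_repeats Repeats per condition.
#' @param threshold_pairs Optional dual-threshold grid for per-bin
#'   comparisons (`NULL` skips them).
#' @return Named list per plane: `report` (a [two_sample_ttest()]),
#'   `true_mcc`, `perm_mcc`, and `per_threshold` when requested.
#' @export
run_permutation_study <- function(cohort, split, slices,
                                  cfg = desk_train_config(), spec = cnn2d_spec(),
                                  n_repeats = cfg$n_repeats,
                                  threshold_pairs = NULL) {
  out <- list()
  for (plane in names(slices)) {
    sspec <- slice_spec(plane, slices[[plane]])
    true_preds <- list(); perm_preds <- list()
    for (r in seq_len(n_repeats)) {
      res_t <- train_slice_model(cohort, sspec, split, cfg, spec,
                                 seed = derive_seed(cfg$seed, 31L, plane_axis(plane), r))
      perm_co <- permute_labels(cohort, seed = derive_seed(cfg$seed, 37L, r))
      res_p <- train_slice_model(perm_co, sspec, split, cfg, spec,
                                 seed = derive_seed(cfg$seed, 31L, plane_axis(plane), r))
      true_preds[[r]] <- res_t$test
      perm_preds[[r]] <- res_p$test
    }
    true_mcc <- vapply(true_preds, function(p) prediction_metrics(p)$mcc, numeric(1))
    perm_mcc <- vapply(perm_preds, function(p) prediction_metrics(p)$mcc, numeric(1))
    entry <- list(report = two_sample_ttest(true_mcc, perm_mcc),
                  true_mcc = true_mcc, perm_mcc = perm_mcc)
    if (!is.null(threshold_pairs)) {
      per_thr <- lapply(seq_len(nrow(threshold_pairs)), function(i) {
        pair <- threshold_pairs[i, , drop = FALSE]
        tm <- vapply(true_preds, function(p) dual_threshold(p, threshold_pairs = pair)$mcc,
                     numeric(1))
        pm <- vapply(perm_preds, function(p) dual_threshold(p, threshold_pairs = pair)$mcc,
                     numeric(1))
        ok <- is.finite(tm) & is.finite(pm)
        list(lower = pair[1, 1], upper = pair[1, 2],
             report = if (sum(ok) >= 2) two_sample_ttest(tm[ok], pm[ok]) else NULL)
      })
      entry$per_threshold <- per_thr
    }
    out[[plane]] <- entry
  }
  attr(out, "provenance") <- run_provenance(cfg)
  out
}

#' Multi-slice fusion study
#'
#' Trains the three-trunk fusion classifier on each subject's three
#' best-performing slices and summarizes test metrics over repeats.
#'
#' @param cohort A (normalized) `volume_cohort`.
#' @param split A [split_subjects()] result.
#' @param best_slices Named vector (`sagittal`, `coronal`, `axial`) of
#'   0-based slice indices.
#' @param cfg,spec Training settings.
#' @param n_repeats Repeated runs.
#' @return List with `runs` (per-repeat metrics), `mean_mcc`, `sd_mcc`.
#' @export
run_fusion_study <- function(cohort, split, best_slices,
                             cfg = desk_train_config(), spec = cnn2d_spec(),
                             n_repeats = cfg$n_repeats) {
  get_inputs <- function(which_split) {
    ds <- lapply(PLANES, function(pl)
      slice_dataset(cohort, slice_spec(pl, best_slices[[pl]]), split, which_split))
    list(x = lapply(ds, `[[`, "images"), y = ds[[1]]$labels,
         ids = ds[[1]]$subject_ids)
  }
  tr <- get_inputs("train"); va <- get_inputs("val"); te <- get_inputs("test")
  runs <- lapply(seq_len(n_repeats), function(r) {
    res <- train_model(tr$x, tr$y, va$x, va$y, te$x, te$y, cfg = cfg,
                       spec = spec, seed = derive_seed(cfg$seed, 53L, r),
                       subject_ids_test = te$ids)
    m <- prediction_metrics(res$test)
    data.frame(repeat_id = r, mcc = m$mcc, accuracy = m$accuracy,
               precision = m$precision)
  })
  runs <- do.call(rbind, runs)
  list(runs = runs, mean_mcc = mean(runs$mcc), sd_mcc = sd(runs$mcc),
       provenance = run_provenance(cfg))
}

#' Correlate slice MCC with slice-level occlusion summaries
#'
#' @param sweep A [run_slice_sweep()] table.
#' @param summaries Data frame with columns `plane`, `slice`, `summary`
#'   (per-slice [slice_occlusion_summary()] values).
#' @return Named list per plane with `r` and `p` from [pearson_r()].
#' @export
run_mcc_attribution_correlation <- function(sweep, summaries) {
  out <- list()
  for (plane in unique(sweep$plane)) {
    a <- sweep[sweep$plane == plane, c("slice", "mean_mcc")]
    b <- summaries[summaries$plane == plane, c("slice", "summary")]
    m <- merge(a, b, by = "slice")
    if (nrow(m) < 3L) stop_param("need >= 3 slices with both quantities for ", plane)
    out[[plane]] <- pearson_r(m$mean_mcc, m$summary)
  }
  out
}

#' End-to-end localization on a cohort
#'
#' Convenience pipeline: slice sweep per plane, best-slice selection, one
#' final model per best slice, occlusion analysis on the test split, and
#' cross-plane ROI construction.
#'
#' @param cohort A (normalized) `volume_cohort`.
#' @param split A [split_subjects()] result.
#' @param slice_indices As in [run_slice_sweep()].
#' @param cfg,spec Training settings.
#' @param sweep_repeats Repeats per slice during the sweep.
#' @param occ_cfg An [occlusion_config()].
#' @param roi_side Candidate ROI side length.
#' @return List with `sweep`, `best_slices`, `freq_maps`, `roi`.
#' @export
run_localization <- function(cohort, split, slice_indices = NULL,
                             cfg = desk_train_config(), spec = cnn2d_spec(),
                             sweep_repeats = 1L, occ_cfg = occlusion_config(),
                             roi_side = 24L) {
  shape <- dim(cohort[[1]]$voxels)
  rows <- list(); models <- list()
  for (plane in PLANES) {
    idxs <- if (is.null(slice_indices)) {
      sample_slice_indices(shape[plane_axis(plane)], 20L)
    } else slice_indices[[plane]]
    for (s in idxs) {
      rep_res <- train_slice_repeats(cohort, slice_spec(plane, s), split,
                                     cfg, spec, sweep_repeats)
      runs <- rep_res$runs
      rows[[length(rows) + 1L]] <- data.frame(
        plane = plane, slice = s,
        mean_mcc = mean(runs$mcc), sd_mcc = sd(runs$mcc),
        mean_accuracy = mean(runs$accuracy), sd_accuracy = sd(runs$accuracy),
        mean_precision = mean(runs$precision), sd_precision = sd(runs$precision),
        n_repeats = sweep_repeats, stringsAsFactors = FALSE)
      models[[paste(plane, s)]] <- rep_res$last_result$model
    }
  }
  sweep <- do.call(rbind, rows)
  attr(sweep, "provenance") <- run_provenance(cfg)
  best <- vapply(PLANES, function(pl) best_slice(sweep, pl), numeric(1))
  freq_maps <- list()
  for (plane in PLANES) {
    # occlusion runs on the fixed trained model of the best slice (the
    # sweep's last-repeat model for that slice)
    sspec <- slice_spec(plane, best[[plane]])
    te <- slice_dataset(cohort, sspec, split, "test")
    occ <- occlusion_analysis(models[[paste(plane, best[[plane]])]], te, occ_cfg)
    freq_maps[[plane]] <- occ$freq
  }
  roi <- define_candidate_roi(freq_maps, best, shape, roi_side)
  list(sweep = sweep, best_slices = best, freq_maps = freq_maps, roi = roi)
}
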