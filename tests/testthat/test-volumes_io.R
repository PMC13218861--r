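test_that("extract_slice fixes the right axis and preserves axis order", {
  v <- array(0, c(3, 3, 3))
  for (i in 0:2) for (j in 0:2) for (k in 0:2)
    v[i + 1, j + 1, k + 1] <- 100 * i + 10 * j + k
  img <- extract_slice(v, slice_spec("sagittal", 1))
  expect_equal(img, outer(0:2 * 10, 0:2, "+") + 100)
  expect_equal(extract_slice(v, slice_spec("coronal", 2))[1, 3], 0 + 20 + 2)
  expect_equal(extract_slice(v, slice_spec("axial", 0))[2, 3], 100 + 20)
  expect_error(extract_slice(v, slice_spec("axial", 3)), "out of range")
})

test_that("slice/stack round-trip is lossless for every plane", {
  v <- slicemapr:::with_seed(5, array(rnorm(4 * 5 * 6), c(4, 5, 6)))
  for (plane in c("sagittal", "coronal", "axial")) {
    ax <- slicemapr:::plane_axis(plane)
    slices <- lapply(seq_len(dim(v)[ax]) - 1L,
                     function(i) extract_slice(v, slice_spec(plane, i)))
    expect_identical(stack_slices(slices, plane), v)
  }
})

test_that("sample_slice_indices is deterministic and denser centrally", {
  s <- sample_slice_indices(64, 20)
  expect_identical(s, sample_slice_indices(64, 20))
  expect_true(all(diff(s) > 0))
  expect_gte(min(s), 2)
  expect_lte(max(s), 61)
  expect_true(abs(length(s) - 20) <= 4)        # within +-20%
  central <- s[s >= 16 & s < 48]
  peripheral_spacings <- c(diff(s[s < 16]), diff(s[s >= 48]))
  expect_lte(median(diff(central)), median(peripheral_spacings))
  # degenerate: margins make the request infeasible
  expect_error(sample_slice_indices(40, 40), "margins")
  expect_identical(sample_slice_indices(40, 40, fallback = "full"), 0:39)
  expect_error(sample_slice_indices(64, 2), ">= 3")
})

test_that("split_subjects follows largest-remainder rounding", {
  ids <- sprintf("s%04d", 1:2258)
  sp <- split_subjects(ids, seed = 3)
  sizes <- c(length(sp$train_ids), length(sp$val_ids), length(sp$test_ids))
  expect_equal(sum(sizes), 2258)
  expect_true(all(abs(sizes - 2258 * c(0.64, 0.16, 0.20)) <= 1))
  sp10 <- split_subjects(sprintf("x%02d", 1:10), seed = 1)
  expect_equal(c(length(sp10$train_ids), length(sp10$val_ids),
                 length(sp10$test_ids)), c(6, 2, 2))
})

test_that("splitting is a reproducible partition without leakage", {
  ids <- sprintf("p%03d", 1:37)
  for (seed in 1:5) {
    sp <- split_subjects(ids, seed = seed)
    expect_length(intersect(sp$train_ids, sp$val_ids), 0)
    expect_length(intersect(sp$train_ids, sp$test_ids), 0)
    expect_length(intersect(sp$val_ids, sp$test_ids), 0)
    expect_setequal(c(sp$train_ids, sp$val_ids, sp$test_ids), ids)
    expect_identical(sp, split_subjects(ids, seed = seed))
  }
  expect_error(split_subjects(ids, ratios = c(0.9, 0.2, 0.1)), "summing to 1")
  expect_error(split_subjects(c("a", "b")), "at least 3")
})

test_that("scans of one subject always share a split", {
  co <- tiny_cohort(n = 6, shape = 16)
  # add a second scan for subject 2
  extra <- co[[2]]; extra$scan_id <- "sub0002_scan2"
  co <- structure(c(co, list(extra)), class = "volume_cohort")
  sp <- split_subjects(cohort_ids(co), seed = 2)
  tags <- vapply(co, function(v) slicemapr:::split_of(sp, v$subject_id), "")
  expect_equal(tags[2], tags[7])
})

test_that("cohort writes to NIfTI + manifest and reads back", {
  co <- tiny_cohort(n = 4, shape = 16)
  sp <- split_subjects(cohort_ids(co), seed = 1)
  d <- withr::local_tempdir()
  write_cohort(co, d, split = sp)
  m <- utils::read.csv(file.path(d, "manifest.csv"))
  expect_setequal(names(m), c("subject_id", "scan_id", "label", "path", "split"))
  expect_setequal(m$split, c("train", "val", "test"))
  rc <- read_cohort(d)
  expect_equal(rc[[3]]$voxels, co[[3]]$voxels, tolerance = 1e-6)
  expect_equal(cohort_labels(rc), cohort_labels(co))
})

test_that("nifti io round-trips both precisions and rejects junk", {
  v <- slicemapr:::with_seed(8, array(rnorm(5 * 6 * 7), c(5, 6, 7)))
  p32 <- withr::local_tempfile(fileext = ".nii.gz")
  p64 <- withr::local_tempfile(fileext = ".nii")
  write_nifti(v, p32)
  write_nifti(v, p64, datatype = "float64")
  expect_equal(read_nifti(p32), v, tolerance = 1e-6)
  expect_identical(read_nifti(p64), v)
  bad <- withr::local_tempfile(fileext = ".nii")
  writeBin(raw(100), bad)
  expect_error(read_nifti(bad), "NIfTI")
})
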