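test_that("NIfTI round trip preserves intensities and geometry", {
  set.seed(21)
  v <- native_volume(array(rnorm(9 * 11 * 7, 30, 12), c(9, 11, 7)),
                     spacing = c(0.5, 0.5, 1.2), orientation = "LPS",
                     origin = c(3, -4, 10))
  f <- withr::local_tempfile(fileext = ".nii.gz")
  write_nifti(v, f)
  r <- read_nifti(f)
  expect_equal(r$intensities, v$intensities, tolerance = 1e-12)
  expect_equal(r$orientation, "LPS")
  expect_equal(r$spacing, v$spacing, tolerance = 1e-6)
  expect_equal(r$origin, v$origin, tolerance = 1e-6)
})

test_that("label volumes round-trip with integer storage and validate values", {
  set.seed(22)
  lab <- array(sample(0:12, 5^3, TRUE), c(5, 5, 5))
  lv <- label_volume(lab)
  f <- withr::local_tempfile(fileext = ".nii")
  write_nifti(lv, f)
  r <- read_nifti(f, as = "labels")
  expect_identical(r$labels, lv$labels)
  # per-class counts preserved exactly
  expect_equal(tabulate(r$labels + 1L, 13), tabulate(lv$labels + 1L, 13))

  expect_error(label_volume(array(13L, c(2, 2, 2))), "0\\.\\.12")
  bad <- withr::local_tempfile(fileext = ".nii")
  write_nifti(native_volume(array(13, c(2, 2, 2)), c(1, 1, 1)), bad)
  expect_error(read_nifti(bad, as = "labels"), "0\\.\\.12")

  f4 <- withr::local_tempfile(fileext = ".nii")
  RNifti::writeNifti(RNifti::asNifti(array(0, c(3, 3, 3, 2))), f4)
  expect_error(read_nifti(f4), "3D")

  # background-only label volume reads back all zero
  f0 <- withr::local_tempfile(fileext = ".nii")
  write_nifti(label_volume(array(0L, c(4, 4, 4))), f0)
  expect_true(all(read_nifti(f0, as = "labels")$labels == 0L))
})

test_that("YOLO label files are an exact 6-decimal inverse", {
  full <- detection_table(2L, 0L, 0.5, 0.5, 1, 1, 1)
  f <- withr::local_tempfile()
  write_yolo_labels(full, f)
  expect_equal(readLines(f), "2 0.500000 0.500000 1.000000 1.000000")

  set.seed(33)
  n <- 50
  det <- detection_table(
    class_id = sample(0:11, n, TRUE), z_index = 7L,
    cx = runif(n, 0.2, 0.8), cy = runif(n, 0.2, 0.8),
    w = runif(n, 0.01, 0.3), h = runif(n, 0.01, 0.3),
    confidence = runif(n)
  )
  write_yolo_labels(det, f, predictions = TRUE)
  back <- read_yolo_labels(f, z_index = 7L)
  for (col in c("cx", "cy", "w", "h", "confidence")) {
    expect_lt(max(abs(back[[col]] - det[[col]])), 1e-6 + 1e-12)
  }
  expect_equal(back$class_id, det$class_id)

  write_yolo_labels(detection_table(), f)
  expect_equal(nrow(read_yolo_labels(f)), 0L)

  expect_error(detection_table(12L, 0L, .5, .5, .1, .1, 1), "class id")
  expect_error(detection_table(1L, 0L, 1.5, .5, .1, .1, 1), "\\[0,1\\]")
  expect_equal(yolo_label_filename("ct", 7L), "ct_z007.txt")
})

test_that("boxes_from_mask produces tight per-class per-slice boxes", {
  lab <- array(0L, c(256, 256, 3))
  lab[124:133, 119:138, 2] <- 5L   # class 4: 10 x 20 rectangle, centered
  bx <- boxes_from_mask(label_volume(lab))
  expect_equal(nrow(bx), 1L)
  expect_equal(bx$class_id, 4L)
  expect_equal(bx$z_index, 1L)
  expect_equal(bx$cx, 0.5)
  expect_equal(bx$cy, 0.5)
  expect_equal(bx$w, 10 / 256)
  expect_equal(bx$h, 20 / 256)
  expect_equal(bx$confidence, 1)

  # two disjoint blobs of one class merge to a single spanning box
  lab2 <- array(0L, c(64, 64, 1))
  lab2[5:10, 5:10, 1] <- 3L
  lab2[40:45, 50:55, 1] <- 3L
  b2 <- boxes_from_mask(label_volume(lab2))
  expect_equal(nrow(b2), 1L)
  expect_equal(b2$w * 64, 45 - 5 + 1)
  expect_equal(b2$h * 64, 55 - 5 + 1)

  expect_equal(nrow(boxes_from_mask(label_volume(array(0L, c(8, 8, 8))))), 0L)
})

test_that("boxes always contain all class voxels on their slice", {
  ph <- desk_cohort(2)[[1]]
  lv <- ph$labels
  bx <- boxes_from_mask(lv)
  d <- dim(lv$labels)
  # exhaustive containment + per-slice class presence equals box count
  for (z in unique(bx$z_index)) {
    sl <- lv$labels[, , z + 1L]
    present <- sort(setdiff(unique(as.integer(sl)), 0L)) - 1L
    bz <- bx[bx$z_index == z, ]
    expect_setequal(bz$class_id, present)
    for (i in seq_len(nrow(bz))) {
      idx <- which(sl == bz$class_id[i] + 1L, arr.ind = TRUE)
      x0 <- (bz$cx[i] - bz$w[i] / 2) * d[1]
      x1 <- (bz$cx[i] + bz$w[i] / 2) * d[1]
      y0 <- (bz$cy[i] - bz$h[i] / 2) * d[2]
      y1 <- (bz$cy[i] + bz$h[i] / 2) * d[2]
      expect_true(all(idx[, 1] - 1 >= x0 - 1e-9 & idx[, 1] <= x1 + 1e-9))
      expect_true(all(idx[, 2] - 1 >= y0 - 1e-9 & idx[, 2] <= y1 + 1e-9))
    }
  }
})

test_that("DICOM series reading sorts by position and rescales to HU", {
  dir <- withr::local_tempdir()
  write_test_series(dir, n_slices = 6, gap = 1.2, pixel_spacing = c(0.45, 0.45))
  v <- read_dicom_series(dir)
  expect_equal(dim(v$intensities), c(8, 8, 6))
  expect_equal(v$spacing, c(0.45, 0.45, 1.2), tolerance = 1e-9)
  # slice k stores HU = 10 * k after slope/intercept rescale
  expect_equal(v$intensities[1, 1, ], 10 * (1:6))
  expect_equal(v$orientation, "LPS")

  # file-name permutation must not matter
  dir2 <- withr::local_tempdir()
  write_test_series(dir2, n_slices = 6, gap = 1.2, shuffle_names = TRUE)
  v2 <- read_dicom_series(dir2)
  expect_identical(v2$intensities, v$intensities)
})

test_that("DICOM reader rejects mixed series and non-uniform spacing", {
  dir <- withr::local_tempdir()
  write_test_series(dir, n_slices = 3)
  write_test_dicom(file.path(dir, "other.dcm"), matrix(0, 8, 8),
                   ipp = c(0, 0, 99), series_uid = "5.5.5")
  expect_error(read_dicom_series(dir), "multiple series")

  dir2 <- withr::local_tempdir()
  for (i in 1:4) {
    z <- c(0, 1.2, 2.4, 4.5)[i]   # last gap 75% larger
    write_test_dicom(file.path(dir2, sprintf("s%d.dcm", i)),
                     matrix(1000, 8, 8), ipp = c(0, 0, z))
  }
  expect_error(read_dicom_series(dir2), "non-uniform slice spacing")
})
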