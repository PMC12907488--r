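test_that("backsampling inverts pad-only crops bit-exactly", {
  ph <- desk_cohort(2)[[1]]
  lc <- resample_labels(ph$labels, resample_canonical(ph$image, grid = 64))
  boxes <- boxes_from_mask(lc)
  preds <- lapply(seq_len(nrow(boxes)), function(i) {
    det <- boxes[i, ]
    msk <- (lc$labels[, , det$z_index + 1L] == det$class_id + 1L) * 1
    cr <- crop_pad_resize(msk, det, factor = 3, target = 64, mode = "pad",
                          interp = "nearest", class_id = det$class_id,
                          z_index = det$z_index)
    list(mask = cr$patch, transform = cr$transform)
  })
  fused <- backsample(preds, grid = 64)
  expect_identical(fused$labels, lc$labels)
  expect_equal(attr(fused, "contested"), 0L)

  # duplicate (class, slice) predictions are rejected
  expect_error(backsample(c(preds, preds[1])), "conflicting ROI")
  # empty prediction set gives an all-background volume
  empty <- backsample(list(), grid = 16)
  expect_true(all(empty$labels == 0L))
})

test_that("overlap fusion assigns contested voxels by rarity priority", {
  mk <- function() array(0L, c(8, 8, 2))
  vols <- replicate(12, mk(), simplify = FALSE)
  atrium <- subregion_id("right_atrium")
  body <- subregion_id("body_right_lateral")
  vols[[body + 1L]][2:6, 2:6, 1] <- 1L
  vols[[atrium + 1L]][4:7, 4:7, 1] <- 1L   # overlaps the body by 3x3
  fused <- fuse_overlaps(vols)
  # contested voxels go to the atrium (smaller structure wins)
  expect_true(all(fused$labels[4:6, 4:6, 1] == atrium + 1L))
  expect_true(all(fused$labels[2:3, 2:3, 1] == body + 1L))
  expect_equal(attr(fused, "contested"), 9L)
  # brute-force overlap count
  brute <- sum(vols[[body + 1L]] & vols[[atrium + 1L]])
  expect_equal(attr(fused, "contested"), brute)

  # disjoint inputs: union with no contested voxels
  vols2 <- replicate(12, mk(), simplify = FALSE)
  vols2[[1]][1:2, 1:2, 1] <- 1L
  vols2[[5]][5:6, 5:6, 2] <- 1L
  f2 <- fuse_overlaps(vols2)
  expect_equal(attr(f2, "contested"), 0L)
  expect_equal(sum(f2$labels != 0), 8)
})

test_that("volumetry converts counts to ml and groups add up exactly", {
  lab <- array(0L, c(20, 20, 20))
  lab[1:10, 1:10, 1:10] <- 2L           # 1000 voxels of class 1
  lv <- label_volume(lab, frame = "canonical", spacing = c(1, 1, 1))
  rep <- compute_volumes(lv)
  expect_equal(unname(rep$per_class_ml["body_left_lateral"]), 1.0)
  expect_equal(unname(rep$groups_ml["whole_system"]), sum(rep$per_class_ml))

  set.seed(81)
  lab2 <- array(sample(0:12, 15^3, TRUE), c(15, 15, 15))
  rep2 <- compute_volumes(label_volume(lab2, "canonical", c(1, 1, 1)))
  g <- subregion_groups()
  for (nm in names(g)) {
    expect_equal(unname(rep2$groups_ml[nm]), sum(rep2$per_class_ml[g[[nm]] + 1L]))
  }
  # non-unit spacing scales the voxel volume
  rep3 <- compute_volumes(label_volume(lab, "native", c(0.5, 0.5, 2)))
  expect_equal(unname(rep3$per_class_ml["body_left_lateral"]), 1000 * 0.5 / 1000)
  expect_error(compute_volumes(label_volume(lab), spacing = c(0, 1, 1)), "spacing")
})

test_that("digital ellipsoid volume matches the closed form within 3%", {
  g <- 64L
  co <- (0:(g - 1)) - (g - 1) / 2
  E <- array(
    outer(outer((co / 20)^2, (co / 15)^2, "+"), (co / 10)^2, "+"),
    c(g, g, g)
  )
  lab <- array(0L, c(g, g, g))
  lab[E <= 1] <- 1L
  rep <- compute_volumes(label_volume(lab, "canonical", c(1, 1, 1)))
  analytic <- 4 / 3 * pi * 20 * 15 * 10 / 1000
  expect_lt(abs(unname(rep$per_class_ml[1]) / analytic - 1), 0.03)
})

test_that("relative volumetric error is signed and missing at zero reference", {
  expect_equal(relative_volumetric_error(11, 10), 0.1)
  expect_equal(relative_volumetric_error(10, 10), 0)
  expect_equal(relative_volumetric_error(9, 10), -0.1)
  expect_true(is.na(relative_volumetric_error(1, 0)))

  # report with reference: per-entry RVE and NA propagation
  lab <- array(0L, c(10, 10, 10)); lab[1:5, 1:5, 1:4] <- 1L
  ref <- array(0L, c(10, 10, 10)); ref[1:5, 1:5, 1:5] <- 1L
  rp <- compute_volumes(label_volume(lab, "canonical"),
                        reference = label_volume(ref, "canonical"))
  expect_equal(unname(rp$rve$per_class["body_right_lateral"]), -0.2)
  expect_true(is.na(rp$rve$per_class[["third_ventricle"]]))
})

test_that("volume reports serialize to JSON and CSV", {
  lab <- array(0L, c(10, 10, 10)); lab[1:5, 1:5, 1:4] <- 1L
  rp <- compute_volumes(label_volume(lab, "canonical"))
  stem <- file.path(withr::local_tempdir(), "volumes")
  write_volume_report(rp, stem)
  j <- jsonlite::read_json(paste0(stem, ".json"), simplifyVector = TRUE)
  expect_equal(j$per_class_ml$body_right_lateral, 0.1)
  csv <- utils::read.csv(paste0(stem, ".csv"))
  expect_equal(nrow(csv), 16L)  # 12 classes + 4 groups
})
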