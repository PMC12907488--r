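test_that("Dice and Jaccard match direct voxel counting", {
  a <- array(0, c(4, 4, 1)); a[1:2, 1:2, 1] <- 1       # |A| = 4
  b <- array(0, c(4, 4, 1)); b[1:4, 1:2, 1] <- 1       # |B| = 8, overlap 4
  expect_equal(dice(a, b), 2 * 4 / 12, ignore_attr = TRUE)
  expect_equal(jaccard(a, b), 4 / 8, ignore_attr = TRUE)
  expect_equal(jaccard(a, b), dice(a, b) / (2 - dice(a, b)), ignore_attr = TRUE)

  expect_equal(as.numeric(dice(a, a)), 1)
  d0 <- dice(a, 1 - a)  # complements share no voxel
  expect_equal(as.numeric(d0), 0)
  e <- array(0, c(3, 3, 3))
  expect_equal(as.numeric(dice(e, e)), 1)
  expect_true(isTRUE(attr(dice(e, e), "both_empty")))
  expect_error(dice(a, array(0, c(5, 5, 1))), "mismatch")
  # symmetry
  expect_equal(as.numeric(dice(a, b)), as.numeric(dice(b, a)))
  expect_equal(as.numeric(jaccard(a, b)), as.numeric(jaccard(b, a)))
})

test_that("the Dice/Jaccard identity holds to 1e-12 on random pairs", {
  set.seed(71)
  for (i in 1:500) {
    a <- array(rbinom(64, 1, 0.4), c(4, 4, 4))
    b <- array(rbinom(64, 1, 0.4), c(4, 4, 4))
    d <- as.numeric(dice(a, b))
    j <- as.numeric(jaccard(a, b))
    expect_lt(abs(j - d / (2 - d)), 1e-12)
  }
})

test_that("HD95 agrees with an exhaustive all-pairs oracle", {
  m1 <- array(0, c(8, 8, 8)); m1[2, 2, 2] <- 1
  m2 <- array(0, c(8, 8, 8)); m2[5, 2, 2] <- 1
  expect_equal(hausdorff95(m1, m2, c(1, 1, 1)), 3)
  expect_equal(hausdorff95(m1, m1, c(1, 1, 1)), 0)
  expect_true(is.na(hausdorff95(m1, array(0, c(8, 8, 8)), c(1, 1, 1))))

  set.seed(72)
  for (i in 1:30) {
    a <- random_blob(c(8, 8, 8), seed = 1000 + i)
    b <- random_blob(c(8, 8, 8), seed = 2000 + i)
    sp <- c(0.7, 1, 1.4)
    expect_equal(hausdorff95(a, b, sp), oracle_hd95(a, b, sp), tolerance = 1e-9)
    # symmetric by construction
    expect_equal(hausdorff95(a, b, sp), hausdorff95(b, a, sp), tolerance = 1e-12)
  }
})

test_that("greedy matching follows confidence order and single-use GT", {
  gt <- detection_table(1L, 0L, 0.5, 0.5, 0.3, 0.3, 1)
  p1 <- detection_table(1L, 0L, 0.52, 0.5, 0.3, 0.3, 0.8)
  expect_gte(box_iou(gt, p1), 0.7)
  mt <- match_detections(gt, p1, 0.5)
  expect_equal(mt$tp, 1L)

  # two predictions on one GT: higher confidence wins, other is FP
  p2 <- rbind(p1, detection_table(1L, 0L, 0.49, 0.5, 0.3, 0.3, 0.9))
  mt2 <- match_detections(gt, p2, 0.5)
  expect_equal(mt2$tp, 1L)
  expect_equal(mt2$fp, 1L)
  expect_true(mt2$matches$is_tp[1])           # confidence 0.9 row first
  expect_equal(mt2$matches$confidence[1], 0.9)
  # input order does not matter
  mt3 <- match_detections(gt, p2[2:1, ], 0.5)
  expect_equal(mt3$matches$is_tp, mt2$matches$is_tp)
})

test_that("average precision equals the PR enumeration oracle", {
  # constructed case: confidences 0.9 (TP), 0.8 (FP), 0.7 (TP); n_gt = 2
  m <- data.frame(confidence = c(0.9, 0.8, 0.7), is_tp = c(TRUE, FALSE, TRUE))
  expect_equal(average_precision(m, 2), oracle_ap(m$is_tp, 2))
  expect_equal(average_precision(m, 2), 0.5 * 1 + 0.5 * (2 / 3))

  expect_equal(average_precision(m[0, ], 3), 0)
  expect_true(is.na(average_precision(m, 0)))
  single <- data.frame(confidence = 0.9, is_tp = TRUE)
  expect_equal(average_precision(single, 1), 1)

  set.seed(73)
  for (i in 1:40) {
    k <- sample(1:5, 1)
    flags <- as.logical(rbinom(k, 1, 0.6))
    n_gt <- max(sum(flags), sample(1:5, 1))
    mm <- data.frame(confidence = sort(runif(k), decreasing = TRUE), is_tp = flags)
    expect_equal(average_precision(mm, n_gt), oracle_ap(flags, n_gt),
                 tolerance = 1e-12)
  }
})

test_that("the oracle detector scores perfectly against its own labels", {
  ph <- desk_cohort(2)[[2]]
  cv <- resample_canonical(ph$image, grid = 64)
  lc <- resample_labels(ph$labels, cv)
  gt <- boxes_from_mask(lc)
  sc <- det_scores(gt, gt)
  all_row <- sc[sc$name == "all", ]
  expect_equal(all_row$precision, 1)
  expect_equal(all_row$recall, 1)
  expect_equal(all_row$ap50, 1)
  expect_equal(all_row$ap50_95, 1)
  expect_equal(map50_95(gt, gt), 1)
  # self-scored segmentation: perfect overlap, zero boundary distance
  body <- lc$labels == 1L
  sc2 <- seg_score(body, body, c(1, 1, 1))
  expect_equal(sc2$dice, 1)
  expect_equal(sc2$jaccard, 1)
  expect_equal(sc2$hd95, 0)
})
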