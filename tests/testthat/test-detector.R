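test_that("the oracle detector reproduces ground-truth boxes exactly", {
  ph <- desk_cohort(2)[[1]]
  cv <- resample_canonical(ph$image, grid = 64)
  lc <- resample_labels(ph$labels, cv)
  gt <- boxes_from_mask(lc)
  model <- oracle_detector(lc)
  cfg <- detector_config(image_size = 64)
  sls <- slice_axial(cv)
  z_busy <- gt$z_index[which.max(table(gt$z_index))[1]]
  d <- detect(sls[[z_busy + 1L]], model, cfg)
  ref <- gt[gt$z_index == z_busy, ]
  expect_equal(nrow(d), nrow(ref))
  expect_equal(d$class_id, ref$class_id)
  expect_equal(d[, c("cx", "cy", "w", "h")], ref[, c("cx", "cy", "w", "h")],
               ignore_attr = TRUE)
  # empty slice -> empty list
  z_empty <- setdiff(0:63, gt$z_index)[1]
  expect_equal(nrow(detect(sls[[z_empty + 1L]], model, cfg)), 0L)
})

test_that("NMS keeps the best box, is order-invariant, respects thresholds", {
  two <- detection_table(
    class_id = c(3L, 3L), z_index = 0L,
    cx = c(0.50, 0.52), cy = c(0.5, 0.5), w = c(0.2, 0.2), h = c(0.2, 0.2),
    confidence = c(0.9, 0.7)
  )
  expect_gt(box_iou(two[1, ], two[2, ]), 0.6)
  kept <- nms(two, iou_threshold = 0.6)
  expect_equal(nrow(kept), 1L)
  expect_equal(kept$confidence, 0.9)
  expect_identical(nms(two[2:1, ], 0.6), kept)

  # different classes are never suppressed against each other
  mixed <- two
  mixed$class_id <- c(3L, 4L)
  expect_equal(nrow(nms(mixed, 0.6)), 2L)

  # confidence threshold removes sub-threshold candidates in detect()
  lc <- label_volume(array(0L, c(64, 64, 2)), frame = "canonical")
  model <- oracle_detector(lc)
  low <- detection_table(1L, 0L, 0.5, 0.5, 0.2, 0.2, 0.0005)
  model$boxes <- low
  cfg <- detector_config(image_size = 64)  # confidence threshold 0.001
  expect_equal(nrow(detect(matrix(0, 64, 64), model, cfg, z_index = 0L)), 0L)
})

test_that("built-in detector training obeys the contract on a tiny problem", {
  set.seed(5)
  n_sl <- 8
  slices <- lapply(seq_len(n_sl), function(i) {
    m <- matrix(0.45 + rnorm(32 * 32, 0, 0.02), 32, 32)
    m[10:17, 12:21] <- 0.1
    pmin(pmax(m, 0), 1)
  })
  gt <- do.call(rbind, lapply(seq_len(n_sl) - 1L, function(z) {
    detection_table(0L, z, cx = 13.5 / 32, cy = 16.5 / 32, w = 8 / 32, h = 10 / 32, 1)
  }))
  cfg <- detector_config(epochs = 12, batch_size = 4, image_size = 32,
                         model_size = 32, learning_rate = 2e-3, pos_weight = 8,
                         seed = 2, augmentation = list(flip = FALSE))
  expect_warning(m <- train_detector(slices, gt, cfg), "never predictable")
  # loss decreases over training (logged trace)
  expect_lt(tail(m$history, 1), m$history[1])
  # detections satisfy the Detection contract and fit in the slice
  d <- detect(structure(slices[[1]], z_index = 0L), m, cfg, top1 = FALSE)
  if (nrow(d) > 0) {
    ventriseg:::validate_detections(d)
    expect_true(all(d$cx - d$w / 2 >= -1e-9 & d$cx + d$w / 2 <= 1 + 1e-9))
    expect_true(all(d$cy - d$h / 2 >= -1e-9 & d$cy + d$h / 2 <= 1 + 1e-9))
  }
  # seeded retraining is identical
  m2 <- suppressWarnings(train_detector(slices, gt, cfg))
  expect_equal(m$history, m2$history, tolerance = 1e-14)
  expect_identical(m$level_frac, m2$level_frac)
})

test_that("left/right confusion diagnostic reports a rate", {
  gt <- detection_table(
    class_id = c(0L, 1L), z_index = 0L,
    cx = c(0.6, 0.4), cy = 0.5, w = 0.15, h = 0.15, confidence = 1
  )
  # one prediction on the wrong side: matches the mirror class's box
  pred <- detection_table(0L, 0L, cx = 0.4, cy = 0.5, w = 0.15, h = 0.15, 0.9)
  rep <- lr_confusion_rate(gt, pred)
  expect_equal(rep$n_pred, 1L)
  expect_equal(rep$n_confused, 1L)
  expect_equal(rep$rate, 1)
})
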