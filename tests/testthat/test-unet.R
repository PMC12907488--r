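test_that("U-Net construction follows the doubling rule and preserves shape", {
  cfg <- seg_config(start_filters = 32, depth = 3, blocks_per_level = 2,
                    patch = 32, epochs = 1, desk = TRUE)
  m <- build_unet(cfg)
  convs <- Filter(function(nd) nd$op == "conv3", m$tape$nodes)
  # bottleneck filter count = start * 2^depth
  expect_equal(max(vapply(convs, function(nd) as.integer(nd$cout), 0L)), 32L * 2L^3L)
  # output is single-channel at input shape
  patch <- matrix(runif(32 * 32), 32, 32)
  pm <- predict_mask(m, patch)
  expect_equal(dim(pm), c(32L, 32L))
  expect_true(all(pm %in% c(0, 1)))
  # same seed -> identical initial predictions
  m2 <- build_unet(cfg)
  expect_equal(predict_prob(m, patch), predict_prob(m2, patch), tolerance = 1e-15)
  expect_error(seg_config(depth = 3, patch = 50, desk = TRUE), "divisible")
  # production range checks active without desk mode
  expect_error(seg_config(start_filters = 16), "start_filters")
})

test_that("fold splits are subject-level, disjoint, exhaustive, reproducible", {
  f <- fold_split(1:80, k = 5, seed = 11)
  expect_length(f, 5L)
  expect_equal(unname(lengths(f)), rep(16L, 5))
  expect_setequal(unlist(f), 1:80)
  for (i in 1:4) for (j in (i + 1):5) {
    expect_length(intersect(f[[i]], f[[j]]), 0L)
  }
  expect_identical(f, fold_split(1:80, k = 5, seed = 11))
  expect_false(identical(f, fold_split(1:80, k = 5, seed = 12)))
  expect_error(fold_split(1:3, k = 5), "fewer subjects")
  # uneven sizes differ by at most one
  f2 <- fold_split(1:13, k = 5, seed = 2)
  expect_lte(diff(range(lengths(f2))), 1L)
})

test_that("augmentation applies shared geometry and patch-only brightness", {
  set.seed(8)
  patch <- matrix(runif(48 * 48), 48, 48)
  mask <- disk_mask(48, 20, 25, 8)
  # forced flip is an involution
  a1 <- augment(patch, mask, force = list(flip = TRUE, shift = c(0, 0),
                                          rot = 0, bright = 1))
  a2 <- augment(a1$patch, a1$mask, force = list(flip = TRUE, shift = c(0, 0),
                                                rot = 0, bright = 1))
  expect_equal(a2$patch, patch)
  expect_equal(a2$mask, mask)
  # interior shift preserves mask voxel count
  a3 <- augment(patch, mask, force = list(flip = FALSE, shift = c(3, -2),
                                          rot = 0, bright = 1))
  expect_equal(sum(a3$mask), sum(mask))
  # brightness scales the patch only, clipped to [0, 1]
  a4 <- augment(matrix(0.5, 16, 16), disk_mask(16, 8, 8, 3),
                force = list(flip = FALSE, shift = c(0, 0), rot = 0, bright = 1.2))
  expect_equal(unique(as.vector(a4$patch)), 0.6)
  expect_equal(a4$mask, disk_mask(16, 8, 8, 3))
  # same seed, same draw
  expect_equal(augment(patch, mask, seed = 5), augment(patch, mask, seed = 5))
})

test_that("training rejects empty masks and is seed-reproducible", {
  patches <- replicate(6, matrix(runif(16 * 16), 16, 16), simplify = FALSE)
  zeros <- replicate(6, matrix(0, 16, 16), simplify = FALSE)
  cfg <- seg_config(start_filters = 4, depth = 2, blocks_per_level = 1,
                    batch_size = 4, epochs = 2, patch = 16, desk = TRUE, seed = 3)
  expect_error(train_subregion_model(patches, zeros, cfg), "no positive pixels")

  masks <- replicate(6, disk_mask(16, 8, 8, 4), simplify = FALSE)
  m1 <- train_subregion_model(patches, masks, cfg)
  m2 <- train_subregion_model(patches, masks, cfg)
  expect_equal(m1$history, m2$history, tolerance = 1e-14)
  expect_equal(predict_prob(m1, patches[[1]]), predict_prob(m2, patches[[1]]),
               tolerance = 1e-12)
})

test_that("cross-validation keeps validation subjects out of training folds", {
  set.seed(10)
  patches <- replicate(12, matrix(runif(16 * 16), 16, 16), simplify = FALSE)
  masks <- replicate(12, disk_mask(16, 8, 8, 4), simplify = FALSE)
  subj <- rep(1:4, each = 3)
  cfg <- seg_config(start_filters = 4, depth = 2, blocks_per_level = 1,
                    batch_size = 4, epochs = 1, patch = 16, desk = TRUE, seed = 3)
  m <- train_subregion_model(patches, masks, cfg, subjects = subj, folds = 2)
  expect_length(m$fold_dice, 2L)
  expect_true(all(is.finite(m$fold_dice)))
  # the split audit itself: folds partition the subjects
  fl <- fold_split(unique(subj), k = 2, seed = cfg$seed)
  expect_setequal(unlist(fl), 1:4)
})

test_that("model checkpoints round-trip through save/load", {
  cfg <- seg_config(start_filters = 4, depth = 2, blocks_per_level = 1,
                    patch = 16, epochs = 1, desk = TRUE)
  m <- build_unet(cfg)
  f <- withr::local_tempfile(fileext = ".rds")
  save_model(m, f)
  m2 <- load_model(f)
  patch <- matrix(runif(256), 16, 16)
  expect_equal(predict_prob(m, patch), predict_prob(m2, patch))
})
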