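test_that("phantom generation is deterministic and well-formed", {
  sp <- phantom_spec(seed = 9, grid = 64, head_scale = 0.24)
  a <- generate_phantom(sp)
  b <- generate_phantom(sp)
  expect_identical(a$image$intensities, b$image$intensities)
  expect_identical(a$labels$labels, b$labels$labels)
  # all 12 classes present, labels exclusive by construction
  expect_setequal(setdiff(unique(as.integer(a$labels$labels)), 0L), 1:12)
})

test_that("voxelized volumes match the closed-form primitive volumes", {
  ph <- generate_phantom(phantom_spec(seed = 3, grid = 256))
  cnt <- tabulate(ph$labels$labels + 1L, nbins = 13L)[-1]
  cls <- subregion_classes()
  prims <- ventriseg:::subregion_primitives(1)
  for (i in seq_len(nrow(cls))) {
    p <- prims[[cls$name[i]]]
    min_feature <- if (p$kind == "ellipsoid") min(p$semi) else p$tube_radius
    if (min_feature < 5) next  # thin tubes voxelize coarsely at 1 mm
    err <- abs(cnt[i] / 1000 / ph$analytic_volumes_ml[i] - 1)
    expect_lt(err, 0.03)
  }
  # a bare ellipsoid example: semi-axes (20, 15, 10) mm
  expect_equal(4 / 3 * pi * 20 * 15 * 10, 12566.37, tolerance = 1e-6)
})

test_that("ventriculomegaly dilates voxel volumes by the cube of the scale", {
  base <- generate_phantom(phantom_spec(seed = 5, grid = 128, head_scale = 0.45))
  big <- generate_phantom(phantom_spec(seed = 5, grid = 128, head_scale = 0.45,
                                       ventriculomegaly_scale = 1.25))
  expect_equal(big$analytic_volumes_ml, base$analytic_volumes_ml * 1.25^3)
  c0 <- tabulate(base$labels$labels + 1L, 13)[-1]
  c1 <- tabulate(big$labels$labels + 1L, 13)[-1]
  keep <- c0 > 500   # classes large enough for a stable ratio
  expect_true(any(keep))
  expect_true(all(abs(c1[keep] / c0[keep] / 1.25^3 - 1) < 0.05))
})

test_that("left/right mirror symmetry holds without pose jitter", {
  ph <- generate_phantom(phantom_spec(seed = 7, grid = 128, head_scale = 0.45))
  cnt <- tabulate(ph$labels$labels + 1L, 13)[-1]
  cls <- subregion_classes()
  pairs <- list(
    c("body_right_lateral", "body_left_lateral"),
    c("right_anterior_horn", "left_anterior_horn"),
    c("right_atrium", "left_atrium"),
    c("right_posterior_horn", "left_posterior_horn"),
    c("right_temporal_horn", "left_temporal_horn")
  )
  for (pr in pairs) {
    i <- subregion_id(pr[1]) + 1L
    j <- subregion_id(pr[2]) + 1L
    expect_lt(abs(cnt[i] / cnt[j] - 1), 0.01)
  }
})

test_that("CSF is darker than parenchyma after windowing on every seed", {
  for (sd in c(1, 12, 123)) {
    ph <- generate_phantom(phantom_spec(seed = sd, grid = 64, head_scale = 0.24))
    w <- window_hu(ph$image$intensities)
    csf <- ph$labels$labels != 0L
    # parenchyma = inside head, unlabeled, non-bone
    paren <- !csf & ph$image$intensities > 15 & ph$image$intensities < 70
    expect_lt(mean(w[csf]), mean(w[paren]))
  }
})

test_that("overlapping primitives are rejected", {
  sp <- phantom_spec(seed = 1, grid = 64, head_scale = 0.24)
  sp$subregions$third_ventricle$center <- sp$subregions$fourth_ventricle$center
  expect_error(generate_phantom(sp), "collision")
})

test_that("cohorts are reproducible per subject and contain all classes", {
  a <- phantom_cohort(3, desk_base_spec(), seed = 99)
  b <- phantom_cohort(3, desk_base_spec(), seed = 99)
  for (i in 1:3) {
    expect_identical(a[[i]]$image$intensities, b[[i]]$image$intensities)
    expect_setequal(setdiff(unique(as.integer(a[[i]]$labels$labels)), 0L), 1:12)
  }
  # analytic-only cohorts agree with rasterized ones on the analytic volumes
  fast <- phantom_cohort(3, desk_base_spec(), seed = 99, rasterize = FALSE)
  for (i in 1:3) {
    expect_equal(fast[[i]]$analytic_volumes_ml, a[[i]]$analytic_volumes_ml)
  }
})

test_that("cohort mean body volume tracks the target mean", {
  # analytic cohort at full scale: Monte-Carlo over per-subject dilation
  co <- phantom_cohort(40, phantom_spec(seed = 0), seed = 7, rasterize = FALSE)
  vols <- vapply(co, function(s) s$analytic_volumes_ml[["body_right_lateral"]], 0)
  target <- ventriseg:::primitive_volume_mm3(
    ventriseg:::subregion_primitives(1)$body_right_lateral
  ) / 1000
  expect_lt(abs(mean(vols) - target), 3 * stats::sd(vols))
})

test_that("phantom sidecar round-trips analytic volumes", {
  dir <- withr::local_tempdir()
  ph <- desk_cohort(2)[[2]]
  write_phantom(ph, dir, stem = "p1")
  side <- jsonlite::read_json(file.path(dir, "p1.json"), simplifyVector = TRUE)
  expect_equal(unlist(side$analytic_volumes_ml), ph$analytic_volumes_ml,
               tolerance = 1e-12)
  img <- read_nifti(file.path(dir, "p1_image.nii.gz"))
  lab <- read_nifti(file.path(dir, "p1_labels.nii.gz"), as = "labels")
  expect_equal(dim(img$intensities), dim(ph$image$intensities))
  expect_identical(lab$labels, ph$labels$labels)
})
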