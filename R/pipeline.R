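#' Pipeline configuration
#'
#' One object controlling the full inference chain: preprocessing (canonical
#' grid, CSF window), the detector stage (`"oracle"`, `"builtin"`, or
#' `"external"` YOLO-format predictions produced by any external detector),
#' ROI geometry (enlargement factor, crop mode, patch size), the
#' segmentation stage (`"models"` registry or `"oracle"` ground-truth
#' passthrough for validation), and the fusion/volumetry stage. Can be
#' loaded from and written to YAML so every run is reproducible from the
#' resolved config alongside its outputs.
#'
#' @param grid canonical grid edge (voxels)
#' @param spacing_mm canonical voxel size
#' @param window CSF window in HU
#' @param detector detector stage choice
#' @param detector_model trained detector (for `"builtin"`)
#' @param detector_cfg a [detector_config()]
#' @param external_labels_dir directory of YOLO `.txt` predictions
#' @param external_stem file stem of the external label files
#' @param enlarge_factor box enlargement before cropping
#' @param crop_mode `"auto"`, `"pad"` or `"resize"` (see [crop_pad_resize()])
#' @param patch segmentation patch size
#' @param segmenter `"models"` or `"oracle"`
#' @param registry a model registry (for `"models"`)
#' @param threshold segmentation probability threshold
#' @param seed run seed
#' @return object of class `pipeline_config`
#' @export
pipeline_config <- function(grid = 256L, spacing_mm = 1, window = c(0, 80),
                            detector = c("oracle", "builtin", "external"),
                            detector_model = NULL,
                            detector_cfg = detector_config(),
                            external_labels_dir = NULL,
                            external_stem = "slice",
                            enlarge_factor = 3,
                            crop_mode = c("auto", "pad", "resize"),
                            patch = 256L,
                            segmenter = c("models", "oracle"),
                            registry = NULL, threshold = 0.5, seed = 1L) {
  structure(
    list(
      grid = as.integer(grid), spacing_mm = spacing_mm, window = window,
      detector = match.arg(detector), detector_model = detector_model,
      detector_cfg = detector_cfg,
      external_labels_dir = external_labels_dir,
      external_stem = external_stem,
      enlarge_factor = enlarge_factor, crop_mode = match.arg(crop_mode),
      patch = as.integer(patch), segmenter = match.arg(segmenter),
      registry = registry, threshold = threshold, seed = as.integer(seed)
    ),
    class = "pipeline_config"
  )
}

#' Model registry: eleven models covering twelve classes
#'
#' The left and right posterior horns share one pooled model (trained in
#' left chirality); every other class maps one-to-one.
#'
#' @param models named list of trained models keyed by `model_key` of
#'   [subregion_classes()]
#' @return object of class `model_registry`
#' @export
model_registry <- function(models) {
  keys <- unique(subregion_classes()$model_key)
  missing <- setdiff(keys, names(models))
  if (length(missing) > 0) {
    stop("missing models for: ", paste(missing, collapse = ", "))
  }
  models <- models[keys]
  if (length(models) != 11L) stop("registry must hold exactly 11 models")
  structure(list(models = models), class = "model_registry")
}

#' @rdname model_registry
#' @param registry a `model_registry`
#' @param class_id subregion class id 0-11
#' @export
resolve_model <- function(registry, class_id) {
  key <- subregion_classes()$model_key[match(class_id, subregion_classes()$id)]
  registry$models[[key]]
}

# right-side posterior-horn patches are mirrored into left chirality before
# the pooled model sees them (and predictions are mirrored back)
needs_mirror <- function(class_id) {
  subregion_name(class_id) == "right_posterior_horn"
}

mirror_patch <- function(p) p[rev(seq_len(nrow(p))), , drop = FALSE]

#' Run the full inference chain
#'
#' Preprocess, detect, crop, segment, backsample, volumetrize: the native CT
#' is standardized onto the canonical frame, subregion boxes are produced
#' per axial slice, each box is enlarged and cropped to a standardized
#' patch, the per-subregion model predicts a mask, and all masks are
#' backsampled into one fused label volume from which the volume report is
#' computed. Deterministic given config and seed.
#'
#' @param volume a [native_volume()], or a path to a NIfTI file or DICOM
#'   series directory
#' @param config a [pipeline_config()]
#' @param labels optional ground-truth [label_volume()] on the native frame
#'   (required for the oracle detector / oracle segmenter; also used as the
#'   volumetry reference)
#' @param out_dir optional output directory (fused NIfTI, report JSON/CSV,
#'   resolved config YAML)
#' @return list with `canonical`, `labels_canonical`, `detections`, `fused`
#'   ([label_volume()]), `report` ([compute_volumes()] result), `timings`
#' @export
run_inference <- function(volume, config = pipeline_config(), labels = NULL,
                          out_dir = NULL) {
  stopifnot(inherits(config, "pipeline_config"))
  timings <- c()
  tic <- function() Sys.time()
  lap <- function(t0, what) {
    timings[what] <<- as.numeric(difftime(Sys.time(), t0, units = "secs"))
  }

  if (is.character(volume)) {
    volume <- if (dir.exists(volume)) read_dicom_series(volume) else read_nifti(volume)
  }
  needs_labels <- config$detector == "oracle" || config$segmenter == "oracle"
  if (needs_labels && is.null(labels)) {
    stop("oracle detector/segmenter requires ground-truth labels")
  }

  t0 <- tic()
  canonical <- resample_canonical(volume, grid = config$grid,
                                  spacing_mm = config$spacing_mm,
                                  window = config$window)
  labc <- if (!is.null(labels)) resample_labels(labels, canonical) else NULL
  lap(t0, "preprocess")

  t0 <- tic()
  detections <- switch(config$detector,
    oracle = boxes_from_mask(labc),
    builtin = {
      if (is.null(config$detector_model)) stop("missing model for detector stage")
      do.call(rbind, lapply(slice_axial(canonical), function(sl) {
        detect(sl, config$detector_model, config$detector_cfg)
      }))
    },
    external = {
      files <- list.files(config$external_labels_dir, pattern = "_z\\d+\\.txt$",
                          full.names = TRUE)
      do.call(rbind, lapply(files, function(f) {
        z <- as.integer(sub(".*_z(\\d+)\\.txt$", "\\1", f))
        read_yolo_labels(f, z_index = z)
      }))
    }
  )
  if (is.null(detections)) detections <- detection_table()
  lap(t0, "detect")

  if (config$segmenter == "models") {
    if (is.null(config$registry)) {
      stop("missing segmentation model registry (needed for all 12 classes)")
    }
  }

  t0 <- tic()
  vol <- canonical$intensities
  lab_arr <- if (!is.null(labc)) labc$labels else NULL
  predictions <- vector("list", nrow(detections))
  for (i in seq_len(nrow(detections))) {
    det <- detections[i, ]
    z <- det$z_index
    sl <- vol[, , z + 1L]
    cr <- crop_pad_resize(
      sl, det, factor = config$enlarge_factor, target = config$patch,
      mode = config$crop_mode, interp = "bilinear"
    )
    tr <- cr$transform
    if (config$segmenter == "oracle") {
      mask_slice <- (lab_arr[, , z + 1L] == det$class_id + 1L) * 1
      mk <- crop_pad_resize(
        mask_slice, tr$source_box, target = config$patch,
        mode = if (tr$resize_factor == 1) "pad" else "resize",
        interp = "nearest", class_id = det$class_id, z_index = z
      )
      mask <- mk$patch
    } else {
      model <- resolve_model(config$registry, det$class_id)
      patch <- cr$patch
      if (needs_mirror(det$class_id)) patch <- mirror_patch(patch)
      mask <- predict_mask(model, patch, config$threshold)
      if (needs_mirror(det$class_id)) mask <- mirror_patch(mask)
    }
    predictions[[i]] <- list(mask = mask, transform = tr)
  }
  lap(t0, "segment")

  t0 <- tic()
  fused <- backsample(predictions, grid = config$grid,
                      spacing_mm = config$spacing_mm)
  report <- compute_volumes(fused, reference = labc)
  lap(t0, "volumetry")

  result <- list(
    canonical = canonical, labels_canonical = labc, detections = detections,
    fused = fused, report = report, timings = timings
  )
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    write_nifti(fused, file.path(out_dir, "segmentation.nii.gz"))
    write_volume_report(report, file.path(out_dir, "volumes"))
    cfg <- config
    cfg$registry <- if (is.null(cfg$registry)) NULL else "<in-memory registry>"
    cfg$detector_model <- if (is.null(cfg$detector_model)) NULL else "<in-memory model>"
    yaml::write_yaml(unclass_deep(cfg), file.path(out_dir, "config.yaml"))
  }
  result
}

unclass_deep <- function(x) {
  if (is.list(x)) {
    lapply(unclass(x), unclass_deep)
  } else {
    x
  }
}

#' Extract ROI training patches from a canonicalized subject
#'
#' Ground-truth boxes ([boxes_from_mask()]) are enlarged and cropped from
#' the windowed image and the class mask with identical geometry — the same
#' construction the published pipeline uses to build its segmentation
#' training set.
#'
#' @param canonical a [canonical_volume()]
#' @param labels_canonical matching [label_volume()]
#' @param enlarge_factor box enlargement
#' @param patch patch size
#' @param crop_mode crop mode (see [crop_pad_resize()])
#' @return list with parallel lists `patches`, `masks`, and vectors
#'   `class_id`, `z_index`
#' @export
extract_training_patches <- function(canonical, labels_canonical,
                                     enlarge_factor = 3, patch = 256L,
                                     crop_mode = "auto") {
  boxes <- boxes_from_mask(labels_canonical)
  vol <- canonical$intensities
  lab <- labels_canonical$labels
  patches <- vector("list", nrow(boxes))
  masks <- vector("list", nrow(boxes))
  for (i in seq_len(nrow(boxes))) {
    det <- boxes[i, ]
    z <- det$z_index
    cr <- crop_pad_resize(vol[, , z + 1L], det, factor = enlarge_factor,
                          target = patch, mode = crop_mode, interp = "bilinear")
    mask_slice <- (lab[, , z + 1L] == det$class_id + 1L) * 1
    tr <- cr$transform
    mk <- crop_pad_resize(mask_slice, tr$source_box, target = patch,
                          mode = if (tr$resize_factor == 1) "pad" else "resize",
                          interp = "nearest")
    patches[[i]] <- cr$patch
    masks[[i]] <- mk$patch
  }
  list(patches = patches, masks = masks,
       class_id = boxes$class_id, z_index = boxes$z_index)
}

#' Train the full model registry (and optionally the detector)
#'
#' Canonicalizes every subject, builds the ROI training set from
#' ground-truth boxes, and trains the eleven per-subregion models (left and
#' right posterior-horn patches pooled after mirroring the right side into
#' left chirality) in subject-level cross-validation. Classes with zero
#' instances in the cohort are skipped with a prominent warning.
#'
#' @param cohort list of subjects, each `list(image = <native_volume>,
#'   labels = <label_volume>)`
#' @param seg_cfg a [seg_config()] applied to every model
#' @param config a [pipeline_config()] for preprocessing/geometry
#' @param folds cross-validation folds (subject-level)
#' @param det_cfg optional [detector_config()]; when supplied the built-in
#'   detector is trained on all canonical slices
#' @param out_dir optional directory for fold metrics CSV and fold
#'   assignment CSV
#' @return list with `registry`, `fold_metrics` (data.frame model_key x
#'   fold), `detector` (or NULL), `fold_assignment`
#' @export
run_training <- function(cohort, seg_cfg, config = pipeline_config(),
                         folds = 5L, det_cfg = NULL, out_dir = NULL) {
  cls <- subregion_classes()
  subjects <- seq_along(cohort)
  per_subj <- lapply(cohort, function(su) {
    canonical <- resample_canonical(su$image, grid = config$grid,
                                    spacing_mm = config$spacing_mm,
                                    window = config$window)
    labc <- resample_labels(su$labels, canonical)
    tp <- extract_training_patches(canonical, labc,
                                   enlarge_factor = config$enlarge_factor,
                                   patch = seg_cfg$patch,
                                   crop_mode = config$crop_mode)
    list(canonical = canonical, labc = labc, patches = tp)
  })

  models <- list()
  fold_rows <- list()
  for (key in unique(cls$model_key)) {
    ids <- cls$id[cls$model_key == key]
    patches <- list()
    masks <- list()
    subj_of <- integer(0)
    for (s in subjects) {
      tp <- per_subj[[s]]$patches
      sel <- which(tp$class_id %in% ids)
      for (i in sel) {
        p <- tp$patches[[i]]
        m <- tp$masks[[i]]
        if (needs_mirror(tp$class_id[i])) {
          p <- mirror_patch(p)
          m <- mirror_patch(m)
        }
        patches[[length(patches) + 1L]] <- p
        masks[[length(masks) + 1L]] <- m
        subj_of <- c(subj_of, s)
      }
    }
    if (length(patches) == 0) {
      warning("class(es) ", paste(subregion_name(ids), collapse = "/"),
              " have zero instances in the cohort; model '", key,
              "' skipped", immediate. = TRUE)
      next
    }
    model <- train_subregion_model(patches, masks, seg_cfg,
                                   subjects = subj_of, folds = folds)
    models[[key]] <- model
    if (!is.null(model$fold_dice)) {
      fold_rows[[key]] <- data.frame(
        model_key = key, fold = seq_along(model$fold_dice),
        val_dice = model$fold_dice, n_patches = length(patches)
      )
    }
  }
  fold_metrics <- if (length(fold_rows)) do.call(rbind, fold_rows) else NULL

  detector <- NULL
  if (!is.null(det_cfg)) {
    slices <- list()
    gt_rows <- list()
    for (s in subjects) {
      sls <- slice_axial(per_subj[[s]]$canonical)
      bx <- boxes_from_mask(per_subj[[s]]$labc)
      bx$z_index <- bx$z_index + length(slices)
      gt_rows[[s]] <- bx
      slices <- c(slices, sls)
    }
    detector <- train_detector(slices, do.call(rbind, gt_rows), det_cfg)
  }

  fold_assignment <- fold_split(subjects, k = min(folds, length(subjects)),
                                seed = seg_cfg$seed)
  registry <- model_registry(models)
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    if (!is.null(fold_metrics)) {
      utils::write.csv(fold_metrics, file.path(out_dir, "fold_metrics.csv"),
                       row.names = FALSE)
    }
    fa <- data.frame(
      subject = unlist(fold_assignment),
      fold = rep(seq_along(fold_assignment), lengths(fold_assignment))
    )
    utils::write.csv(fa, file.path(out_dir, "fold_assignment.csv"),
                     row.names = FALSE)
  }
  list(registry = registry, fold_metrics = fold_metrics, detector = detector,
       fold_assignment = fold_assignment)
}

#' Per-class segmentation scores of a fused volume
#'
#' Mirrors the per-structure evaluation of the pipeline: Dice, Jaccard and
#' HD95 of every class of a predicted label volume against a reference.
#'
#' @param pred,gt [label_volume()]s on the same grid
#' @param spacing voxel spacing in mm
#' @return data.frame with one row per class
#' @export
evaluate_segmentation <- function(pred, gt, spacing = c(1, 1, 1)) {
  cls <- subregion_classes()
  rows <- lapply(cls$id, function(k) {
    pm <- pred$labels == k + 1L
    gm <- gt$labels == k + 1L
    sc <- seg_score(pm, gm, spacing)
    data.frame(
      class_id = k, name = cls$name[cls$id == k],
      dice = sc$dice, jaccard = sc$jaccard, hd95 = sc$hd95,
      gt_voxels = sum(gm), pred_voxels = sum(pm)
    )
  })
  do.call(rbind, rows)
}

#' Export one axial slice with a label overlay as PNG
#'
#' @param canonical a [canonical_volume()]
#' @param labels a [label_volume()] on the same grid (or NULL)
#' @param z 0-based slice index
#' @param path output PNG path
#' @param alpha overlay opacity
#' @return `path` invisibly
#' @export
overlay_png <- function(canonical, labels, z, path, alpha = 0.45) {
  sl <- canonical$intensities[, , z + 1L]
  img <- array(rep(t(sl), 3), dim = c(ncol(sl), nrow(sl), 3))
  if (!is.null(labels)) {
    lab <- t(labels$labels[, , z + 1L])
    pal <- grDevices::hcl.colors(12, "Dark 3")
    for (k in 1:12) {
      fg <- lab == k
      if (!any(fg)) next
      rgb <- grDevices::col2rgb(pal[k]) / 255
      for (ch in 1:3) {
        plane <- img[, , ch]
        plane[fg] <- (1 - alpha) * plane[fg] + alpha * rgb[ch]
        img[, , ch] <- plane
      }
    }
  }
  png::writePNG(img, path)
  invisible(path)
}

#' Export windowed axial slices as PNG images for detector training
#'
#' @param canonical a [canonical_volume()]
#' @param dir output directory
#' @param stem file stem (`<stem>_z<index>.png`)
#' @return character vector of paths, invisibly
#' @export
export_slices_png <- function(canonical, dir, stem = "slice") {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- vapply(seq_len(canonical$grid), function(zi) {
    p <- file.path(dir, sprintf("%s_z%03d.png", stem, zi - 1L))
    png::writePNG(t(canonical$intensities[, , zi]), p)
    p
  }, "")
  invisible(paths)
}
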