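#' Backsample ROI predictions into a fused 3D label volume
#'
#' Each predicted mask patch is inverted through its recorded crop transform
#' ([invert_crop()]), placed on its axial slice, and the per-class binary
#' volumes are fused into one exclusive label volume. Voxels claimed by more
#' than one class are resolved by the fixed anatomical priority (smaller /
#' rarer structure wins); the contested-voxel count is attached as attribute
#' `contested`.
#'
#' @param predictions list of `list(mask = <patch>, transform =
#'   <crop_transform>)`; each transform must carry `class_id` and `z_index`
#' @param grid edge length of the output canonical grid
#' @param spacing_mm canonical voxel size
#' @return a [label_volume()] on the canonical frame
#' @export
backsample <- function(predictions, grid = 256L, spacing_mm = 1) {
  keys <- vapply(predictions, function(p) {
    tr <- p$transform
    if (is.na(tr$class_id) || is.na(tr$z_index)) {
      stop("prediction transform lacks class_id / z_index")
    }
    paste(tr$class_id, tr$z_index)
  }, "")
  if (anyDuplicated(keys)) stop("conflicting ROI predictions (duplicate class/slice)")

  labels <- array(0L, dim = c(grid, grid, grid))
  contested <- 0L
  by_z <- split(predictions, vapply(predictions, function(p) p$transform$z_index, 0L))
  prio <- fusion_priority_order()
  for (zc in names(by_z)) {
    z <- as.integer(zc)
    preds <- by_z[[zc]]
    cls_of <- vapply(preds, function(p) p$transform$class_id, 0L)
    slice <- matrix(0L, grid, grid)
    claims <- matrix(0L, grid, grid)
    for (k in rev(prio)) {       # lowest priority first, highest wins
      j <- which(cls_of == k)
      if (length(j) == 0) next
      m <- invert_crop(preds[[j]]$mask, preds[[j]]$transform, out_size = grid,
                       interp = "nearest")
      fg <- m != 0
      slice[fg] <- k + 1L
      claims[fg] <- claims[fg] + 1L
    }
    contested <- contested + sum(claims >= 2L)
    labels[, , z + 1L] <- slice
  }
  out <- label_volume(labels, frame = "canonical", spacing = rep(spacing_mm, 3))
  attr(out, "contested") <- contested
  out
}

#' Fuse per-class binary volumes into an exclusive label volume
#'
#' Voxels claimed once keep their class; voxels claimed by several classes
#' are assigned by the fixed anatomical priority posterior horn > temporal
#' horn > atrium > anterior horn > third > fourth > body (the smaller or
#' rarer structure wins). The number of contested voxels is attached as
#' attribute `contested`.
#'
#' @param per_class_volumes list of 12 binary arrays named or ordered by
#'   class id 0-11
#' @param spacing_mm voxel size of the shared grid
#' @return a [label_volume()] with attribute `contested`
#' @export
fuse_overlaps <- function(per_class_volumes, spacing_mm = 1) {
  stopifnot(length(per_class_volumes) == 12L)
  d <- dim(per_class_volumes[[1]])
  labels <- array(0L, dim = d)
  claims <- array(0L, dim = d)
  for (k in rev(fusion_priority_order())) {
    m <- per_class_volumes[[k + 1L]]
    if (is.null(m)) next
    stopifnot(all(dim(m) == d))
    fg <- m != 0
    labels[fg] <- k + 1L
    claims[fg] <- claims[fg] + 1L
  }
  out <- label_volume(labels, frame = "canonical", spacing = rep(spacing_mm, 3))
  attr(out, "contested") <- sum(claims >= 2L)
  out
}

#' Subregion volumetry of a label volume
#'
#' Per-class volumes in ml (voxel count times voxel volume in mm^3 / 1000),
#' the grouped volumes (whole system, left and right side, midline), and —
#' when a reference is supplied — the signed relative volumetric error of
#' every entry.
#'
#' @param label_volume a [label_volume()]
#' @param spacing voxel spacing in mm (taken from the volume if omitted)
#' @param reference optional reference: a `label_volume` on the same grid or
#'   a named numeric of per-class ml (names as in [subregion_classes()])
#' @return object of class `volume_report`: list with `per_class_ml`,
#'   `groups_ml`, and `rve` (NULL without reference; reference entries of 0
#'   yield `NA` rather than infinity)
#' @export
compute_volumes <- function(label_volume, spacing = NULL, reference = NULL) {
  stopifnot(inherits(label_volume, "label_volume"))
  spacing <- spacing %||% label_volume$spacing
  if (is.null(spacing) || any(!is.finite(spacing)) || any(spacing <= 0)) {
    stop("unknown spacing")
  }
  voxel_ml <- prod(spacing) / 1000
  cls <- subregion_classes()
  counts <- tabulate(label_volume$labels + 1L, nbins = 13L)[-1]
  per_class <- counts * voxel_ml
  names(per_class) <- cls$name
  groups <- vapply(subregion_groups(), function(ids) sum(per_class[ids + 1L]), 0)

  rve <- NULL
  if (!is.null(reference)) {
    if (inherits(reference, "label_volume")) {
      ref_report <- compute_volumes(reference, spacing = spacing)
      ref_class <- ref_report$per_class_ml
    } else {
      ref_class <- reference[cls$name]
      names(ref_class) <- cls$name
    }
    ref_groups <- vapply(subregion_groups(), function(ids) sum(ref_class[ids + 1L]), 0)
    rve <- list(
      per_class = mapply(relative_volumetric_error, per_class, ref_class),
      groups = mapply(relative_volumetric_error, groups, ref_groups)
    )
  }
  structure(
    list(per_class_ml = per_class, groups_ml = groups, rve = rve,
         voxel_ml = voxel_ml),
    class = "volume_report"
  )
}

#' Signed relative volumetric error
#'
#' `(predicted - reference) / reference`; a non-positive reference yields a
#' missing value (subregions such as the posterior horns can be genuinely
#' absent), never an infinity.
#'
#' @param predicted_ml,reference_ml volumes in ml
#' @return signed fraction, or `NA` when `reference_ml <= 0`
#' @export
relative_volumetric_error <- function(predicted_ml, reference_ml) {
  if (!is.finite(reference_ml) || reference_ml <= 0) return(NA_real_)
  (predicted_ml - reference_ml) / reference_ml
}

#' @export
print.volume_report <- function(x, ...) {
  cat("<volume_report>\n")
  df <- data.frame(volume_ml = round(x$per_class_ml, 3))
  if (!is.null(x$rve)) df$rve <- round(x$rve$per_class, 4)
  print(df)
  cat("groups (ml):\n")
  gdf <- data.frame(volume_ml = round(x$groups_ml, 3))
  if (!is.null(x$rve)) gdf$rve <- round(x$rve$groups, 4)
  print(gdf)
  invisible(x)
}

#' Write a volume report as JSON and CSV
#'
#' @param report a `volume_report`
#' @param stem output path stem (writes `<stem>.json` and `<stem>.csv`)
#' @return the JSON path, invisibly
#' @export
write_volume_report <- function(report, stem) {
  j <- list(
    per_class_ml = as.list(report$per_class_ml),
    groups_ml = as.list(report$groups_ml)
  )
  if (!is.null(report$rve)) {
    j$rve_per_class <- as.list(report$rve$per_class)
    j$rve_groups <- as.list(report$rve$groups)
  }
  jsonlite::write_json(j, paste0(stem, ".json"), auto_unbox = TRUE, digits = NA)
  df <- data.frame(
    entry = c(names(report$per_class_ml), names(report$groups_ml)),
    volume_ml = c(report$per_class_ml, report$groups_ml)
  )
  if (!is.null(report$rve)) {
    df$rve <- c(report$rve$per_class, report$rve$groups)
  }
  utils::write.csv(df, paste0(stem, ".csv"), row.names = FALSE)
  invisible(paste0(stem, ".json"))
}
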