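#' Construct a detection table
#'
#' Detections are plain data.frames with one row per bounding box:
#' 0-based class id, 0-based axial slice index, normalized box center and
#' size (`cx, cy, w, h` in `[0, 1]`, x = image column, y = image row with
#' origin at the top-left pixel of the slice), and a confidence.
#'
#' @param class_id,z_index,cx,cy,w,h,confidence equal-length vectors
#' @return data.frame of class `detections`
#' @export
detection_table <- function(class_id = integer(), z_index = integer(),
                            cx = numeric(), cy = numeric(),
                            w = numeric(), h = numeric(),
                            confidence = numeric()) {
  df <- data.frame(
    class_id = as.integer(class_id), z_index = as.integer(z_index),
    cx = as.numeric(cx), cy = as.numeric(cy),
    w = as.numeric(w), h = as.numeric(h),
    confidence = as.numeric(confidence),
    stringsAsFactors = FALSE
  )
  validate_detections(df)
  class(df) <- c("detections", "data.frame")
  df
}

validate_detections <- function(df) {
  if (nrow(df) == 0) return(invisible(df))
  if (any(df$class_id < 0L | df$class_id > 11L)) stop("class id out of range 0..11")
  geo <- c(df$cx, df$cy, df$w, df$h)
  if (any(!is.finite(geo)) || any(geo < -1e-9) || any(c(df$cx, df$cy) > 1 + 1e-9)) {
    stop("normalized coordinates must lie in [0,1]")
  }
  if (any(df$w > 1 + 1e-9 | df$h > 1 + 1e-9)) stop("normalized coordinates must lie in [0,1]")
  if (any(df$confidence < -1e-9 | df$confidence > 1 + 1e-9)) {
    stop("confidence must lie in [0,1]")
  }
  invisible(df)
}

#' Write / read YOLO-format annotation files
#'
#' One text line per box: `class_id cx cy w h` for ground truth, with the
#' confidence appended as a sixth field for predictions; all fields 6-decimal
#' fixed point. `read_yolo_labels()` is the exact inverse up to that
#' precision.
#'
#' @param detections a detections data.frame referencing a single slice
#' @param path output/input text file
#' @param predictions write the confidence column (`TRUE` for predictions)
#' @return `path` invisibly / a detections data.frame
#' @export
write_yolo_labels <- function(detections, path, predictions = FALSE) {
  validate_detections(detections)
  if (nrow(detections) > 0 && length(unique(detections$z_index)) > 1L) {
    stop("all detections must reference one slice")
  }
  lines <- character(0)
  if (nrow(detections) > 0) {
    fmt6 <- function(v) sprintf("%.6f", v)
    lines <- paste(
      detections$class_id,
      fmt6(detections$cx), fmt6(detections$cy),
      fmt6(detections$w), fmt6(detections$h)
    )
    if (predictions) lines <- paste(lines, fmt6(detections$confidence))
  }
  writeLines(lines, path)
  invisible(path)
}

#' @rdname write_yolo_labels
#' @param z_index slice index assigned to the boxes read back
#' @export
read_yolo_labels <- function(path, z_index = 0L) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == 0) return(detection_table())
  parts <- strsplit(trimws(lines), "\\s+")
  nf <- lengths(parts)
  if (any(nf != 5L & nf != 6L)) stop("malformed YOLO line (expected 5 or 6 fields)")
  num <- lapply(parts, as.numeric)
  m <- do.call(rbind, lapply(num, function(v) c(v, rep(NA, 6 - length(v)))))
  detection_table(
    class_id = as.integer(m[, 1]), z_index = z_index,
    cx = m[, 2], cy = m[, 3], w = m[, 4], h = m[, 5],
    confidence = ifelse(is.na(m[, 6]), 1, m[, 6])
  )
}

#' YOLO annotation file name for one slice
#'
#' @param stem series identifier
#' @param z 0-based slice index
#' @export
yolo_label_filename <- function(stem, z) sprintf("%s_z%03d.txt", stem, z)

#' Ground-truth bounding boxes from a label volume
#'
#' For each axial slice and each class present on it, the tightest
#' axis-aligned box containing all voxels of that class on that slice
#' (disjoint components of one class are merged into one box: one box per
#' class per slice), converted to normalized center/size with confidence 1.
#'
#' @param label_volume a [label_volume()] (or a 3D integer array)
#' @return a detections data.frame
#' @export
boxes_from_mask <- function(label_volume) {
  lab <- if (inherits(label_volume, "label_volume")) label_volume$labels else label_volume
  d <- dim(lab)
  idx <- which(lab != 0L)
  if (length(idx) == 0) return(detection_table())
  v <- as.integer(lab[idx])
  idx0 <- idx - 1L
  x <- idx0 %% d[1]                       # 0-based image x (array dim 1)
  y <- (idx0 %/% d[1]) %% d[2]            # 0-based image y (array dim 2)
  z <- idx0 %/% (d[1] * d[2])
  g <- (v - 1L) * d[3] + z                # class/slice group key
  x0 <- tapply(x, g, min)
  x1 <- tapply(x, g, max) + 1L            # half-open
  y0 <- tapply(y, g, min)
  y1 <- tapply(y, g, max) + 1L
  key <- as.integer(names(x0))
  cls <- key %/% d[3]
  zz <- key %% d[3]
  out <- detection_table(
    class_id = cls, z_index = zz,
    cx = (x0 + x1) / 2 / d[1], cy = (y0 + y1) / 2 / d[2],
    w = (x1 - x0) / d[1], h = (y1 - y0) / d[2],
    confidence = 1
  )
  out[order(out$z_index, out$class_id), , drop = FALSE]
}

# convert a normalized detection row into a clipped integer half-open pixel
# box (x0, y0, x1, y1) on a size x size slice
denormalize_box <- function(det, size) {
  x0 <- floor((det$cx - det$w / 2) * size + 0.5)
  x1 <- ceiling((det$cx + det$w / 2) * size - 0.5)
  y0 <- floor((det$cy - det$h / 2) * size + 0.5)
  y1 <- ceiling((det$cy + det$h / 2) * size - 0.5)
  c(
    x0 = max(0L, as.integer(x0)), y0 = max(0L, as.integer(y0)),
    x1 = min(as.integer(size), as.integer(x1)), y1 = min(as.integer(size), as.integer(y1))
  )
}
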