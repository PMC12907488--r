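#' Intersection over union of normalized boxes
#'
#' @param a single-row detections data.frame (or list with cx, cy, w, h)
#' @param b detections data.frame; IoU is computed row-wise against `a`
#' @return numeric vector of IoU values in `[0, 1]`
#' @export
box_iou <- function(a, b) {
  ax0 <- a$cx - a$w / 2; ax1 <- a$cx + a$w / 2
  ay0 <- a$cy - a$h / 2; ay1 <- a$cy + a$h / 2
  bx0 <- b$cx - b$w / 2; bx1 <- b$cx + b$w / 2
  by0 <- b$cy - b$h / 2; by1 <- b$cy + b$h / 2
  iw <- pmax(0, pmin(ax1, bx1) - pmax(ax0, bx0))
  ih <- pmax(0, pmin(ay1, by1) - pmax(ay0, by0))
  inter <- iw * ih
  union <- a$w * a$h + b$w * b$h - inter
  ifelse(union > 0, inter / union, 0)
}

#' Match predicted boxes to ground truth
#'
#' Greedy matching in descending confidence: a prediction is a true positive
#' if its IoU with a not-yet-matched ground-truth box of the same class on
#' the same slice is at least `iou_thresh`; each ground-truth box can be
#' matched at most once.
#'
#' @param gt_boxes,pred_boxes detections data.frames
#' @param iou_thresh IoU threshold
#' @return list with `matches` (the predictions, confidence-descending, plus
#'   logical `is_tp` and `matched_gt` index into `gt_boxes`), `n_gt`, and
#'   counts `tp`, `fp`, `fn`
#' @export
match_detections <- function(gt_boxes, pred_boxes, iou_thresh = 0.5) {
  n_gt <- nrow(gt_boxes)
  if (nrow(pred_boxes) == 0) {
    m <- cbind(pred_boxes, is_tp = logical(0), matched_gt = integer(0))
    return(list(matches = m, n_gt = n_gt, tp = 0L, fp = 0L, fn = n_gt))
  }
  ord <- order(-pred_boxes$confidence)
  pred <- pred_boxes[ord, , drop = FALSE]
  taken <- rep(FALSE, n_gt)
  is_tp <- logical(nrow(pred))
  matched <- rep(NA_integer_, nrow(pred))
  for (i in seq_len(nrow(pred))) {
    cand <- which(!taken &
                    gt_boxes$class_id == pred$class_id[i] &
                    gt_boxes$z_index == pred$z_index[i])
    if (length(cand) == 0) next
    ious <- box_iou(pred[i, ], gt_boxes[cand, , drop = FALSE])
    j <- which.max(ious)
    if (ious[j] >= iou_thresh) {
      is_tp[i] <- TRUE
      matched[i] <- cand[j]
      taken[cand[j]] <- TRUE
    }
  }
  m <- cbind(pred, is_tp = is_tp, matched_gt = matched)
  list(
    matches = m, n_gt = n_gt,
    tp = sum(is_tp), fp = sum(!is_tp), fn = n_gt - sum(is_tp)
  )
}

#' Average precision from a confidence-ranked matching
#'
#' Area under the precision-recall curve using all-point interpolation (the
#' precision envelope). `matches` must be sorted by descending confidence,
#' as returned by [match_detections()].
#'
#' @param matches data.frame with logical column `is_tp`, confidence-sorted
#' @param n_gt number of ground-truth boxes
#' @return AP in `[0, 1]`; `NA` when `n_gt` is 0 (undefined)
#' @export
average_precision <- function(matches, n_gt) {
  if (n_gt == 0) return(NA_real_)
  if (nrow(matches) == 0) return(0)
  tp <- cumsum(matches$is_tp)
  fp <- cumsum(!matches$is_tp)
  recall <- tp / n_gt
  precision <- tp / (tp + fp)
  # precision envelope (running max from the right)
  env <- rev(cummax(rev(precision)))
  r_prev <- c(0, recall[-length(recall)])
  sum((recall - r_prev) * env)
}

#' Per-class detection scores
#'
#' Precision and recall at `iou_thresh` for all predictions above
#' `conf_threshold`, AP at IoU 0.5, and mAP50-95 (mean AP over the ten IoU
#' thresholds 0.5 to 0.95 in steps of 0.05). The aggregate row is the
#' unweighted mean over classes with at least one ground-truth instance.
#'
#' @param gt,pred detections data.frames
#' @param iou_thresh IoU threshold for precision/recall
#' @param conf_threshold predictions below it are dropped before scoring
#' @return data.frame with one row per class plus an `"all"` row
#' @export
det_scores <- function(gt, pred, iou_thresh = 0.5, conf_threshold = 0) {
  pred <- pred[pred$confidence >= conf_threshold, , drop = FALSE]
  cls <- subregion_classes()
  rows <- lapply(cls$id, function(k) {
    g <- gt[gt$class_id == k, , drop = FALSE]
    p <- pred[pred$class_id == k, , drop = FALSE]
    mt <- match_detections(g, p, iou_thresh)
    ap50 <- average_precision(match_detections(g, p, 0.5)$matches, nrow(g))
    aps <- vapply(
      seq(0.5, 0.95, by = 0.05),
      function(t) average_precision(match_detections(g, p, t)$matches, nrow(g)),
      0
    )
    data.frame(
      class_id = k, name = cls$name[cls$id == k], instances = nrow(g),
      precision = if (nrow(p) > 0) mt$tp / nrow(p) else NA_real_,
      recall = if (nrow(g) > 0) mt$tp / nrow(g) else NA_real_,
      ap50 = ap50, ap50_95 = mean(aps),
      stringsAsFactors = FALSE
    )
  })
  per_class <- do.call(rbind, rows)
  present <- per_class$instances > 0
  agg <- data.frame(
    class_id = NA_integer_, name = "all",
    instances = sum(per_class$instances),
    precision = mean(per_class$precision[present], na.rm = TRUE),
    recall = mean(per_class$recall[present]),
    ap50 = mean(per_class$ap50[present]),
    ap50_95 = mean(per_class$ap50_95[present]),
    stringsAsFactors = FALSE
  )
  rbind(per_class, agg)
}

#' @rdname det_scores
#' @export
map50_95 <- function(gt, pred) {
  sc <- det_scores(gt, pred)
  sc$ap50_95[sc$name == "all"]
}
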