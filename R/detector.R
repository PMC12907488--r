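#' Detector configuration
#'
#' Defaults follow the published training and validation settings: 300
#' epochs, batch size 64, 256-pixel images, flip/scale/translate
#' augmentation, and the validation operating point of an IoU threshold of
#' 0.6 for non-maximum suppression with a confidence threshold of 0.001.
#' `model_size` is the input resolution of the built-in convolutional
#' detector (slices are resampled to it before the forward pass); the
#' built-in head predicts a per-class support map at `model_size / 2`.
#'
#' @param epochs training epochs (>= 1)
#' @param batch_size minibatch size
#' @param image_size slice size the detector operates on
#' @param augmentation named list of toggles: `flip`, `scale`, `translate`
#' @param iou_threshold class-wise NMS IoU threshold
#' @param confidence_threshold candidates below it are discarded
#' @param decode_threshold probability at which support-map cells count as
#'   part of a box
#' @param learning_rate Adam learning rate
#' @param model_size built-in detector input resolution
#' @param pos_weight loss weight of positive cells (class imbalance)
#' @param seed training seed
#' @return object of class `detector_config`
#' @export
detector_config <- function(epochs = 300L, batch_size = 64L, image_size = 256L,
                            augmentation = list(flip = TRUE, scale = TRUE,
                                                translate = TRUE),
                            iou_threshold = 0.6, confidence_threshold = 0.001,
                            decode_threshold = 0.25, learning_rate = 0.001,
                            model_size = 64L, pos_weight = 5,
                            seed = 1L) {
  stopifnot(
    epochs >= 1L,
    iou_threshold >= 0, iou_threshold <= 1,
    confidence_threshold >= 0, confidence_threshold <= 1
  )
  structure(
    list(
      epochs = as.integer(epochs), batch_size = as.integer(batch_size),
      image_size = as.integer(image_size), augmentation = augmentation,
      iou_threshold = iou_threshold,
      confidence_threshold = confidence_threshold,
      decode_threshold = decode_threshold,
      learning_rate = learning_rate, model_size = as.integer(model_size),
      pos_weight = pos_weight, seed = as.integer(seed)
    ),
    class = "detector_config"
  )
}

#' Oracle detector from ground-truth labels
#'
#' A detector whose `detect()` output is exactly [boxes_from_mask()] of the
#' supplied label volume with confidence 1 — the box source the published
#' pipeline itself uses to build its segmentation training set.
#'
#' @param label_volume a [label_volume()] on the canonical frame
#' @return model of class `oracle_detector`
#' @export
oracle_detector <- function(label_volume) {
  structure(
    list(boxes = boxes_from_mask(label_volume)),
    class = "oracle_detector"
  )
}

#' Run detection on one axial slice
#'
#' Raw candidate boxes are filtered by the confidence threshold, then
#' class-wise non-maximum suppression is applied at the configured IoU
#' threshold; with `top1 = TRUE` (the pipeline default) at most one
#' surviving box per class — the highest-confidence one — is forwarded.
#'
#' @param slice 2D slice matrix in `[0, 1]` (square)
#' @param model an `oracle_detector` or trained `conv_detector`
#' @param config a [detector_config()]
#' @param z_index slice index (defaults to the slice's `z_index` attribute)
#' @param top1 keep only the best box per class
#' @return detections data.frame
#' @export
detect <- function(slice, model, config = detector_config(),
                   z_index = attr(slice, "z_index"), top1 = TRUE) {
  if (is.null(z_index)) stop("slice has no z_index")
  z_index <- as.integer(z_index)
  if (inherits(model, "oracle_detector")) {
    cand <- model$boxes[model$boxes$z_index == z_index, , drop = FALSE]
  } else if (inherits(model, "conv_detector")) {
    if (nrow(slice) != config$image_size) {
      stop("slice size does not match the detector config")
    }
    cand <- decode_conv_detections(slice, model, config, z_index)
  } else {
    stop("unknown detector model")
  }
  cand <- cand[cand$confidence >= config$confidence_threshold, , drop = FALSE]
  cand <- nms(cand, config$iou_threshold)
  if (top1 && nrow(cand) > 0) {
    keep <- unlist(lapply(split(seq_len(nrow(cand)), cand$class_id), function(ix) {
      ix[which.max(cand$confidence[ix])]
    }))
    cand <- cand[sort(keep), , drop = FALSE]
  }
  rownames(cand) <- NULL
  cand
}

#' Class-wise non-maximum suppression
#'
#' Keeps the highest-confidence box and discards same-class boxes whose IoU
#' with a kept box reaches `iou_threshold`. Ties are broken deterministically
#' (by center coordinates), making the result invariant to input order.
#'
#' @param detections detections data.frame
#' @param iou_threshold suppression threshold
#' @return filtered detections data.frame
#' @export
nms <- function(detections, iou_threshold = 0.6) {
  if (nrow(detections) <= 1) return(detections)
  out_idx <- integer(0)
  for (k in unique(detections$class_id)) {
    for (z in unique(detections$z_index[detections$class_id == k])) {
      idx <- which(detections$class_id == k & detections$z_index == z)
      d <- detections[idx, , drop = FALSE]
      ord <- order(-d$confidence, d$cx, d$cy, d$w, d$h)
      alive <- rep(TRUE, length(ord))
      keep <- integer(0)
      for (i in seq_along(ord)) {
        if (!alive[i]) next
        keep <- c(keep, ord[i])
        if (i < length(ord)) {
          rest <- (i + 1):length(ord)
          ious <- box_iou(d[ord[i], ], d[ord[rest], , drop = FALSE])
          alive[rest][ious >= iou_threshold] <- FALSE
        }
      }
      out_idx <- c(out_idx, idx[keep])
    }
  }
  out <- detections[sort(out_idx), , drop = FALSE]
  rownames(out) <- NULL
  out
}

# decode per-class support maps into candidate boxes: each above-threshold
# connected component (8-connectivity) becomes one box. Box geometry is
# estimated from the probability-weighted coordinate moments of the
# component (a uniform box of width W has standard deviation W/sqrt(12), so
# W = sqrt(12)*sd), which recovers sub-cell box edges from the soft map;
# the component's maximum probability is the confidence.
decode_conv_detections <- function(slice, model, config, z_index) {
  s <- config$model_size
  x <- resize2d(slice, s, "bilinear")
  fw <- nn_forward(model, det_input(list(x), s), s, s, 1L, train = FALSE)
  p <- sigmoid(fw$outs[[length(model$tape$nodes)]])
  G <- s
  out <- list()
  for (k in 0:11) {
    pm <- matrix(p[, k + 1L], G, G)
    comp <- connected_components(pm >= config$decode_threshold)
    if (comp$n == 0) next
    for (ci in seq_len(comp$n)) {
      sel <- comp$labels == ci
      # box edges at the half-peak crossings of the component's marginal
      # max-profiles, linearly interpolated between cells: for a saturated
      # map this is the 0.5 level set of P(inside box); for small,
      # unsaturated bumps the full width at half maximum still estimates
      # the box extent
      masked <- pm
      masked[!sel] <- 0
      peak <- max(masked)
      level <- (model$level_frac %||% 0.5) * peak
      ex <- profile_edges(apply(masked, 1, max), level, G)
      ey <- profile_edges(apply(masked, 2, max), level, G)
      out[[length(out) + 1L]] <- data.frame(
        class_id = k, z_index = z_index,
        cx = mean(ex), cy = mean(ey),
        w = diff(ex), h = diff(ey),
        confidence = peak
      )
    }
  }
  if (length(out) == 0) return(detection_table())
  df <- do.call(rbind, out)
  class(df) <- c("detections", "data.frame")
  df
}

# interpolated positions (normalized) where a cell-center profile crosses
# `level`, searched from both ends; the profile is zero-extended so edges
# inside the first/last occupied cell interpolate correctly
profile_edges <- function(f, level, G) {
  n <- length(f)
  fe <- c(0, f, 0)
  centers <- (seq_len(n + 2) - 1.5) / G   # extended cell centers, 0-based
  lo_i <- which(fe >= level)[1]
  hi_i <- utils::tail(which(fe >= level), 1)
  interp <- function(i0, i1) {
    if (fe[i1] == fe[i0]) return(centers[i1])
    centers[i0] + (level - fe[i0]) / (fe[i1] - fe[i0]) * (centers[i1] - centers[i0])
  }
  lo <- interp(lo_i - 1L, lo_i)
  hi <- interp(hi_i + 1L, hi_i)
  c(max(lo, 0), min(hi, 1))
}

# 8-connected components of a binary matrix (iterative flood fill)
connected_components <- function(mask) {
  d <- dim(mask)
  labels <- matrix(0L, d[1], d[2])
  n <- 0L
  todo <- which(mask & labels == 0L)
  for (start in todo) {
    if (labels[start] != 0L || !mask[start]) next
    n <- n + 1L
    queue <- start
    labels[start] <- n
    while (length(queue) > 0) {
      cur <- queue[length(queue)]
      queue <- queue[-length(queue)]
      cy <- (cur - 1L) %/% d[1] + 1L
      cx <- (cur - 1L) %% d[1] + 1L
      for (dx in -1:1) {
        for (dy in -1:1) {
          nx <- cx + dx
          ny <- cy + dy
          if (nx < 1L || nx > d[1] || ny < 1L || ny > d[2]) next
          ni <- nx + (ny - 1L) * d[1]
          if (mask[ni] && labels[ni] == 0L) {
            labels[ni] <- n
            queue <- c(queue, ni)
          }
        }
      }
    }
  }
  list(labels = labels, n = n)
}

#' Train the built-in convolutional detector
#'
#' A minimal single-scale anchor-free detector trainable on CPU: a small
#' convolutional backbone predicts a per-class sigmoid support map at half
#' the input resolution, trained with positively-weighted binary
#' cross-entropy against the rasterized ground-truth boxes; boxes are decoded
#' as the extent of above-threshold connected components. Training is
#' deterministic under the config seed; classes absent from the training
#' labels trigger a warning (they can never be predicted).
#'
#' @param slices list of square slice matrices in `[0, 1]` at
#'   `config$image_size`
#' @param yolo_labels detections data.frame of ground-truth boxes whose
#'   `z_index` indexes into `slices` (0-based)
#' @param config a [detector_config()]
#' @return model of class `conv_detector` with per-epoch loss in `$history`
#' @export
train_detector <- function(slices, yolo_labels, config = detector_config()) {
  present <- sort(unique(yolo_labels$class_id))
  absent <- setdiff(0:11, present)
  if (length(absent) > 0) {
    warning(
      "classes absent from training data and never predictable: ",
      paste(subregion_name(absent), collapse = ", ")
    )
  }
  s <- config$model_size
  G <- s
  # encoder-decoder backbone with two skip connections and the per-class
  # head at full input resolution: small structures (a few pixels across)
  # need full-resolution support maps for IoU-tight boxes
  model <- with_seed(config$seed, {
    tp <- nn_tape()
    tp <- nn_add(tp, "conv3", 0L, cin = 3L, cout = 12L)      # 1 @ s
    tp <- nn_add(tp, "relu", 1L)                             # 2 (skip A)
    tp <- nn_add(tp, "pool", 2L)                             # 3 @ s/2
    tp <- nn_add(tp, "conv3", 3L, cin = 12L, cout = 24L)     # 4
    tp <- nn_add(tp, "relu", 4L)                             # 5 (skip B)
    tp <- nn_add(tp, "pool", 5L)                             # 6 @ s/4
    tp <- nn_add(tp, "conv3", 6L, cin = 24L, cout = 48L)     # 7
    tp <- nn_add(tp, "relu", 7L)                             # 8
    tp <- nn_add(tp, "up", 8L)                               # 9 @ s/2
    tp <- nn_add(tp, "conv3", 9L, cin = 48L, cout = 24L)     # 10
    tp <- nn_add(tp, "relu", 10L)                            # 11
    tp <- nn_add(tp, "concat", c(11L, 5L))                   # 12 (48 ch)
    tp <- nn_add(tp, "conv3", 12L, cin = 48L, cout = 24L)    # 13
    tp <- nn_add(tp, "relu", 13L)                            # 14
    tp <- nn_add(tp, "up", 14L)                              # 15 @ s
    tp <- nn_add(tp, "conv3", 15L, cin = 24L, cout = 12L)    # 16
    tp <- nn_add(tp, "relu", 16L)                            # 17
    tp <- nn_add(tp, "concat", c(17L, 2L))                   # 18 (24 ch)
    tp <- nn_add(tp, "conv3", 18L, cin = 24L, cout = 12L)    # 19
    tp <- nn_add(tp, "relu", 19L)                            # 20
    tp <- nn_add(tp, "conv1", 20L, cin = 12L, cout = 12L)    # 21 logits
    structure(
      list(tape = tp, opt = nn_adam_init(tp), config = config, history = NULL),
      class = "conv_detector"
    )
  })
  n <- length(slices)
  small <- lapply(slices, function(sl) resize2d(sl, s, "bilinear"))
  boxes_by_z <- split(yolo_labels, yolo_labels$z_index)
  target_of <- function(boxes) {
    tgt <- matrix(0, G * G, 12L)
    if (!is.null(boxes) && nrow(boxes) > 0) {
      centers <- ((1:G) - 0.5) / G
      for (r in seq_len(nrow(boxes))) {
        inx <- centers >= boxes$cx[r] - boxes$w[r] / 2 &
          centers <= boxes$cx[r] + boxes$w[r] / 2
        iny <- centers >= boxes$cy[r] - boxes$h[r] / 2 &
          centers <= boxes$cy[r] + boxes$h[r] / 2
        cell <- as.vector(outer(inx, iny, `&`))
        tgt[cell, boxes$class_id[r] + 1L] <- 1
      }
    }
    tgt
  }
  with_seed(config$seed + 1L, {
    t_adam <- 0L
    losses <- numeric(config$epochs)
    for (ep in seq_len(config$epochs)) {
      ord <- sample(n)
      ep_loss <- 0
      nb <- 0L
      for (st in seq(1, n, by = config$batch_size)) {
        idx <- ord[st:min(st + config$batch_size - 1L, n)]
        B <- length(idx)
        xs <- vector("list", B)
        ys <- vector("list", B)
        for (j in seq_len(B)) {
          img <- small[[idx[j]]]
          boxes <- boxes_by_z[[as.character(idx[j] - 1L)]]
          aug <- augment_detection(img, boxes, config$augmentation)
          xs[[j]] <- aug$img
          ys[[j]] <- target_of(aug$boxes)
        }
        X <- det_input(xs, s)
        Y <- do.call(rbind, ys)
        fw <- nn_forward(model, X, s, s, B, train = TRUE)
        model <- fw$model
        z <- fw$outs[[length(model$tape$nodes)]]
        wgt <- 1 + (config$pos_weight - 1) * Y
        bce <- nn_bce(z, Y, weight = wgt)
        bw <- nn_backward(model, fw, X, s, s, B, bce$dz)
        t_adam <- t_adam + 1L
        model <- nn_adam_step(model, bw$pgrads, config$learning_rate, t_adam)
        ep_loss <- ep_loss + bce$loss
        nb <- nb + 1L
      }
      losses[ep] <- ep_loss / nb
    }
    model$history <- losses
  })
  model$level_frac <- calibrate_decode_level(model, slices, yolo_labels, config)
  model
}

# decode calibration on *training* slices: the half-maximum level assumes a
# symmetric blur; the actual blur of the learned maps depends on capacity
# and training length, so the level fraction used for edge extraction is
# chosen to maximize recall (ties broken by mean IoU) against the training
# boxes. No held-out data is touched.
calibrate_decode_level <- function(model, slices, yolo_labels, config,
                                   fracs = seq(0.35, 0.65, by = 0.05),
                                   max_slices = 30L) {
  zs <- sort(unique(yolo_labels$z_index))
  if (length(zs) > max_slices) {
    zs <- zs[round(seq(1, length(zs), length.out = max_slices))]
  }
  gts <- yolo_labels[yolo_labels$z_index %in% zs, , drop = FALSE]
  best <- c(recall = -1, iou = -1, frac = 0.5)
  for (fr in fracs) {
    model$level_frac <- fr
    preds <- do.call(rbind, lapply(zs, function(z) {
      detect(structure(slices[[z + 1L]], z_index = z), model, config)
    }))
    if (is.null(preds) || nrow(preds) == 0) next
    mt <- match_detections(gts, preds, 0.5)
    rec <- mt$tp / max(1L, mt$n_gt)
    ious <- vapply(seq_len(nrow(gts)), function(i) {
      p <- preds[preds$class_id == gts$class_id[i] &
                   preds$z_index == gts$z_index[i], , drop = FALSE]
      if (nrow(p) == 0) return(0)
      max(box_iou(gts[i, ], p))
    }, 0)
    if (rec > best["recall"] ||
        (rec == best["recall"] && mean(ious) > best["iou"])) {
      best <- c(recall = rec, iou = mean(ious), frac = fr)
    }
  }
  unname(best["frac"])
}

# detector input: the slice plus two normalized coordinate channels.
# A small fully convolutional net is translation-equivariant and cannot
# otherwise distinguish mirror-identical lateralized structures (left vs
# right), which need absolute position.
det_input <- function(imgs, s) {
  xm <- matrix(((1:s) - 0.5) / s, s, s)
  ym <- t(xm)
  B <- length(imgs)
  cbind(
    nn_pack(imgs),
    rep(as.vector(xm), B),
    rep(as.vector(ym), B)
  )
}

# id of the mirror class (left <-> right); midline classes map to themselves
mirror_class_id <- function(id) {
  cls <- subregion_classes()
  nm <- cls$name[match(id, cls$id)]
  mirrored <- ifelse(
    grepl("right", nm), sub("right", "left", nm),
    ifelse(grepl("left", nm), sub("left", "right", nm), nm)
  )
  cls$id[match(mirrored, cls$name)]
}

# flip / scale / translate augmentation of a slice and its boxes.
# A horizontal flip turns right-sided anatomy into left-sided anatomy, so
# lateralized class ids are swapped with their mirror class — without the
# swap, flipping teaches the detector systematic left/right confusion.
augment_detection <- function(img, boxes, toggles) {
  n <- nrow(img)
  if (isTRUE(toggles$flip) && stats::runif(1) < 0.5) {
    img <- img[rev(seq_len(n)), , drop = FALSE]
    if (!is.null(boxes) && nrow(boxes) > 0) {
      boxes$cx <- 1 - boxes$cx
      boxes$class_id <- mirror_class_id(boxes$class_id)
    }
  }
  if (isTRUE(toggles$scale)) {
    f <- stats::runif(1, 0.9, 1.1)
    m <- as.integer(round(n * f))
    scaled <- resize2d(img, m, "bilinear")
    out <- matrix(0, n, n)
    if (m >= n) {
      o <- (m - n) %/% 2L
      out <- scaled[(o + 1):(o + n), (o + 1):(o + n)]
    } else {
      o <- (n - m) %/% 2L
      out[(o + 1):(o + m), (o + 1):(o + m)] <- scaled
    }
    img <- out
    if (!is.null(boxes) && nrow(boxes) > 0) {
      sgn <- if (m >= n) -1 else 1
      off <- sgn * ((max(m, n) - min(m, n)) %/% 2L) / n
      boxes$cx <- pmin(pmax(boxes$cx * (m / n) + off, 0), 1)
      boxes$cy <- pmin(pmax(boxes$cy * (m / n) + off, 0), 1)
      boxes$w <- pmin(boxes$w * (m / n), 1)
      boxes$h <- pmin(boxes$h * (m / n), 1)
    }
  }
  if (isTRUE(toggles$translate)) {
    sh <- round(stats::runif(2, -0.05, 0.05) * n)
    img <- shift2d(img, sh)
    if (!is.null(boxes) && nrow(boxes) > 0) {
      boxes$cx <- pmin(pmax(boxes$cx + sh[1] / n, 0), 1)
      boxes$cy <- pmin(pmax(boxes$cy + sh[2] / n, 0), 1)
    }
  }
  list(img = img, boxes = boxes)
}

#' Left/right confusion diagnostic for a detector
#'
#' Fraction of unmatched predictions of a lateralized class whose box would
#' have matched the mirror class's ground truth — a diagnostic for chirality
#' confusion introduced by flip augmentation. Reported, not asserted.
#'
#' @param gt,pred detections data.frames
#' @param iou_thresh IoU used for the counterfactual match
#' @return named list with `n_pred`, `n_confused`, `rate`
#' @export
lr_confusion_rate <- function(gt, pred, iou_thresh = 0.5) {
  cls <- subregion_classes()
  mirror_of <- function(k) {
    nm <- cls$name[cls$id == k]
    mirrored <- if (grepl("right", nm)) sub("right", "left", nm) else sub("left", "right", nm)
    if (mirrored %in% cls$name) subregion_id(mirrored) else NA_integer_
  }
  lateral <- cls$id[cls$laterality != "midline"]
  mt <- match_detections(gt, pred, iou_thresh)
  mm <- mt$matches
  miss <- mm[!mm$is_tp & mm$class_id %in% lateral, , drop = FALSE]
  n_conf <- 0L
  for (i in seq_len(nrow(miss))) {
    mk <- mirror_of(miss$class_id[i])
    g <- gt[gt$class_id == mk & gt$z_index == miss$z_index[i], , drop = FALSE]
    if (nrow(g) > 0 && max(box_iou(miss[i, ], g)) >= iou_thresh) {
      n_conf <- n_conf + 1L
    }
  }
  n_pred <- sum(pred$class_id %in% lateral)
  list(
    n_pred = n_pred, n_confused = n_conf,
    rate = if (n_pred > 0) n_conf / n_pred else NA_real_
  )
}
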