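#' Segmentation model configuration
#'
#' The hyperparameter space of the per-subregion 2D U-Nets: starting filter
#' count 32-128, depth 3-5, 2-5 convolution blocks per level, optional
#' dropout and batch normalization, batch size 32 or 64, learning rate 1e-3
#' or 1e-4. The activation (rectified linear) and the loss (binary
#' cross-entropy) are fixed. `desk = TRUE` lifts the range checks so that
#' small CPU-scale configurations (e.g. 16 starting filters, one block,
#' 64-pixel patches) can be trained in tests and examples.
#'
#' @param start_filters filters at the first level; doubled per level
#' @param depth number of resolution levels (each halves the grid)
#' @param blocks_per_level convolution blocks per level
#' @param dropout,dropout_rate dropout toggle and rate (bottleneck)
#' @param batch_norm batch-normalization toggle
#' @param batch_size minibatch size
#' @param learning_rate Adam learning rate
#' @param epochs training epochs
#' @param patch patch edge length consumed by the model; must be divisible
#'   by `2^depth`
#' @param threshold probability threshold for [predict_mask()]
#' @param augment apply random augmentation during training
#' @param seed training seed
#' @param desk allow desk-scale values outside the production ranges
#' @return object of class `seg_config`
#' @export
seg_config <- function(start_filters = 32L, depth = 3L, blocks_per_level = 2L,
                       dropout = FALSE, dropout_rate = 0.5,
                       batch_norm = FALSE, batch_size = 32L,
                       learning_rate = 0.001, epochs = 50L, patch = 256L,
                       threshold = 0.5, augment = TRUE, seed = 1L,
                       desk = FALSE) {
  if (!desk) {
    stopifnot(
      start_filters >= 32L, start_filters <= 128L,
      depth >= 3L, depth <= 5L,
      blocks_per_level >= 2L, blocks_per_level <= 5L,
      batch_size %in% c(32L, 64L),
      learning_rate %in% c(0.001, 0.0001)
    )
  }
  if (patch %% 2^depth != 0) stop("patch size must be divisible by 2^depth")
  structure(
    list(
      start_filters = as.integer(start_filters), depth = as.integer(depth),
      blocks_per_level = as.integer(blocks_per_level),
      dropout = isTRUE(dropout), dropout_rate = dropout_rate,
      batch_norm = isTRUE(batch_norm), batch_size = as.integer(batch_size),
      learning_rate = learning_rate, epochs = as.integer(epochs),
      patch = as.integer(patch), threshold = threshold,
      augment = isTRUE(augment), seed = as.integer(seed),
      activation = "relu", loss = "binary_crossentropy"
    ),
    class = "seg_config"
  )
}

#' Build a 2D U-Net
#'
#' Standard encoder-decoder with skip connections: `depth` levels each
#' halving the resolution and doubling the filter count from
#' `start_filters`, `blocks_per_level` convolution blocks per level, a
#' bottleneck with `start_filters * 2^depth` filters, nearest-neighbor
#' upsampling with skip concatenation on the way up, and a single-channel
#' sigmoid output at the input resolution.
#'
#' @param config a [seg_config()]
#' @return an untrained model of class `unet_model`
#' @export
build_unet <- function(config) {
  stopifnot(inherits(config, "seg_config"))
  with_seed(config$seed, {
    tp <- nn_tape()
    prev <- 0L
    prev_ch <- 1L
    skips <- integer(config$depth)
    conv_block <- function(tp, prev, prev_ch, f) {
      for (b in seq_len(config$blocks_per_level)) {
        tp <- nn_add(tp, "conv3", prev, cin = prev_ch, cout = f)
        prev <- length(tp$nodes)
        if (config$batch_norm) {
          tp <- nn_add(tp, "bnorm", prev, cin = f)
          prev <- length(tp$nodes)
        }
        tp <- nn_add(tp, "relu", prev)
        prev <- length(tp$nodes)
        prev_ch <- f
      }
      list(tp = tp, prev = prev, ch = prev_ch)
    }
    for (l in seq_len(config$depth)) {
      f <- config$start_filters * 2^(l - 1)
      blk <- conv_block(tp, prev, prev_ch, f)
      tp <- blk$tp; prev <- blk$prev; prev_ch <- blk$ch
      skips[l] <- prev
      tp <- nn_add(tp, "pool", prev)
      prev <- length(tp$nodes)
    }
    blk <- conv_block(tp, prev, prev_ch, config$start_filters * 2^config$depth)
    tp <- blk$tp; prev <- blk$prev; prev_ch <- blk$ch
    if (config$dropout) {
      tp <- nn_add(tp, "dropout", prev, rate = config$dropout_rate)
      prev <- length(tp$nodes)
    }
    for (l in rev(seq_len(config$depth))) {
      f <- config$start_filters * 2^(l - 1)
      tp <- nn_add(tp, "up", prev)
      prev <- length(tp$nodes)
      tp <- nn_add(tp, "conv3", prev, cin = prev_ch, cout = f)
      prev <- length(tp$nodes)
      tp <- nn_add(tp, "relu", prev)
      prev <- length(tp$nodes)
      tp <- nn_add(tp, "concat", c(prev, skips[l]))
      prev <- length(tp$nodes)
      prev_ch <- 2L * f
      blk <- conv_block(tp, prev, prev_ch, f)
      tp <- blk$tp; prev <- blk$prev; prev_ch <- blk$ch
    }
    tp <- nn_add(tp, "conv1", prev, cin = prev_ch, cout = 1L)
    structure(
      list(tape = tp, opt = nn_adam_init(tp), config = config, history = NULL),
      class = "unet_model"
    )
  })
}

#' Subject-level k-fold split
#'
#' Splits subjects (never slices) into `k` disjoint folds whose sizes differ
#' by at most one; the same seed always yields the same split.
#'
#' @param subject_ids vector of unique subject identifiers
#' @param k number of folds
#' @param seed split seed
#' @return list of `k` vectors of subject ids
#' @export
fold_split <- function(subject_ids, k = 5L, seed = 1L) {
  ids <- unique(subject_ids)
  if (length(ids) < k) stop("fewer subjects than folds")
  with_seed(seed, {
    shuffled <- sample(ids)
    split(shuffled, rep_len(seq_len(k), length(shuffled)))
  })
}

#' Random training augmentation of a patch/mask pair
#'
#' Randomly composed horizontal flip, integer-pixel shift, small rotation and
#' multiplicative brightness change. The identical geometric transform is
#' applied to the mask; the brightness change is applied to the patch only
#' and the result is clipped back to `[0, 1]`.
#'
#' @param patch image patch in `[0, 1]`
#' @param mask aligned binary mask
#' @param seed optional seed (otherwise the current RNG stream is used)
#' @param max_shift maximum shift in pixels per axis
#' @param max_rot_deg maximum rotation in degrees
#' @param brightness multiplicative brightness range
#' @param force list overriding the random draws, e.g. `list(flip = TRUE)`
#' @return list with transformed `patch` and `mask`
#' @export
augment <- function(patch, mask, seed = NULL, max_shift = 5L, max_rot_deg = 10,
                    brightness = c(0.9, 1.1), force = list()) {
  draw <- function() {
    list(
      flip = stats::runif(1) < 0.5,
      shift = round(stats::runif(2, -max_shift, max_shift)),
      rot = stats::runif(1, -max_rot_deg, max_rot_deg),
      bright = stats::runif(1, brightness[1], brightness[2])
    )
  }
  tr <- if (is.null(seed)) draw() else with_seed(seed, draw())
  tr[names(force)] <- force
  geom <- function(img, interp) {
    out <- img
    if (tr$flip) out <- out[rev(seq_len(nrow(out))), , drop = FALSE]
    if (abs(tr$rot) > 1e-9) out <- rotate2d(out, tr$rot, interp)
    if (any(tr$shift != 0)) out <- shift2d(out, tr$shift)
    out
  }
  p <- geom(patch, "bilinear")
  m <- geom(mask, "nearest")
  p <- pmin(pmax(p * tr$bright, 0), 1)
  list(patch = p, mask = m, transform = tr)
}

rotate2d <- function(img, deg, interp = c("bilinear", "nearest")) {
  interp <- match.arg(interp)
  n <- nrow(img)
  th <- deg * pi / 180
  c0 <- (n - 1) / 2
  xs <- (0:(n - 1)) - c0
  X <- matrix(xs, n, n)
  Y <- matrix(xs, n, n, byrow = TRUE)
  sx <- cos(th) * X - sin(th) * Y + c0
  sy <- sin(th) * X + cos(th) * Y + c0
  if (interp == "nearest") {
    ix <- round(sx); iy <- round(sy)
    ok <- ix >= 0 & ix <= n - 1 & iy >= 0 & iy <= n - 1
    out <- matrix(0, n, n)
    out[ok] <- img[cbind(ix[ok] + 1, iy[ok] + 1)]
    return(out)
  }
  i0x <- floor(sx); i0y <- floor(sy)
  fx <- sx - i0x; fy <- sy - i0y
  out <- matrix(0, n, n)
  for (dx in 0:1) {
    for (dy in 0:1) {
      ix <- i0x + dx; iy <- i0y + dy
      wgt <- (if (dx == 0) 1 - fx else fx) * (if (dy == 0) 1 - fy else fy)
      ok <- ix >= 0 & ix <= n - 1 & iy >= 0 & iy <= n - 1
      acc <- matrix(0, n, n)
      acc[ok] <- img[cbind(ix[ok] + 1, iy[ok] + 1)] * wgt[ok]
      out <- out + acc
    }
  }
  out
}

shift2d <- function(img, shift) {
  n <- nrow(img); m <- ncol(img)
  out <- matrix(0, n, m)
  sx <- shift[1]; sy <- shift[2]
  xs <- max(1, 1 + sx):min(n, n + sx)
  ys <- max(1, 1 + sy):min(m, m + sy)
  out[xs, ys] <- img[xs - sx, ys - sy]
  out
}

#' Train a per-subregion segmentation model
#'
#' Minimizes binary cross-entropy with Adam over minibatches of augmented
#' patch/mask pairs; deterministic under the config seed. With `folds >= 2`
#' and subject ids supplied, a subject-level cross-validation is run first
#' (per-fold validation Dice is returned) and the final model is trained on
#' all data.
#'
#' @param patches list of patch matrices in `[0, 1]`
#' @param masks list of aligned binary mask matrices
#' @param config a [seg_config()]
#' @param subjects optional subject id per patch (required when `folds >= 2`)
#' @param folds number of cross-validation folds (0 = train on all data)
#' @return trained `unet_model`; `$history` holds the per-epoch loss and
#'   `$fold_dice` the per-fold validation Dice (when folds were run)
#' @export
train_subregion_model <- function(patches, masks, config, subjects = NULL,
                                  folds = 0L) {
  stopifnot(length(patches) == length(masks), length(patches) >= 1)
  npos <- sum(vapply(masks, function(m) sum(m != 0), 0))
  if (npos == 0) stop("no positive pixels in training set")
  fold_dice <- NULL
  if (folds >= 2L) {
    if (is.null(subjects)) stop("subject ids required for cross-validation")
    fl <- fold_split(unique(subjects), k = folds, seed = config$seed)
    fold_dice <- vapply(seq_len(folds), function(fi) {
      val <- subjects %in% fl[[fi]]
      m <- fit_unet(patches[!val], masks[!val], config)
      mean(vapply(which(val), function(i) {
        as.numeric(dice(predict_mask(m, patches[[i]], config$threshold), masks[[i]]))
      }, 0))
    }, 0)
  }
  model <- fit_unet(patches, masks, config)
  model$fold_dice <- fold_dice
  model
}

fit_unet <- function(patches, masks, config) {
  model <- build_unet(config)
  n <- length(patches)
  H <- nrow(patches[[1]])
  if (H != config$patch) stop("patch size does not match the model config")
  with_seed(config$seed + 1L, {
    t_adam <- 0L
    losses <- numeric(config$epochs)
    for (ep in seq_len(config$epochs)) {
      ord <- sample(n)
      ep_loss <- 0
      nb <- 0L
      for (s in seq(1, n, by = config$batch_size)) {
        idx <- ord[s:min(s + config$batch_size - 1L, n)]
        B <- length(idx)
        ps <- patches[idx]
        ms <- masks[idx]
        if (config$augment) {
          for (j in seq_len(B)) {
            a <- augment(ps[[j]], ms[[j]])
            ps[[j]] <- a$patch
            ms[[j]] <- a$mask
          }
        }
        X <- nn_pack(ps)
        Y <- nn_pack(ms)
        fw <- nn_forward(model, X, H, H, B, train = TRUE)
        model <- fw$model
        z <- fw$outs[[length(model$tape$nodes)]]
        bce <- nn_bce(z, Y)
        bw <- nn_backward(model, fw, X, H, H, B, bce$dz)
        t_adam <- t_adam + 1L
        model <- nn_adam_step(model, bw$pgrads, config$learning_rate, t_adam)
        ep_loss <- ep_loss + bce$loss
        nb <- nb + 1L
      }
      losses[ep] <- ep_loss / nb
    }
    model$history <- losses
  })
  model
}

#' Predict a binary mask for one patch
#'
#' Deterministic at inference (no dropout, batch-norm in evaluation mode):
#' the sigmoid output map is thresholded at `threshold`.
#'
#' @param model a trained `unet_model`
#' @param patch patch matrix in `[0, 1]` of the model's patch size
#' @param threshold probability threshold
#' @return binary matrix of the same shape
#' @export
predict_mask <- function(model, patch, threshold = 0.5) {
  H <- nrow(patch)
  if (H != model$config$patch || ncol(patch) != H) {
    stop("patch shape does not match the model")
  }
  fw <- nn_forward(model, nn_pack(list(patch)), H, H, 1L, train = FALSE)
  p <- sigmoid(fw$outs[[length(model$tape$nodes)]])
  matrix(as.numeric(p >= threshold), H, H)
}

#' Probability map for one patch (no thresholding)
#' @rdname predict_mask
#' @export
predict_prob <- function(model, patch) {
  H <- nrow(patch)
  fw <- nn_forward(model, nn_pack(list(patch)), H, H, 1L, train = FALSE)
  matrix(sigmoid(fw$outs[[length(model$tape$nodes)]]), H, H)
}

#' Save / load a model checkpoint
#'
#' Checkpoints are single-file archives with the configuration embedded.
#'
#' @param model model object
#' @param path file path
#' @export
save_model <- function(model, path) {
  saveRDS(model, path)
  invisible(path)
}

#' @rdname save_model
#' @export
load_model <- function(path) readRDS(path)
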