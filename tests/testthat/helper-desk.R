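# Desk-scale phantom cohort shared by the learning and end-to-end tests:
# 64 mm isotropic grid with the head scaled to fit, mild ventriculomegaly
# spread and pose jitter. Expensive objects are memoized for the session.

.desk_memo <- new.env(parent = emptyenv())

desk_base_spec <- function() {
  phantom_spec(
    seed = 0, grid = 64L, head_scale = 0.24,
    ventriculomegaly_scale = 1.1, pose_jitter_deg = 4
  )
}

desk_cohort <- function(n = 20, seed = 42) {
  key <- paste0("cohort_", n, "_", seed)
  if (is.null(.desk_memo[[key]])) {
    .desk_memo[[key]] <- phantom_cohort(n, desk_base_spec(), seed = seed)
  }
  .desk_memo[[key]]
}

# canonicalized slices and ground-truth boxes per subject
desk_prepped <- function(n = 20, seed = 42) {
  key <- paste0("prep_", n, "_", seed)
  if (is.null(.desk_memo[[key]])) {
    .desk_memo[[key]] <- lapply(desk_cohort(n, seed), function(ph) {
      cv <- resample_canonical(ph$image, grid = 64)
      lc <- resample_labels(ph$labels, cv)
      list(canonical = cv, labels = lc,
           slices = slice_axial(cv), boxes = boxes_from_mask(lc))
    })
  }
  .desk_memo[[key]]
}

# concatenate selected subjects' annotated slices into one 0-indexed list
desk_slice_set <- function(prep, idx) {
  slices <- list()
  gt <- list()
  for (s in idx) {
    bx <- prep[[s]]$boxes
    zs <- sort(unique(bx$z_index))
    bx$z_index <- match(bx$z_index, zs) - 1L + length(slices)
    slices <- c(slices, prep[[s]]$slices[zs + 1L])
    gt[[length(gt) + 1L]] <- bx
  }
  list(slices = slices, gt = do.call(rbind, gt))
}

# mirrored-pooled lateral-ventricle body patches (right side flipped into
# left chirality), with subject ids
desk_body_patches <- function(prep, patch = 48L) {
  body_ids <- subregion_id(c("body_right_lateral", "body_left_lateral"))
  patches <- list()
  masks <- list()
  subj <- integer(0)
  for (s in seq_along(prep)) {
    tp <- extract_training_patches(prep[[s]]$canonical, prep[[s]]$labels,
                                   enlarge_factor = 3, patch = patch)
    sel <- which(tp$class_id %in% body_ids)
    for (i in sel) {
      p <- tp$patches[[i]]
      m <- tp$masks[[i]]
      if (tp$class_id[i] == body_ids[1]) {
        p <- p[rev(seq_len(nrow(p))), ]
        m <- m[rev(seq_len(nrow(m))), ]
      }
      patches[[length(patches) + 1L]] <- p
      masks[[length(masks) + 1L]] <- m
    }
    subj <- c(subj, rep(s, length(sel)))
  }
  list(patches = patches, masks = masks, subj = subj)
}
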