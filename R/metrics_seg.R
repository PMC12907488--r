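#' Overlap metrics for binary masks
#'
#' Dice coefficient `2|A∩B| / (|A|+|B|)` and Jaccard coefficient
#' `|A∩B| / |A∪B|`. The two are linked by the identity
#' `jaccard = dice / (2 - dice)`. When both masks are empty the score is 1
#' by convention (correct absence; the result carries a `both_empty`
#' attribute so callers can log it).
#'
#' @param a,b binary (logical or 0/1) arrays of identical shape
#' @return scalar in `[0, 1]`
#' @export
dice <- function(a, b) {
  check_same_shape(a, b)
  sa <- sum(a != 0)
  sb <- sum(b != 0)
  if (sa + sb == 0) return(structure(1, both_empty = TRUE))
  2 * sum(a != 0 & b != 0) / (sa + sb)
}

#' @rdname dice
#' @export
jaccard <- function(a, b) {
  check_same_shape(a, b)
  un <- sum(a != 0 | b != 0)
  if (un == 0) return(structure(1, both_empty = TRUE))
  sum(a != 0 & b != 0) / un
}

check_same_shape <- function(a, b) {
  da <- dim(a) %||% length(a)
  db <- dim(b) %||% length(b)
  if (!identical(da, db)) stop("mask shape mismatch")
  invisible(TRUE)
}

#' 95th-percentile Hausdorff distance between mask surfaces
#'
#' The surface of a mask is the set of foreground voxels with at least one
#' background face-neighbor (the volume border counts as background).
#' Directed surface-to-surface distances are computed in both directions in
#' mm via `spacing`, pooled, and the 95th percentile of the pooled set is
#' returned. Empty masks yield a missing value rather than infinity.
#'
#' @param a,b binary arrays (2D or 3D) of identical shape
#' @param spacing voxel spacing in mm (length matching the dimensionality)
#' @param percentile percentile of the pooled distances (default 0.95)
#' @return distance in mm, or `NA` if either mask is empty
#' @export
hausdorff95 <- function(a, b, spacing = NULL, percentile = 0.95) {
  check_same_shape(a, b)
  nd <- length(dim(a) %||% 1L)
  spacing <- spacing %||% rep(1, nd)
  if (length(spacing) == 1L) spacing <- rep(spacing, nd)
  sa <- surface_coords(a, spacing)
  sb <- surface_coords(b, spacing)
  if (nrow(sa) == 0 || nrow(sb) == 0) return(NA_real_)
  d_ab <- min_dists(sa, sb)
  d_ba <- min_dists(sb, sa)
  unname(stats::quantile(c(d_ab, d_ba), percentile, type = 7))
}

# mm coordinates of the surface voxels of a binary mask; a voxel is surface
# when any face-neighbor (the volume border included) is background
surface_coords <- function(mask, spacing) {
  m <- mask != 0
  d <- dim(m)
  if (is.null(d)) {
    d <- length(m)
    dim(m) <- d
  }
  nd <- length(d)
  if (nd == 2L) {
    p <- matrix(FALSE, d[1] + 2L, d[2] + 2L)
    p[2:(d[1] + 1L), 2:(d[2] + 1L)] <- m
    cx <- 2:(d[1] + 1L)
    cy <- 2:(d[2] + 1L)
    all_fg <- p[cx - 1L, cy] & p[cx + 1L, cy] & p[cx, cy - 1L] & p[cx, cy + 1L]
  } else if (nd == 3L) {
    p <- array(FALSE, d + 2L)
    p[2:(d[1] + 1L), 2:(d[2] + 1L), 2:(d[3] + 1L)] <- m
    cx <- 2:(d[1] + 1L)
    cy <- 2:(d[2] + 1L)
    cz <- 2:(d[3] + 1L)
    all_fg <- p[cx - 1L, cy, cz] & p[cx + 1L, cy, cz] &
      p[cx, cy - 1L, cz] & p[cx, cy + 1L, cz] &
      p[cx, cy, cz - 1L] & p[cx, cy, cz + 1L]
  } else {
    stop("masks must be 2D or 3D")
  }
  surf <- m & !all_fg
  idx <- which(surf)
  if (length(idx) == 0) return(matrix(0, 0, nd))
  coords <- arrayInd(idx, d)
  sweep(coords, 2, spacing, `*`)
}

# per-row minimum Euclidean distance from points in A to the set B (chunked)
min_dists <- function(a, b, chunk = 1024L) {
  nb2 <- rowSums(b^2)
  out <- numeric(nrow(a))
  for (s in seq(1, nrow(a), by = chunk)) {
    e <- min(s + chunk - 1L, nrow(a))
    blk <- a[s:e, , drop = FALSE]
    d2 <- outer(rowSums(blk^2), nb2, `+`) - 2 * tcrossprod(blk, b)
    out[s:e] <- sqrt(pmax(apply(d2, 1, min), 0))
  }
  out
}

#' Score one predicted mask against a reference
#'
#' @param pred,ref binary arrays of identical shape
#' @param spacing voxel spacing in mm for the Hausdorff component
#' @return list with `dice`, `jaccard`, `hd95` (`hd95` is `NA` when either
#'   mask is empty)
#' @export
seg_score <- function(pred, ref, spacing = NULL) {
  list(
    dice = as.numeric(dice(pred, ref)),
    jaccard = as.numeric(jaccard(pred, ref)),
    hd95 = hausdorff95(pred, ref, spacing)
  )
}
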