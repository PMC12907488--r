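# Brute-force reference implementations used as independent oracles.
# Deliberately naive (loops, O(n^2)) and kept free of any package internals.

oracle_dice <- function(a, b) {
  na <- 0; nb <- 0; ni <- 0
  for (i in seq_along(a)) {
    ai <- a[i] != 0
    bi <- b[i] != 0
    na <- na + ai
    nb <- nb + bi
    ni <- ni + (ai && bi)
  }
  if (na + nb == 0) return(1)
  2 * ni / (na + nb)
}

oracle_jaccard <- function(a, b) {
  ni <- 0; nu <- 0
  for (i in seq_along(a)) {
    ai <- a[i] != 0
    bi <- b[i] != 0
    ni <- ni + (ai && bi)
    nu <- nu + (ai || bi)
  }
  if (nu == 0) return(1)
  ni / nu
}

# naive surface extraction: foreground voxel with any 6-neighbour background
# (grid border counts as background)
oracle_surface <- function(mask, spacing) {
  d <- dim(mask)
  out <- NULL
  for (x in seq_len(d[1])) for (y in seq_len(d[2])) for (z in seq_len(d[3])) {
    if (mask[x, y, z] == 0) next
    nb <- c(
      if (x > 1) mask[x - 1, y, z] else 0, if (x < d[1]) mask[x + 1, y, z] else 0,
      if (y > 1) mask[x, y - 1, z] else 0, if (y < d[2]) mask[x, y + 1, z] else 0,
      if (z > 1) mask[x, y, z - 1] else 0, if (z < d[3]) mask[x, y, z + 1] else 0
    )
    if (any(nb == 0) || x == 1 || x == d[1] || y == 1 || y == d[2] ||
        z == 1 || z == d[3]) {
      out <- rbind(out, c(x, y, z) * spacing)
    }
  }
  out
}

oracle_hd95 <- function(a, b, spacing = c(1, 1, 1), q = 0.95) {
  sa <- oracle_surface(a, spacing)
  sb <- oracle_surface(b, spacing)
  if (is.null(sa) || is.null(sb)) return(NA_real_)
  dmin <- function(p, set) {
    best <- Inf
    for (j in seq_len(nrow(set))) {
      best <- min(best, sqrt(sum((p - set[j, ])^2)))
    }
    best
  }
  d_ab <- apply(sa, 1, dmin, set = sb)
  d_ba <- apply(sb, 1, dmin, set = sa)
  unname(stats::quantile(c(d_ab, d_ba), q, type = 7))
}

# all-point-interpolated AP via the recall-step identity:
# AP = sum_k p_interp(k / n_gt) / n_gt with p_interp(r) the maximum prefix
# precision at recall >= r (a different computation path from the envelope
# integration in the package)
oracle_ap <- function(is_tp_sorted, n_gt) {
  if (n_gt == 0) return(NA_real_)
  if (length(is_tp_sorted) == 0) return(0)
  tp <- cumsum(is_tp_sorted)
  prec <- tp / seq_along(is_tp_sorted)
  rec <- tp / n_gt
  total <- 0
  for (k in seq_len(n_gt)) {
    r <- k / n_gt
    ok <- rec >= r
    total <- total + if (any(ok)) max(prec[ok]) else 0
  }
  total / n_gt
}

# random blob mask: a few dilated seed points, reproducible
random_blob <- function(dims, seed, n_seeds = 3, grow = 2) {
  set.seed(seed)
  m <- array(0L, dims)
  for (k in seq_len(n_seeds)) {
    c0 <- sapply(dims, function(n) sample(seq_len(n), 1))
    for (x in max(1, c0[1] - grow):min(dims[1], c0[1] + grow))
      for (y in max(1, c0[2] - grow):min(dims[2], c0[2] + grow))
        for (z in max(1, c0[3] - grow):min(dims[3], c0[3] + grow))
          if (sum(abs(c(x, y, z) - c0)) <= grow + 1) m[x, y, z] <- 1L
  }
  m
}

disk_mask <- function(n, cx, cy, r) {
  xs <- matrix(seq_len(n), n, n)
  ys <- t(xs)
  ((xs - cx)^2 + (ys - cy)^2 <= r^2) * 1
}
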