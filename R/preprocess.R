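#' CSF-window Hounsfield units into [0, 1]
#'
#' Voxelwise linear windowing `clip((hu - lo) / (hi - lo), 0, 1)`. The
#' default 0-80 HU window maximizes CSF/parenchyma contrast on head CT.
#'
#' @param x numeric array (HU) or a [native_volume()]
#' @param lo,hi window bounds in HU, `hi > lo`
#' @return object of the same shape with values in `[0, 1]`
#' @export
window_hu <- function(x, lo = 0, hi = 80) {
  if (hi <= lo) stop("window requires hi > lo")
  if (inherits(x, "native_volume")) {
    x$intensities <- window_hu(x$intensities, lo, hi)
    return(x)
  }
  pmin(pmax((x - lo) / (hi - lo), 0), 1)
}

#' Resample a native CT onto the standardized frame
#'
#' Reorients the native volume to the canonical RAS axis convention,
#' resamples to isotropic voxels (1 mm) with trilinear interpolation in HU
#' space, center-places the result into a cubic grid (256 by default,
#' symmetric crop or zero-fill per axis), and finally applies the CSF window.
#' The exact canonical-voxel to native-voxel affine is recorded and
#' invertible.
#'
#' @param native a [native_volume()]
#' @param grid edge length of the cubic canonical grid
#' @param spacing_mm isotropic canonical voxel size in mm
#' @param window HU window applied after resampling
#' @return a [canonical_volume()]
#' @export
resample_canonical <- function(native, grid = 256L, spacing_mm = 1,
                               window = c(0, 80)) {
  stopifnot(inherits(native, "native_volume"))
  if (any(native$spacing <= 0) || any(!is.finite(native$spacing))) {
    stop("degenerate spacing")
  }
  geo <- canonical_geometry(native, grid, spacing_mm)
  ras <- reorient_to_ras(native$intensities, native$orientation)

  if (geo$identity) {
    hu <- ras
  } else {
    hu <- trilinear_sample(ras, geo)
  }
  canonical_volume(
    window_hu(hu, window[1], window[2]),
    native_transform = geo$affine,
    window = window,
    native_meta = geo
  )
}

#' Resample a label volume onto the canonical frame
#'
#' Nearest-neighbor resampling of the labels through the same geometry that
#' produced a canonical volume; the class set can only be preserved or
#' shrunk, never invented.
#'
#' @param labels a [label_volume()] on the native frame
#' @param canonical the [canonical_volume()] whose geometry to follow
#' @return a [label_volume()] on the canonical frame
#' @export
resample_labels <- function(labels, canonical) {
  stopifnot(inherits(labels, "label_volume"), inherits(canonical, "canonical_volume"))
  geo <- canonical$native_meta
  if (is.null(geo)) stop("canonical volume carries no resampling geometry")
  if (!all(dim(labels$labels) == geo$native_dim) ||
      max(abs(labels$spacing - geo$native_spacing)) > 1e-9 ||
      !identical(labels$orientation, geo$native_orientation)) {
    stop("label volume does not share the canonical volume's native frame")
  }
  ras <- reorient_to_ras(labels$labels, labels$orientation)
  out <- if (geo$identity) ras else nearest_sample(ras, geo)
  label_volume(out, frame = "canonical", spacing = rep(geo$spacing_mm, 3),
               orientation = "RAS")
}

# geometry shared by intensity and label resampling:
# canonical voxel c (0-based) samples reoriented voxel r_k = a_k c_k + b_k
canonical_geometry <- function(native, grid, spacing_mm) {
  po <- ras_permutation(native$orientation)
  nd <- dim(native$intensities)[po$perm]
  sp <- native$spacing[po$perm]
  a <- spacing_mm / sp
  b <- (nd - 1) / 2 - a * (grid - 1) / 2
  identity <- all(abs(a - 1) < 1e-12) && all(abs(b) < 1e-12) && all(nd == grid)
  # affine canonical voxel -> native voxel (both 0-based)
  m <- matrix(0, 4, 4)
  m[4, 4] <- 1
  for (k in 1:3) {
    j <- po$perm[k]
    if (po$flip[k]) {
      m[j, k] <- -a[k]
      m[j, 4] <- (dim(native$intensities)[j] - 1) - b[k]
    } else {
      m[j, k] <- a[k]
      m[j, 4] <- b[k]
    }
  }
  list(
    grid = grid, spacing_mm = spacing_mm, a = a, b = b,
    ras_dim = nd, identity = identity, affine = m,
    native_dim = dim(native$intensities), native_spacing = native$spacing,
    native_orientation = native$orientation
  )
}

# permutation/flips taking a stored array to RAS axis order
ras_permutation <- function(orientation) {
  ax <- axis_of_letter(strsplit(toupper(orientation), "")[[1]])
  perm <- match(1:3, abs(ax))
  list(perm = perm, flip = ax[perm] < 0)
}

reorient_to_ras <- function(arr, orientation) {
  po <- ras_permutation(orientation)
  out <- aperm(arr, po$perm)
  for (k in which(po$flip)) {
    idx <- rev(seq_len(dim(out)[k]))
    out <- switch(k,
      out[idx, , , drop = FALSE],
      out[, idx, , drop = FALSE],
      out[, , idx, drop = FALSE]
    )
  }
  out
}

# per-axis interpolation support with zero weight outside the grid
interp_axis <- function(coord, n) {
  i0 <- floor(coord)
  w1 <- coord - i0
  w0 <- 1 - w1
  i1 <- i0 + 1
  w0[i0 < 0 | i0 > n - 1] <- 0
  w1[i1 < 0 | i1 > n - 1] <- 0
  list(
    i0 = pmin(pmax(i0, 0), n - 1) + 1L,
    i1 = pmin(pmax(i1, 0), n - 1) + 1L,
    w0 = w0, w1 = w1
  )
}

trilinear_sample <- function(ras, geo) {
  g <- geo$grid
  nd <- dim(ras)
  cx <- geo$a[1] * (0:(g - 1)) + geo$b[1]
  cy <- geo$a[2] * (0:(g - 1)) + geo$b[2]
  cz <- geo$a[3] * (0:(g - 1)) + geo$b[3]
  ix <- interp_axis(cx, nd[1])
  iy <- interp_axis(cy, nd[2])
  iz <- interp_axis(cz, nd[3])
  w00 <- outer(ix$w0, iy$w0)
  w10 <- outer(ix$w1, iy$w0)
  w01 <- outer(ix$w0, iy$w1)
  w11 <- outer(ix$w1, iy$w1)
  out <- array(0, dim = c(g, g, g))
  for (z in seq_len(g)) {
    bilin <- function(sl) {
      w00 * sl[ix$i0, iy$i0] + w10 * sl[ix$i1, iy$i0] +
        w01 * sl[ix$i0, iy$i1] + w11 * sl[ix$i1, iy$i1]
    }
    acc <- 0
    if (iz$w0[z] > 0) acc <- iz$w0[z] * bilin(ras[, , iz$i0[z]])
    if (iz$w1[z] > 0) acc <- acc + iz$w1[z] * bilin(ras[, , iz$i1[z]])
    out[, , z] <- acc
  }
  out
}

nearest_sample <- function(ras, geo) {
  g <- geo$grid
  nd <- dim(ras)
  near_axis <- function(coord, n) {
    i <- as.integer(round(coord))
    ok <- i >= 0L & i <= n - 1L
    list(i = pmin(pmax(i, 0L), n - 1L) + 1L, ok = ok)
  }
  nx <- near_axis(geo$a[1] * (0:(g - 1)) + geo$b[1], nd[1])
  ny <- near_axis(geo$a[2] * (0:(g - 1)) + geo$b[2], nd[2])
  nz <- near_axis(geo$a[3] * (0:(g - 1)) + geo$b[3], nd[3])
  out <- array(0L, dim = c(g, g, g))
  mask_xy <- outer(nx$ok, ny$ok)
  for (z in seq_len(g)) {
    if (!nz$ok[z]) next
    sl <- ras[nx$i, ny$i, nz$i[z]]
    sl[!mask_xy] <- 0L
    out[, , z] <- sl
  }
  out
}

#' Slice a canonical volume axially
#'
#' @param canonical a [canonical_volume()] (or cubic 3D array)
#' @return list of 2D matrices, one per axial plane, z ascending
#'   (inferior to superior); each has attributes `z_index` (0-based)
#' @export
slice_axial <- function(canonical) {
  arr <- if (inherits(canonical, "canonical_volume")) canonical$intensities else canonical
  lapply(seq_len(dim(arr)[3]), function(z) {
    structure(arr[, , z], z_index = z - 1L)
  })
}

#' @rdname slice_axial
#' @param slices list of 2D matrices as produced by `slice_axial()`
#' @export
stack_axial <- function(slices) {
  d <- dim(slices[[1]])
  arr <- array(0, dim = c(d[1], d[2], length(slices)))
  for (z in seq_along(slices)) arr[, , z] <- slices[[z]]
  arr
}
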