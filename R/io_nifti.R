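#' Read a NIfTI-1 volume
#'
#' Reads a 3D NIfTI file into a [native_volume()] (scalar image) or, on
#' request, a [label_volume()] when the file is integer-valued with a maximum
#' of 12. Orientation is decoded from the stored transform.
#'
#' @param path path to a `.nii` / `.nii.gz` file
#' @param as `"image"` (default) or `"labels"`
#' @param frame frame tag attached when reading labels
#' @return a `native_volume` or `label_volume`
#' @export
read_nifti <- function(path, as = c("image", "labels"),
                       frame = c("native", "canonical")) {
  as <- match.arg(as)
  frame <- match.arg(frame)
  img <- RNifti::readNifti(path)
  d <- dim(img)
  if (length(d) == 4L && d[4] == 1L) {
    img <- img[, , , 1L]
    d <- dim(img)
  }
  if (length(d) != 4L && length(d) != 3L) stop("expected 3D volume")
  if (length(d) == 4L) stop("expected 3D volume, got 4D")
  sp <- RNifti::pixdim(img)[1:3]
  xf <- RNifti::xform(img)
  ori <- orientation_from_xform(xf)
  origin <- xf[1:3, 4]
  arr <- array(as.numeric(img), dim = d)
  if (as == "labels") {
    vals <- unique(as.vector(arr))
    if (any(vals != round(vals))) stop("label volume must be integer-valued")
    if (any(vals < 0 | vals > 12)) stop("label values must be integers in 0..12")
    lab <- array(as.integer(round(arr)), dim = d)
    return(label_volume(lab, frame = frame, spacing = sp, orientation = ori))
  }
  native_volume(arr, spacing = sp, orientation = ori, origin = origin)
}

#' Write a volume as NIfTI-1
#'
#' Stores grid, spacing, orientation and origin; label volumes are written
#' with an integer on-disk type.
#'
#' @param volume a `native_volume`, `label_volume` or `canonical_volume`
#' @param path output path (`.nii` or `.nii.gz`)
#' @return `path`, invisibly
#' @export
write_nifti <- function(volume, path) {
  if (inherits(volume, "native_volume")) {
    arr <- volume$intensities
    sp <- volume$spacing
    ori <- volume$orientation
    origin <- volume$origin
    dtype <- "double"
  } else if (inherits(volume, "label_volume")) {
    arr <- volume$labels
    sp <- volume$spacing
    ori <- volume$orientation
    origin <- c(0, 0, 0)
    dtype <- "uint8"
  } else if (inherits(volume, "canonical_volume")) {
    arr <- volume$intensities
    sp <- c(1, 1, 1)
    ori <- "RAS"
    origin <- c(0, 0, 0)
    dtype <- "double"
  } else {
    stop("unsupported volume type")
  }
  img <- RNifti::asNifti(arr)
  RNifti::pixdim(img) <- sp
  xf <- xform_from_orientation(ori, sp, origin)
  RNifti::qform(img) <- structure(xf, code = 1L)
  RNifti::sform(img) <- structure(xf, code = 1L)
  RNifti::writeNifti(img, path, datatype = dtype)
  invisible(path)
}

# voxel -> patient-RAS affine for an axis-aligned orientation code
xform_from_orientation <- function(orientation, spacing, origin) {
  ax <- axis_of_letter(strsplit(toupper(orientation), "")[[1]])
  m <- matrix(0, 4, 4)
  m[4, 4] <- 1
  for (j in 1:3) {
    m[abs(ax[j]), j] <- sign(ax[j]) * spacing[j]
  }
  m[1:3, 4] <- origin
  m
}

orientation_from_xform <- function(xf) {
  r <- xf[1:3, 1:3]
  if (all(r == 0)) return("RAS")
  letters_pos <- c("R", "A", "S")
  letters_neg <- c("L", "P", "I")
  code <- character(3)
  for (j in 1:3) {
    i <- which.max(abs(r[, j]))
    code[j] <- if (r[i, j] >= 0) letters_pos[i] else letters_neg[i]
  }
  paste(code, collapse = "")
}
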