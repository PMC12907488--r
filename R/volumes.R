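#' Native CT volume container
#'
#' A 3D scalar grid in Hounsfield units together with the geometric metadata
#' needed to map it onto the standardized frame: per-axis voxel spacing in mm,
#' a three-letter axis-direction code (e.g. `"RAS"`: +x right, +y anterior,
#' +z superior), and the scanner-space position of voxel (0,0,0).
#'
#' @param intensities 3D numeric array, Hounsfield units
#' @param spacing numeric length-3, voxel size in mm, strictly positive
#' @param orientation three-letter orientation code; one letter per stored
#'   axis out of R/L, A/P, S/I, covering all three patient axes
#' @param origin numeric length-3, mm position of voxel (0,0,0)
#' @return object of class `native_volume`
#' @export
native_volume <- function(intensities, spacing, orientation = "RAS",
                          origin = c(0, 0, 0)) {
  if (length(dim(intensities)) != 3L) stop("expected 3D volume")
  if (any(dim(intensities) < 1L)) stop("each axis must have length >= 1")
  spacing <- as.numeric(spacing)
  if (length(spacing) != 3L || any(!is.finite(spacing)) || any(spacing <= 0)) {
    stop("spacing must be 3 strictly positive values")
  }
  check_orientation_code(orientation)
  structure(
    list(
      intensities = intensities, spacing = spacing,
      orientation = toupper(orientation), origin = as.numeric(origin)
    ),
    class = "native_volume"
  )
}

check_orientation_code <- function(orientation) {
  if (!is.character(orientation) || length(orientation) != 1L ||
      nchar(orientation) != 3L) {
    stop("orientation must be a 3-letter code like 'RAS'")
  }
  ax <- axis_of_letter(strsplit(toupper(orientation), "")[[1]])
  if (anyDuplicated(abs(ax))) stop("orientation must cover all three patient axes")
  invisible(TRUE)
}

# maps orientation letters to signed patient axes: +-1 = R/L, +-2 = A/P, +-3 = S/I
axis_of_letter <- function(letters) {
  lut <- c(R = 1, L = -1, A = 2, P = -2, S = 3, I = -3)
  out <- lut[letters]
  if (anyNA(out)) stop("orientation letters must be in R,L,A,P,S,I")
  unname(out)
}

#' Integer label volume for the twelve subregions
#'
#' @param labels 3D integer array; 0 = background, `k + 1` = subregion class
#'   id `k` (see [subregion_classes()])
#' @param frame `"native"` or `"canonical"` — the grid the labels index
#' @param spacing voxel spacing in mm of that grid
#' @param orientation orientation code of the stored grid
#' @return object of class `label_volume`
#' @export
label_volume <- function(labels, frame = c("native", "canonical"),
                         spacing = c(1, 1, 1), orientation = "RAS") {
  frame <- match.arg(frame)
  if (length(dim(labels)) != 3L) stop("expected 3D volume")
  vals <- unique(as.integer(labels))
  if (any(vals < 0L | vals > 12L)) {
    stop("label values must be integers in 0..12")
  }
  storage.mode(labels) <- "integer"
  structure(
    list(
      labels = labels, frame = frame, spacing = as.numeric(spacing),
      orientation = toupper(orientation)
    ),
    class = "label_volume"
  )
}

#' Standardized (canonical) CT volume
#'
#' The frame every model consumes: isotropic 1 mm voxels on a cubic grid
#' (256 by default), intensities CSF-windowed into `[0, 1]`, axes in the
#' canonical anatomical convention, plus the invertible affine mapping
#' canonical voxel coordinates back to native voxel coordinates.
#'
#' @param intensities 3D array in `[0, 1]`, cubic
#' @param native_transform 4x4 affine taking 0-based canonical voxel
#'   coordinates to 0-based native voxel coordinates
#' @param window HU window `(lo, hi)` that produced the intensities
#' @param native_meta list carrying the native spacing/orientation/dim
#' @return object of class `canonical_volume`
#' @export
canonical_volume <- function(intensities, native_transform = diag(4),
                             window = c(0, 80), native_meta = NULL) {
  d <- dim(intensities)
  if (length(d) != 3L || length(unique(d)) != 1L) stop("canonical grid must be cubic")
  rng <- range(intensities)
  if (rng[1] < -1e-9 || rng[2] > 1 + 1e-9) stop("canonical intensities must lie in [0,1]")
  stopifnot(is.matrix(native_transform), all(dim(native_transform) == c(4L, 4L)))
  structure(
    list(
      intensities = intensities, grid = d[1], spacing = c(1, 1, 1),
      native_transform = native_transform, window = window,
      native_meta = native_meta
    ),
    class = "canonical_volume"
  )
}

#' @export
print.native_volume <- function(x, ...) {
  cat(
    "<native_volume> ", paste(dim(x$intensities), collapse = "x"),
    " @ (", paste(signif(x$spacing, 4), collapse = ", "), ") mm, ",
    x$orientation, "\n",
    sep = ""
  )
  invisible(x)
}

#' @export
print.label_volume <- function(x, ...) {
  present <- sort(setdiff(unique(as.integer(x$labels)), 0L))
  cat(
    "<label_volume> ", paste(dim(x$labels), collapse = "x"),
    " (", x$frame, " frame), classes present: ",
    if (length(present)) paste(present - 1L, collapse = ",") else "none", "\n",
    sep = ""
  )
  invisible(x)
}

#' @export
print.canonical_volume <- function(x, ...) {
  cat(
    "<canonical_volume> ", x$grid, "^3 @ 1 mm, window [",
    x$window[1], ", ", x$window[2], "] HU\n",
    sep = ""
  )
  invisible(x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
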