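# Pixel conventions, stated once and used everywhere:
# boxes are half-open integer pixel boxes (x0, y0, x1, y1) with origin at the
# top-left pixel, x = image column = array dim 1, y = image row = array dim 2.

#' Enlarge a bounding box about its center
#'
#' Width and height are multiplied by `factor` about the box center, rounded
#' outward to integers, and clipped to the slice bounds so the result never
#' exceeds the full slice. The original box is always contained in the
#' result.
#'
#' @param box integer half-open pixel box `c(x0, y0, x1, y1)`
#' @param factor enlargement factor, between 1 and 4 ("up to 300%": the
#'   default reading is a 3x scale; the additive +300% reading is available
#'   as `factor = 4`)
#' @param bounds slice edge length in pixels
#' @return integer half-open pixel box
#' @export
enlarge_box <- function(box, factor = 3, bounds = 256L) {
  if (factor < 1 || factor > 4) stop("enlargement factor must be in [1, 4]")
  box <- as.numeric(box)
  if (box[1] >= box[3] || box[2] >= box[4]) stop("empty box")
  cx <- (box[1] + box[3]) / 2
  cy <- (box[2] + box[4]) / 2
  hw <- (box[3] - box[1]) * factor / 2
  hh <- (box[4] - box[2]) * factor / 2
  out <- c(
    max(0L, as.integer(floor(cx - hw))),
    max(0L, as.integer(floor(cy - hh))),
    min(as.integer(bounds), as.integer(ceiling(cx + hw))),
    min(as.integer(bounds), as.integer(ceiling(cy + hh)))
  )
  names(out) <- c("x0", "y0", "x1", "y1")
  out
}

#' Crop, pad and resize an ROI to a standardized patch
#'
#' Crops the (already enlarged) box from the slice, zero-pads it
#' symmetrically to a square, and resizes to `target` (bilinear for images,
#' nearest for masks). When the enlarged box is already square with edge
#' `<= target` the pad-only mode is used: the crop is centered in the target
#' frame with `resize_factor = 1` and no interpolation, making the round
#' trip bit-exact. Every geometric parameter is recorded in the returned
#' `crop_transform` so [invert_crop()] can invert the operation exactly.
#'
#' @param slice_2d square numeric matrix (the axial slice)
#' @param box integer half-open pixel box after enlargement, or a
#'   single-row detections data.frame (then `factor` is applied internally)
#' @param factor enlargement factor used when `box` is a detection
#' @param target patch edge length
#' @param mode `"auto"` (spec rule above), `"pad"` (force pad-only; requires
#'   the box to fit in `target`), or `"resize"` (force the pad-to-square +
#'   resize path)
#' @param interp `"bilinear"` for image patches, `"nearest"` for masks
#' @param class_id,z_index provenance recorded in the transform
#' @return list with `patch` (target x target matrix) and `transform`
#' @export
crop_pad_resize <- function(slice_2d, box, factor = 3, target = 256L,
                            mode = c("auto", "pad", "resize"),
                            interp = c("bilinear", "nearest"),
                            class_id = NA_integer_, z_index = NA_integer_) {
  mode <- match.arg(mode)
  interp <- match.arg(interp)
  size <- nrow(slice_2d)
  stopifnot(size == ncol(slice_2d))
  if (is.data.frame(box)) {
    stopifnot(nrow(box) == 1L)
    if (is.na(class_id)) class_id <- box$class_id
    if (is.na(z_index)) z_index <- box$z_index
    box <- enlarge_box(denormalize_box(box, size), factor, bounds = size)
  }
  box <- unname(as.integer(box))
  x0 <- box[1]; y0 <- box[2]; x1 <- box[3]; y1 <- box[4]
  if (x0 >= x1 || y0 >= y1) stop("empty box after clipping")
  w <- x1 - x0
  h <- y1 - y0
  crop <- slice_2d[(x0 + 1):x1, (y0 + 1):y1, drop = FALSE]

  pad_only <- switch(mode,
    auto = (w == h && w <= target),
    pad = TRUE,
    resize = FALSE
  )
  if (pad_only && max(w, h) > target) stop("box does not fit the target frame in pad mode")

  if (pad_only) {
    px <- (target - w) %/% 2L
    py <- (target - h) %/% 2L
    patch <- matrix(0, target, target)
    patch[(px + 1):(px + w), (py + 1):(py + h)] <- crop
    pad <- c(left = px, right = target - w - px, top = py, bottom = target - h - py)
    square <- as.integer(target)
    resize_factor <- 1
  } else {
    square <- max(w, h)
    px <- (square - w) %/% 2L
    py <- (square - h) %/% 2L
    padded <- matrix(0, square, square)
    padded[(px + 1):(px + w), (py + 1):(py + h)] <- crop
    pad <- c(left = px, right = square - w - px, top = py, bottom = square - h - py)
    patch <- resize2d(padded, target, interp)
    resize_factor <- target / square
  }
  transform <- structure(
    list(
      source_box = c(x0 = x0, y0 = y0, x1 = x1, y1 = y1),
      pad = pad, square = as.integer(square), resize_factor = resize_factor,
      target = as.integer(target), out_size = as.integer(size),
      interp = interp, class_id = as.integer(class_id),
      z_index = as.integer(z_index)
    ),
    class = "crop_transform"
  )
  list(patch = patch, transform = transform)
}

#' Invert a crop/pad/resize back onto the full slice
#'
#' Exact inverse of the geometry of [crop_pad_resize()]: inverse-resize,
#' remove the padding, and place the crop at its source box in a zero slice.
#' In pad-only mode (`resize_factor = 1`) the round trip is bit-exact.
#'
#' @param patch target x target matrix (e.g. a predicted mask)
#' @param transform the `crop_transform` recorded at crop time
#' @param out_size edge length of the output slice
#' @param interp interpolation for the inverse resize; defaults to the one
#'   recorded in the transform (`"nearest"` keeps masks binary)
#' @return `out_size` x `out_size` matrix, zero outside the source box
#' @export
invert_crop <- function(patch, transform, out_size = NULL, interp = NULL) {
  stopifnot(inherits(transform, "crop_transform"))
  out_size <- as.integer(out_size %||% transform$out_size)
  interp <- interp %||% transform$interp
  b <- transform$source_box
  if (b["x1"] > out_size || b["y1"] > out_size) {
    stop("transform inconsistent with requested output shape")
  }
  w <- b["x1"] - b["x0"]
  h <- b["y1"] - b["y0"]
  if (transform$resize_factor == 1) {
    square <- patch
  } else {
    square <- resize2d(patch, transform$square, interp)
  }
  pad <- transform$pad
  crop <- square[(pad["left"] + 1):(pad["left"] + w),
                 (pad["top"] + 1):(pad["top"] + h), drop = FALSE]
  out <- matrix(0, out_size, out_size)
  out[(b["x0"] + 1):b["x1"], (b["y0"] + 1):b["y1"]] <- crop
  out
}

# separable resize with pixel-center alignment: output pixel i (0-based)
# samples input coordinate (i + 0.5) * n_in / n_out - 0.5
resize2d <- function(img, out_n, interp = c("bilinear", "nearest")) {
  interp <- match.arg(interp)
  in_n <- nrow(img)
  stopifnot(in_n == ncol(img))
  if (in_n == out_n) return(img)
  coord <- (0:(out_n - 1) + 0.5) * in_n / out_n - 0.5
  if (interp == "nearest") {
    i <- pmin(pmax(as.integer(round(coord)), 0L), in_n - 1L) + 1L
    return(img[i, i, drop = FALSE])
  }
  i0 <- pmin(pmax(floor(coord), 0), in_n - 1)
  i1 <- pmin(i0 + 1, in_n - 1)
  w1 <- pmin(pmax(coord - i0, 0), 1)
  w0 <- 1 - w1
  rows0 <- img[i0 + 1, , drop = FALSE]
  rows1 <- img[i1 + 1, , drop = FALSE]
  tmp <- rows0 * w0 + rows1 * w1
  tmp[, i0 + 1, drop = FALSE] %*% diag(w0, out_n) +
    tmp[, i1 + 1, drop = FALSE] %*% diag(w1, out_n)
}
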