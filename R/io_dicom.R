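#' Read a single-frame CT DICOM series as one volume
#'
#' Minimal reader for uncompressed little-endian (implicit or explicit VR)
#' single-frame CT slices. Slices are sorted by their projected position
#' along the slice normal (never by file name), stored values are rescaled
#' to Hounsfield units with each file's rescale slope/intercept, and the
#' inter-slice distance is derived from the sorted positions.
#'
#' @param directory_path directory containing the `.dcm` files of exactly
#'   one series
#' @param gap_tolerance maximum relative variation of the inter-slice gap
#'   before the series is rejected as non-uniform (default 10%)
#' @return a [native_volume()]
#' @export
read_dicom_series <- function(directory_path, gap_tolerance = 0.1) {
  files <- list.files(directory_path, pattern = "\\.dcm$", full.names = TRUE,
                      ignore.case = TRUE)
  if (length(files) == 0) {
    files <- list.files(directory_path, full.names = TRUE)
    files <- files[!dir.exists(files)]
  }
  if (length(files) == 0) stop("no DICOM files found in ", directory_path)
  slices <- lapply(files, read_dicom_slice)

  uids <- vapply(slices, function(s) s$series_uid, "")
  if (length(unique(uids)) > 1L) stop("multiple series in directory")

  rowdir <- slices[[1]]$iop[1:3]
  coldir <- slices[[1]]$iop[4:6]
  normal <- c(
    rowdir[2] * coldir[3] - rowdir[3] * coldir[2],
    rowdir[3] * coldir[1] - rowdir[1] * coldir[3],
    rowdir[1] * coldir[2] - rowdir[2] * coldir[1]
  )
  pos <- vapply(slices, function(s) sum(s$ipp * normal), 0)
  ord <- order(pos)
  slices <- slices[ord]
  pos <- pos[ord]

  nz <- length(slices)
  if (nz > 1L) {
    gaps <- diff(pos)
    if (any(gaps <= 0)) stop("duplicate slice positions in series")
    if ((max(gaps) - min(gaps)) > gap_tolerance * stats::median(gaps)) {
      stop("non-uniform slice spacing")
    }
    dz <- stats::median(gaps)
  } else {
    dz <- slices[[1]]$spacing_z %||% 1
  }

  d1 <- dim(slices[[1]]$hu)
  arr <- array(0, dim = c(d1[1], d1[2], nz))
  for (k in seq_len(nz)) {
    if (!all(dim(slices[[k]]$hu) == d1)) stop("inconsistent slice dimensions")
    arr[, , k] <- slices[[k]]$hu
  }

  # PixelSpacing is (row spacing, column spacing) = (y, x)
  ps <- slices[[1]]$pixel_spacing
  spacing <- c(ps[2], ps[1], dz)
  ori <- paste(
    c(
      dicom_axis_letter(rowdir), dicom_axis_letter(coldir),
      dicom_axis_letter(normal)
    ),
    collapse = ""
  )
  # DICOM patient coordinates are LPS; store the origin in RAS
  origin_ras <- slices[[1]]$ipp * c(-1, -1, 1)
  native_volume(arr, spacing = spacing, orientation = ori, origin = origin_ras)
}

# dominant patient axis of an LPS direction vector, as an R/L A/P S/I letter
dicom_axis_letter <- function(v) {
  i <- which.max(abs(v))
  pos <- c("L", "P", "S")[i]
  neg <- c("R", "A", "I")[i]
  if (v[i] >= 0) pos else neg
}

read_dicom_slice <- function(path) {
  bytes <- readBin(path, "raw", n = file.size(path))
  offset <- 0L
  explicit <- FALSE
  if (length(bytes) > 132L && rawToChar(bytes[129:132]) == "DICM") {
    meta <- parse_dicom_elements(bytes, 133L, explicit = TRUE, stop_group = 2L)
    ts <- trimws(dicom_string(meta$elements[["0002,0010"]]))
    offset <- meta$offset
    if (identical(ts, "1.2.840.10008.1.2")) {
      explicit <- FALSE
    } else if (identical(ts, "1.2.840.10008.1.2.1") || length(ts) == 0L) {
      explicit <- TRUE
    } else {
      stop("unsupported transfer syntax: ", ts)
    }
  } else {
    offset <- 1L
    explicit <- FALSE
  }
  el <- parse_dicom_elements(bytes, offset, explicit = explicit)$elements

  need <- function(tag, what) {
    if (is.null(el[[tag]])) stop("missing DICOM tag (", tag, ") ", what)
    el[[tag]]
  }
  rows <- dicom_uint16(need("0028,0010", "Rows"))
  cols <- dicom_uint16(need("0028,0011", "Columns"))
  bits <- dicom_uint16(need("0028,0100", "BitsAllocated"))
  if (bits != 16L) stop("only 16-bit pixel data supported")
  signed <- dicom_uint16(el[["0028,0103"]] %||% as.raw(c(0, 0))) == 1L
  slope <- dicom_numbers(el[["0028,1053"]] %||% charToRaw("1"))[1]
  intercept <- dicom_numbers(el[["0028,1052"]] %||% charToRaw("0"))[1]
  ps <- dicom_numbers(need("0028,0030", "PixelSpacing"))
  ipp <- dicom_numbers(need("0020,0032", "ImagePositionPatient"))
  iop <- dicom_numbers(need("0020,0037", "ImageOrientationPatient"))
  uid <- trimws(dicom_string(need("0020,000E", "SeriesInstanceUID")))
  px <- need("7FE0,0010", "PixelData")
  stored <- readBin(px, "integer", n = as.integer(rows) * as.integer(cols),
                    size = 2L, signed = signed, endian = "little")
  if (!signed) stored[stored < 0] <- stored[stored < 0] + 65536
  hu <- slope * stored + intercept
  # pixel order is row-major: x = column index, y = row index
  list(
    hu = matrix(hu, nrow = cols, ncol = rows),
    pixel_spacing = ps, ipp = ipp, iop = iop, series_uid = uid,
    spacing_z = NULL
  )
}

parse_dicom_elements <- function(bytes, offset, explicit, stop_group = NULL) {
  n <- length(bytes)
  elements <- list()
  long_vrs <- c("OB", "OW", "OF", "SQ", "UT", "UN")
  while (offset + 7L <= n) {
    group <- uint16le(bytes[offset + 0:1])
    if (!is.null(stop_group) && group != stop_group) break
    elem <- uint16le(bytes[offset + 2:3])
    tag <- sprintf("%04X,%04X", group, elem)
    if (explicit || group == 2L) {
      vr <- rawToChar(bytes[offset + 4:5])
      if (vr %in% long_vrs) {
        len <- uint32le(bytes[offset + 8:11])
        body <- offset + 12L
      } else {
        len <- uint16le(bytes[offset + 6:7])
        body <- offset + 8L
      }
    } else {
      len <- uint32le(bytes[offset + 4:7])
      body <- offset + 8L
    }
    if (len == 4294967295) stop("undefined-length DICOM elements not supported")
    if (body + len - 1L > n) stop("truncated DICOM element ", tag)
    elements[[tag]] <- if (len > 0) bytes[body:(body + len - 1L)] else raw(0)
    offset <- body + len
  }
  list(elements = elements, offset = offset)
}

uint16le <- function(b) as.integer(b[1]) + 256L * as.integer(b[2])
uint32le <- function(b) {
  as.numeric(b[1]) + 256 * as.numeric(b[2]) +
    65536 * as.numeric(b[3]) + 16777216 * as.numeric(b[4])
}
dicom_string <- function(b) if (length(b) == 0) "" else rawToChar(b)
dicom_numbers <- function(b) as.numeric(strsplit(trimws(dicom_string(b)), "\\\\")[[1]])
dicom_uint16 <- function(b) uint16le(b[1:2])
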