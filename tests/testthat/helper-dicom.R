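# Minimal explicit-VR little-endian DICOM writer used to build test series
# in code. Independent of the package's reader (write path implemented from
# the element layout directly).

dcm_u16 <- function(x) writeBin(as.integer(x), raw(), size = 2, endian = "little")
dcm_u32 <- function(x) writeBin(as.integer(x), raw(), size = 4, endian = "little")

dcm_element <- function(group, elem, vr, value) {
  head <- c(dcm_u16(group), dcm_u16(elem), charToRaw(vr))
  if (vr %in% c("OB", "OW")) {
    body <- value
    c(head, as.raw(c(0, 0)), dcm_u32(length(body)), body)
  } else if (vr == "US") {
    body <- dcm_u16(value)
    c(head, dcm_u16(length(body)), body)
  } else {
    s <- as.character(value)
    if (nchar(s) %% 2 == 1) s <- paste0(s, " ")
    body <- charToRaw(s)
    c(head, dcm_u16(length(body)), body)
  }
}

# pixels: matrix with dim1 = image column (x), dim2 = image row (y);
# stored values = (hu - intercept) / slope
write_test_dicom <- function(path, pixels, ipp = c(0, 0, 0),
                             iop = c(1, 0, 0, 0, 1, 0),
                             pixel_spacing = c(1, 1),
                             series_uid = "1.2.3.4", slope = 1,
                             intercept = 0, signed = TRUE) {
  cols <- nrow(pixels)
  rows <- ncol(pixels)
  stored <- round((as.vector(pixels)))
  px <- writeBin(as.integer(stored), raw(), size = 2, endian = "little")
  meta <- c(
    dcm_element(0x0002, 0x0010, "UI", "1.2.840.10008.1.2.1")
  )
  ds <- c(
    dcm_element(0x0008, 0x0016, "UI", "1.2.840.10008.5.1.4.1.1.2"),
    dcm_element(0x0020, 0x000E, "UI", series_uid),
    dcm_element(0x0020, 0x0032, "DS", paste(ipp, collapse = "\\")),
    dcm_element(0x0020, 0x0037, "DS", paste(iop, collapse = "\\")),
    dcm_element(0x0028, 0x0010, "US", rows),
    dcm_element(0x0028, 0x0011, "US", cols),
    dcm_element(0x0028, 0x0030, "DS", paste(pixel_spacing, collapse = "\\")),
    dcm_element(0x0028, 0x0100, "US", 16),
    dcm_element(0x0028, 0x0103, "US", if (signed) 1 else 0),
    dcm_element(0x0028, 0x1052, "DS", intercept),
    dcm_element(0x0028, 0x1053, "DS", slope),
    dcm_element(0x7FE0, 0x0010, "OW", px)
  )
  con <- file(path, "wb")
  on.exit(close(con))
  writeBin(raw(128), con)
  writeBin(charToRaw("DICM"), con)
  writeBin(c(meta, ds), con)
  invisible(path)
}

# a small synthetic axial series: constant-gradient slices, sorted by z
write_test_series <- function(dir, n_slices = 6, gap = 1.2,
                              pixel_spacing = c(0.45, 0.45),
                              shuffle_names = FALSE, uid = "9.8.7",
                              slope = 1, intercept = -1024) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  z_order <- seq_len(n_slices)
  name_order <- if (shuffle_names) rev(z_order) else z_order
  for (i in z_order) {
    # HU value = 10 * slice index; stored = (hu - intercept) / slope
    hu <- matrix(10 * i, 8, 8)
    write_test_dicom(
      file.path(dir, sprintf("im%03d.dcm", name_order[i])),
      (hu - intercept) / slope,
      ipp = c(0, 0, (i - 1) * gap),
      pixel_spacing = pixel_spacing,
      series_uid = uid, slope = slope, intercept = intercept
    )
  }
  invisible(dir)
}
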