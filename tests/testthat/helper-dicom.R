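# Writer for synthetic single-slice DICOM files (explicit VR little-endian),
# used to exercise the series-to-NIfTI conversion without shipping binary
# fixtures. Pixel data are 16-bit signed integers, written row by row.

dcm_pad_even <- function(raw_val, pad = as.raw(0x20)) {
  if (length(raw_val) %% 2 == 1) c(raw_val, pad) else raw_val
}

dcm_element <- function(group, element, vr, value_raw) {
  value_raw <- dcm_pad_even(value_raw, if (vr == "UI") as.raw(0) else as.raw(0x20))
  hdr <- c(writeBin(as.integer(group), raw(), size = 2, endian = "little"),
           writeBin(as.integer(element), raw(), size = 2, endian = "little"),
           charToRaw(vr))
  if (vr %in% c("OB", "OW", "OF", "SQ", "UT", "UN")) {
    c(hdr, as.raw(c(0, 0)),
      writeBin(length(value_raw), raw(), size = 4, endian = "little"),
      value_raw)
  } else {
    c(hdr, writeBin(length(value_raw), raw(), size = 2, endian = "little"),
      value_raw)
  }
}

dcm_str_el <- function(group, element, vr, s) {
  dcm_element(group, element, vr, charToRaw(s))
}

dcm_us_el <- function(group, element, v) {
  dcm_element(group, element, "US",
              writeBin(as.integer(v), raw(), size = 2, endian = "little"))
}

# stored: integer matrix [rows, cols] of raw (pre-rescale) values
write_dicom_slice <- function(path, stored, ipp, pixel_spacing = c(0.7, 0.7),
                              thickness = 5, series_uid = "1.2.3.4",
                              slope = 1, intercept = -1024,
                              include_ipp = TRUE) {
  rows <- nrow(stored); cols <- ncol(stored)
  # row-major pixel order
  px <- writeBin(as.integer(t(stored)), raw(), size = 2, endian = "little")
  out <- c(raw(128), charToRaw("DICM"),
           dcm_str_el(0x0002, 0x0010, "UI", "1.2.840.10008.1.2.1"),
           dcm_str_el(0x0018, 0x0050, "DS", as.character(thickness)),
           dcm_str_el(0x0020, 0x000E, "UI", series_uid))
  if (include_ipp) {
    out <- c(out, dcm_str_el(0x0020, 0x0032, "DS",
                             paste(ipp, collapse = "\\")))
  }
  out <- c(out,
           dcm_us_el(0x0028, 0x0010, rows),
           dcm_us_el(0x0028, 0x0011, cols),
           dcm_str_el(0x0028, 0x0030, "DS",
                      paste(pixel_spacing, collapse = "\\")),
           dcm_us_el(0x0028, 0x0100, 16),
           dcm_us_el(0x0028, 0x0103, 1),
           dcm_str_el(0x0028, 0x1052, "DS", as.character(intercept)),
           dcm_str_el(0x0028, 0x1053, "DS", as.character(slope)),
           dcm_element(0x7FE0, 0x0010, "OW", px))
  writeBin(out, path)
  invisible(path)
}

write_dicom_series <- function(dir, n_slices = 3, size = 8, seed = 1,
                               shuffle_names = FALSE, ...) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  set.seed(seed)
  vols <- lapply(seq_len(n_slices), function(i) {
    matrix(sample(0:2000, size * size, replace = TRUE), size, size)
  })
  z <- seq(0, by = 5, length.out = n_slices)
  order_names <- if (shuffle_names) rev(seq_len(n_slices)) else seq_len(n_slices)
  for (i in seq_len(n_slices)) {
    write_dicom_slice(file.path(dir, sprintf("slice_%02d.dcm", order_names[i])),
                      vols[[i]], ipp = c(0, 0, z[i]), ...)
  }
  list(stored = vols, z = z)
}
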