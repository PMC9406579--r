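# Minimal DICOM series reader and DICOM -> NIfTI conversion.
#
# Scope: uncompressed, explicit-VR little-endian single-frame CT slices — the
# storage form scanners export and converters consume. The parser walks the
# element stream sequentially and collects the handful of tags needed to
# assemble a calibrated HU volume: grid size, pixel spacing, slice position,
# rescale slope/intercept, series identity and the pixel data.

dcm_tag <- function(group, element) sprintf("%04X,%04X", group, element)

read_dcm_element <- function(con, file) {
  hdr <- readBin(con, "raw", 4)
  if (length(hdr) < 4) return(NULL)
  group <- readBin(hdr[1:2], "integer", 1, size = 2, signed = FALSE, endian = "little")
  element <- readBin(hdr[3:4], "integer", 1, size = 2, signed = FALSE, endian = "little")
  vr <- rawToChar(readBin(con, "raw", 2))
  if (!grepl("^[A-Z]{2}$", vr)) {
    stop(sprintf("file '%s' does not look like explicit-VR little-endian DICOM (tag %s)",
                 basename(file), dcm_tag(group, element)), call. = FALSE)
  }
  if (vr %in% c("OB", "OW", "OF", "SQ", "UT", "UN")) {
    readBin(con, "raw", 2) # reserved
    len <- readBin(con, "integer", 1, size = 4, endian = "little")
  } else {
    len <- readBin(con, "integer", 1, size = 2, signed = FALSE, endian = "little")
  }
  value <- readBin(con, "raw", len)
  list(tag = dcm_tag(group, element), vr = vr, value = value)
}

dcm_string <- function(el) {
  if (is.null(el)) return(NULL)
  trimws(rawToChar(el$value[el$value != as.raw(0)]))
}

dcm_numbers <- function(el) {
  s <- dcm_string(el)
  if (is.null(s)) return(NULL)
  as.numeric(strsplit(s, "\\\\")[[1]])
}

dcm_uint16 <- function(el) {
  if (is.null(el)) return(NULL)
  readBin(el$value, "integer", 1, size = 2, signed = FALSE, endian = "little")
}

read_dicom_file <- function(file) {
  con <- file(file, "rb")
  on.exit(close(con))
  preamble <- readBin(con, "raw", 132)
  if (length(preamble) < 132 || rawToChar(preamble[129:132]) != "DICM") {
    stop(sprintf("file '%s' is missing the DICM magic marker", basename(file)),
         call. = FALSE)
  }
  els <- list()
  repeat {
    el <- read_dcm_element(con, file)
    if (is.null(el)) break
    els[[el$tag]] <- el
    if (el$tag == "7FE0,0010") break
  }
  ts <- dcm_string(els[["0002,0010"]])
  if (!is.null(ts) && ts != "1.2.840.10008.1.2.1") {
    stop(sprintf("file '%s': unsupported transfer syntax '%s'", basename(file), ts),
         call. = FALSE)
  }
  rows <- dcm_uint16(els[["0028,0010"]])
  cols <- dcm_uint16(els[["0028,0011"]])
  ipp <- dcm_numbers(els[["0020,0032"]])
  if (is.null(ipp) || length(ipp) != 3) {
    stop(sprintf("file '%s' is missing ImagePositionPatient", basename(file)),
         call. = FALSE)
  }
  if (is.null(rows) || is.null(cols)) {
    stop(sprintf("file '%s' is missing Rows/Columns", basename(file)), call. = FALSE)
  }
  bits <- dcm_uint16(els[["0028,0100"]]) %||% 16L
  if (bits != 16L) {
    stop(sprintf("file '%s': only 16-bit pixel data is supported", basename(file)),
         call. = FALSE)
  }
  signed <- (dcm_uint16(els[["0028,0103"]]) %||% 0L) == 1L
  px <- els[["7FE0,0010"]]
  if (is.null(px)) {
    stop(sprintf("file '%s' has no PixelData", basename(file)), call. = FALSE)
  }
  stored <- readBin(px$value, "integer", rows * cols, size = 2, signed = signed,
                    endian = "little")
  slope <- (dcm_numbers(els[["0028,1053"]]) %||% 1)[1]
  intercept <- (dcm_numbers(els[["0028,1052"]]) %||% 0)[1]
  spacing <- dcm_numbers(els[["0028,0030"]]) %||% c(1, 1)
  thickness <- (dcm_numbers(els[["0018,0050"]]) %||% NA_real_)[1]
  # DICOM PixelData is row-major (row by row); R fills column-major.
  hu <- t(matrix(slope * stored + intercept, cols, rows))
  list(file = file, pixels = hu, rows = rows, cols = cols, ipp = ipp,
       spacing = spacing, thickness = thickness,
       series_uid = dcm_string(els[["0020,000E"]]) %||% "")
}

#' Convert a DICOM series to an HU volume and NIfTI file
#'
#' Reads every `.dcm` file in `series_dir` (uncompressed explicit-VR
#' little-endian), verifies they belong to one series, orders the slices by
#' their ImagePositionPatient z-coordinate, applies the rescale
#' slope/intercept so voxels are in Hounsfield units, and carries pixel
#' spacing, slice thickness and origin into the NIfTI header.
#'
#' @param series_dir Directory containing one coherent DICOM series.
#' @param out_file Optional path of the NIfTI file to write (`.nii` or
#'   `.nii.gz`).
#' @return A `ct_volume`: list with `voxels` (`[rows, cols, slices]` HU
#'   array), `spacing` (mm per axis: row, column, slice), and `origin` (the
#'   ImagePositionPatient of the first slice).
#' @export
dicom_series_to_nifti <- function(series_dir, out_file = NULL) {
  files <- list.files(series_dir, pattern = "\\.dcm$", ignore.case = TRUE,
                      full.names = TRUE)
  if (length(files) == 0) {
    stop("no DICOM (.dcm) files found in ", series_dir, call. = FALSE)
  }
  slices <- lapply(sort(files), read_dicom_file)
  uids <- unique(vapply(slices, `[[`, "", "series_uid"))
  if (length(uids) > 1) {
    offender <- slices[[which(vapply(slices, `[[`, "", "series_uid") != uids[1])[1]]]$file
    stop(sprintf("directory mixes series (first offending file: '%s')",
                 basename(offender)), call. = FALSE)
  }
  dims <- unique(t(vapply(slices, function(s) c(s$rows, s$cols), numeric(2))))
  if (nrow(dims) > 1) stop("slices disagree on grid size", call. = FALSE)
  z <- vapply(slices, function(s) s$ipp[3], numeric(1))
  ord <- order(z)
  slices <- slices[ord]
  z <- z[ord]
  vox <- array(0, c(slices[[1]]$rows, slices[[1]]$cols, length(slices)))
  for (i in seq_along(slices)) vox[, , i] <- slices[[i]]$pixels
  dz <- if (length(z) > 1) mean(diff(z)) else (slices[[1]]$thickness %||% 1)
  if (!is.finite(dz) || dz <= 0) dz <- slices[[1]]$thickness %||% 1
  spacing <- c(slices[[1]]$spacing[1], slices[[1]]$spacing[2], dz)
  if (any(!is.finite(spacing) | spacing <= 0)) {
    stop("non-positive or missing voxel spacing in series", call. = FALSE)
  }
  vol <- structure(list(voxels = vox, spacing = spacing,
                        origin = slices[[1]]$ipp),
                   class = "ct_volume")
  if (!is.null(out_file)) {
    im <- RNifti::asNifti(vox)
    RNifti::pixdim(im) <- spacing
    RNifti::writeNifti(im, out_file)
  }
  vol
}
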