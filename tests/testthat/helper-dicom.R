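# Minimal DICOM part-10 writer (explicit VR little endian) for test
# fixtures: single-frame 16-bit CT slices with the geometry and rescale tags
# the reader needs. Generated at test time; nothing binary is stored in the
# repository.

dcm_u16 <- function(x) writeBin(as.integer(x), raw(), size = 2L,
                                endian = "little")
dcm_u32 <- function(x) writeBin(as.integer(x), raw(), size = 4L,
                                endian = "little")

dcm_pad <- function(s, nul = FALSE) {
  r <- charToRaw(s)
  if (length(r) %% 2L == 1L)
    r <- c(r, if (nul) as.raw(0L) else charToRaw(" "))
  r
}

dcm_element <- function(group, elem, vr, value) {
  hdr <- c(dcm_u16(group), dcm_u16(elem), charToRaw(vr))
  if (vr %in% c("OB", "OW", "OF", "SQ", "UT", "UN")) {
    c(hdr, as.raw(c(0L, 0L)), dcm_u32(length(value)), value)
  } else {
    c(hdr, dcm_u16(length(value)), value)
  }
}

# stored: integer matrix [x (column index), y (row index)], written row-major
write_test_dicom_slice <- function(path, stored,
                                   ipp = c(0, 0, 0),
                                   iop = c(1, 0, 0, 0, 1, 0),
                                   pixel_spacing = c(1, 1),  # (row, col) mm
                                   slope = 1, intercept = -1024,
                                   thickness = 1,
                                   series_uid = "1.2.3.4.5",
                                   sop_uid = "1.2.3.4.5.6",
                                   signed = FALSE,
                                   omit_rescale = FALSE) {
  cols <- nrow(stored); rows <- ncol(stored)
  ds <- function(x) dcm_pad(paste(format(x, trim = TRUE, scientific = FALSE),
                                  collapse = "\\"))
  body <- c(
    dcm_element(0x0008, 0x0018, "UI", dcm_pad(sop_uid, nul = TRUE)),
    dcm_element(0x0018, 0x0050, "DS", ds(thickness)),
    dcm_element(0x0020, 0x000E, "UI", dcm_pad(series_uid, nul = TRUE)),
    dcm_element(0x0020, 0x0032, "DS", ds(ipp)),
    dcm_element(0x0020, 0x0037, "DS", ds(iop)),
    dcm_element(0x0028, 0x0010, "US", dcm_u16(rows)),
    dcm_element(0x0028, 0x0011, "US", dcm_u16(cols)),
    dcm_element(0x0028, 0x0030, "DS", ds(pixel_spacing)),
    dcm_element(0x0028, 0x0100, "US", dcm_u16(16L)),
    dcm_element(0x0028, 0x0103, "US", dcm_u16(as.integer(signed)))
  )
  if (!omit_rescale) {
    body <- c(body,
              dcm_element(0x0028, 0x1052, "DS", ds(intercept)),
              dcm_element(0x0028, 0x1053, "DS", ds(slope)))
  }
  # row-major pixel order = column index varying fastest = as.vector(stored)
  px <- writeBin(as.integer(as.vector(stored)), raw(), size = 2L,
                 endian = "little")
  body <- c(body, dcm_element(0x7FE0, 0x0010, "OW", px))
  meta <- dcm_element(0x0002, 0x0010, "UI",
                      dcm_pad("1.2.840.10008.1.2.1", nul = TRUE))
  con <- file(path, "wb")
  on.exit(close(con))
  writeBin(c(raw(128L), charToRaw("DICM"), meta, body), con)
  invisible(path)
}

# convenience: write an n-slice series of constant-value slices
write_test_dicom_series <- function(dir, nx = 8, ny = 8, zs = c(0, 1, 2),
                                    stored_value = 924, slope = 1,
                                    intercept = -1024,
                                    pixel_spacing = c(1, 1),
                                    series_uid = "1.2.3.4.5") {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  for (k in seq_along(zs)) {
    write_test_dicom_slice(
      file.path(dir, sprintf("slice%03d.dcm", k)),
      matrix(stored_value, nx, ny), ipp = c(0, 0, zs[k]),
      pixel_spacing = pixel_spacing, slope = slope, intercept = intercept,
      series_uid = series_uid,
      sop_uid = paste0(series_uid, ".", k))
  }
  invisible(dir)
}
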