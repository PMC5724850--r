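# Minimal explicit-VR little-endian DICOM writer for test fixtures.

dcm_raw_u16 <- function(x) writeBin(as.integer(x), raw(), size = 2,
                                    endian = "little")
dcm_raw_u32 <- function(x) writeBin(as.integer(x), raw(), size = 4,
                                    endian = "little")

dcm_pad <- function(s, pad = " ") {
  b <- charToRaw(s)
  if (length(b) %% 2) b <- c(b, charToRaw(pad))
  b
}

dcm_el_short <- function(group, elem, vr, bytes) {
  c(dcm_raw_u16(group), dcm_raw_u16(elem), charToRaw(vr),
    dcm_raw_u16(length(bytes)), bytes)
}

dcm_el_long <- function(group, elem, vr, bytes) {
  c(dcm_raw_u16(group), dcm_raw_u16(elem), charToRaw(vr), as.raw(c(0, 0)),
    dcm_raw_u32(length(bytes)), bytes)
}

# write one axial slice; `img` is a rows x cols matrix of stored values
write_test_dicom_slice <- function(path, img, ipp = c(0, 0, 0),
                                   pixel_spacing = c(0.7, 0.7),
                                   slope = 1, intercept = -1024,
                                   series = "1.2.3.4.5",
                                   thickness = 1,
                                   omit_pixel_spacing = FALSE) {
  ds <- c(
    dcm_el_short(0x0018, 0x0050, "DS", dcm_pad(format(thickness))),
    dcm_el_short(0x0020, 0x000e, "UI", dcm_pad(series, " ")),
    dcm_el_short(0x0020, 0x0032, "DS",
                 dcm_pad(paste(ipp[1], ipp[2], ipp[3], sep = "\\"))),
    dcm_el_short(0x0028, 0x0010, "US", dcm_raw_u16(nrow(img))),
    dcm_el_short(0x0028, 0x0011, "US", dcm_raw_u16(ncol(img))),
    if (!omit_pixel_spacing)
      dcm_el_short(0x0028, 0x0030, "DS",
                   dcm_pad(paste(pixel_spacing[1], pixel_spacing[2],
                                 sep = "\\"))),
    dcm_el_short(0x0028, 0x0100, "US", dcm_raw_u16(16)),
    dcm_el_short(0x0028, 0x0103, "US", dcm_raw_u16(1)),
    dcm_el_short(0x0028, 0x1052, "DS", dcm_pad(format(intercept))),
    dcm_el_short(0x0028, 0x1053, "DS", dcm_pad(format(slope))),
    dcm_el_long(0x7fe0, 0x0010, "OW",
                writeBin(as.integer(t(img)), raw(), size = 2,
                         endian = "little")))
  ts <- dcm_el_short(0x0002, 0x0010, "UI",
                     dcm_pad("1.2.840.10008.1.2.1", " "))
  meta_len <- dcm_el_short(0x0002, 0x0000, "UL", dcm_raw_u32(length(ts)))
  con <- file(path, "wb")
  on.exit(close(con))
  writeBin(raw(128), con)
  writeChar("DICM", con, eos = NULL)
  writeBin(c(meta_len, ts, ds), con)
  invisible(path)
}

# a 3-slice 8x8 series with constant stored value per slice
write_test_dicom_series <- function(dir, values = c(24, 100, 500),
                                    z = c(0, 2.5, 5), ...) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  for (i in seq_along(values))
    write_test_dicom_slice(file.path(dir, sprintf("sl%02d.dcm", i)),
                           matrix(values[i], 8, 8), ipp = c(1, 2, z[i]), ...)
  dir
}
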