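# Minimal DICOM series reader: single series, uncompressed little-endian
# pixel data (implicit or explicit VR). Enough of Part 10 to ingest the
# axial CT exports this package targets; anything fancier should be
# converted upstream.

TS_IMPLICIT_LE <- "1.2.840.10008.1.2"
TS_EXPLICIT_LE <- "1.2.840.10008.1.2.1"

dcm_u16 <- function(raw, at) readBin(raw[at:(at + 1L)], "integer", size = 2L,
                                     signed = FALSE, endian = "little")
dcm_u32 <- function(raw, at) readBin(raw[at:(at + 3L)], "integer", size = 4L,
                                     endian = "little")

# parse one dataset; returns named list keyed "gggg,eeee" -> raw value
dcm_parse <- function(raw, start, explicit, stop_before_pixels = FALSE) {
  out <- list()
  pos <- start
  n <- length(raw)
  long_vrs <- c("OB", "OW", "OF", "SQ", "UT", "UN")
  while (pos + 7L <= n) {
    group <- dcm_u16(raw, pos); elem <- dcm_u16(raw, pos + 2L)
    key <- sprintf("%04x,%04x", group, elem)
    if (explicit) {
      vr <- rawToChar(raw[(pos + 4L):(pos + 5L)])
      if (vr %in% long_vrs) {
        len <- dcm_u32(raw, pos + 8L); hdr <- 12L
      } else {
        len <- dcm_u16(raw, pos + 6L); hdr <- 8L
      }
    } else {
      vr <- NA_character_
      len <- dcm_u32(raw, pos + 4L); hdr <- 8L
    }
    if (len < 0L || identical(len, -1L))
      stop("undefined-length DICOM element ", key, " is not supported")
    if (key == "7fe0,0010" && stop_before_pixels) {
      out[["..pixel_at"]] <- pos + hdr
      out[["..pixel_len"]] <- len
      break
    }
    if (pos + hdr + len - 1L > n) stop("truncated DICOM element ", key)
    out[[key]] <- if (len > 0L) raw[(pos + hdr):(pos + hdr + len - 1L)] else raw(0)
    pos <- pos + hdr + len
  }
  out
}

dcm_str <- function(el) if (is.null(el)) NULL else trimws(rawToChar(el), whitespace = "[ \\0\r\n\t]")
dcm_nums <- function(el) if (is.null(el)) NULL else as.numeric(strsplit(dcm_str(el), "\\\\")[[1]])

read_dicom_file <- function(path) {
  raw <- readBin(path, "raw", n = file.size(path))
  if (length(raw) < 160L || rawToChar(raw[129:132]) != "DICM")
    stop("not a DICOM Part 10 file (missing DICM magic): ", path)
  # file meta group is always explicit VR little endian; its first element
  # (0002,0000) UL gives the byte length of the remaining meta elements
  if (dcm_u16(raw, 133L) != 2L || dcm_u16(raw, 135L) != 0L)
    stop("DICOM file meta header misses FileMetaInformationGroupLength: ", path)
  meta_len <- dcm_u32(raw, 141L)
  meta <- dcm_parse(raw[(133L + 12L):(132L + 12L + meta_len)], 1L,
                    explicit = TRUE)
  ts <- dcm_str(meta[["0002,0010"]])
  if (is.null(ts)) stop("DICOM file misses TransferSyntaxUID (0002,0010): ", path)
  if (!ts %in% c(TS_IMPLICIT_LE, TS_EXPLICIT_LE))
    stop("unsupported DICOM transfer syntax ", ts, " in ", path)
  ds_start <- 133L + 12L + meta_len
  ds <- dcm_parse(raw, ds_start, explicit = ts == TS_EXPLICIT_LE,
                  stop_before_pixels = TRUE)

  bits <- dcm_binint(ds[["0028,0100"]], path, "BitsAllocated (0028,0100)")
  rows <- dcm_binint(ds[["0028,0010"]], path, "Rows (0028,0010)")
  cols <- dcm_binint(ds[["0028,0011"]], path, "Columns (0028,0011)")
  pixrep <- dcm_binint(ds[["0028,0103"]], path, "PixelRepresentation (0028,0103)")
  if (!bits %in% c(8L, 16L)) stop("unsupported BitsAllocated ", bits, " in ", path)
  ps <- dcm_nums(ds[["0028,0030"]])
  if (is.null(ps)) stop("DICOM header misses PixelSpacing (0028,0030): ", path)
  ipp <- dcm_nums(ds[["0020,0032"]])
  if (is.null(ipp)) stop("DICOM header misses ImagePositionPatient (0020,0032): ", path)
  slope <- dcm_nums(ds[["0028,1053"]]); if (is.null(slope)) slope <- 1
  icept <- dcm_nums(ds[["0028,1052"]]); if (is.null(icept)) icept <- 0
  series <- dcm_str(ds[["0020,000e"]]); if (is.null(series)) series <- ""
  thick <- dcm_nums(ds[["0018,0050"]])

  if (is.null(ds[["..pixel_at"]])) stop("DICOM file has no PixelData: ", path)
  at <- ds[["..pixel_at"]]; len <- ds[["..pixel_len"]]
  npix <- rows * cols
  if (len < npix * bits / 8L) stop("PixelData shorter than Rows*Columns in ", path)
  px <- readBin(raw[at:(at + len - 1L)], "integer", n = npix, size = bits / 8L,
                signed = pixrep == 1L, endian = "little")
  # stored (col fastest within row): DICOM pixel order is row-major,
  # i.e. columns vary fastest -> matrix(ncol-fastest) needs byrow
  img <- matrix(px, nrow = rows, ncol = cols, byrow = TRUE)
  list(hu = img * slope + icept, spacing_rc = ps, ipp = ipp,
       series = series, thickness = thick)
}

dcm_binint <- function(el, path, what) {
  if (is.null(el)) stop("DICOM header misses ", what, ": ", path)
  if (length(el) == 2L) dcm_u16(el, 1L)
  else if (length(el) == 4L) dcm_u32(el, 1L)
  else as.integer(dcm_str(el))
}

read_dicom_series <- function(dir) {
  files <- list.files(dir, full.names = TRUE)
  files <- files[!dir.exists(files)]
  if (length(files) == 0L) stop("no files in DICOM directory: ", dir)
  slices <- lapply(files, read_dicom_file)
  series <- vapply(slices, `[[`, "", "series")
  if (length(unique(series)) > 1L)
    stop("directory contains more than one DICOM series: ", dir)
  z <- vapply(slices, function(s) s$ipp[3], 0)
  ord <- order(z)
  slices <- slices[ord]; z <- z[ord]
  d <- dim(slices[[1]]$hu)
  if (!all(vapply(slices, function(s) identical(dim(s$hu), d), TRUE)))
    stop("inconsistent slice dimensions in DICOM series: ", dir)
  vox <- array(0, c(length(slices), d[1], d[2]))
  for (k in seq_along(slices)) vox[k, , ] <- slices[[k]]$hu
  sz <- if (length(slices) > 1L) {
    dz <- diff(z)
    if (any(dz <= 0)) stop("duplicate slice positions in DICOM series: ", dir)
    stats::median(dz)
  } else if (!is.null(slices[[1]]$thickness)) slices[[1]]$thickness
  else stop("cannot determine slice spacing: single slice without ",
            "SliceThickness (0018,0050) in ", dir)
  ps <- slices[[1]]$spacing_rc     # (row spacing = y, column spacing = x)
  ipp <- slices[[1]]$ipp
  list(voxels = vox, spacing = c(sz, ps[1], ps[2]),
       origin = c(z[1], ipp[2], ipp[1]))
}
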