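# MetaImage (.mha/.mhd) reader and writer.
#
# The format is a plain "Key = Value" ASCII header followed by (or pointing
# to) a raw little-endian voxel block, x fastest. Only uncompressed payloads
# are written; zlib-compressed payloads are accepted on read.

META_TYPES <- list(
  MET_UCHAR  = list(what = "integer", size = 1L, signed = FALSE),
  MET_CHAR   = list(what = "integer", size = 1L, signed = TRUE),
  MET_USHORT = list(what = "integer", size = 2L, signed = FALSE),
  MET_SHORT  = list(what = "integer", size = 2L, signed = TRUE),
  MET_INT    = list(what = "integer", size = 4L, signed = TRUE),
  MET_FLOAT  = list(what = "double",  size = 4L, signed = TRUE),
  MET_DOUBLE = list(what = "double",  size = 8L, signed = TRUE)
)

read_metaimage <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  hdr <- list()
  repeat {
    line <- readLines(con, n = 1L, warn = FALSE)
    if (length(line) == 0L) stop("MetaImage header ended before ElementDataFile: ", path)
    kv <- regmatches(line, regexec("^\\s*([A-Za-z0-9_]+)\\s*=\\s*(.*?)\\s*$", line))[[1]]
    if (length(kv) != 3L) stop("malformed MetaImage header line: ", line)
    hdr[[kv[2]]] <- kv[3]
    if (kv[2] == "ElementDataFile") break
  }
  need <- function(key) {
    if (is.null(hdr[[key]])) stop("MetaImage header misses required field '", key, "'")
    hdr[[key]]
  }
  ndims <- as.integer(need("NDims"))
  if (ndims != 3L) stop("only 3-D MetaImage volumes are supported (NDims = ", ndims, ")")
  dims <- as.integer(strsplit(need("DimSize"), "\\s+")[[1]])     # x y z
  sp <- as.numeric(strsplit(need("ElementSpacing"), "\\s+")[[1]]) # x y z
  off <- if (!is.null(hdr$Offset)) as.numeric(strsplit(hdr$Offset, "\\s+")[[1]]) else c(0, 0, 0)
  tinfo <- META_TYPES[[need("ElementType")]]
  if (is.null(tinfo)) stop("unsupported MetaImage ElementType: ", hdr$ElementType)
  if (!is.null(hdr$BinaryDataByteOrderMSB) &&
      tolower(hdr$BinaryDataByteOrderMSB) == "true")
    stop("big-endian MetaImage payloads are not supported")
  n <- prod(dims)
  compressed <- !is.null(hdr$CompressedData) && tolower(hdr$CompressedData) == "true"
  datafile <- hdr$ElementDataFile
  if (identical(datafile, "LOCAL")) {
    raw_len <- if (compressed) as.integer(hdr$CompressedDataSize) else n * tinfo$size
    payload <- readBin(con, "raw", n = raw_len)
  } else {
    dpath <- file.path(dirname(path), datafile)
    if (!file.exists(dpath)) stop("MetaImage data file not found: ", dpath)
    payload <- readBin(dpath, "raw", n = file.size(dpath))
  }
  if (compressed) payload <- memDecompress(payload, type = "gzip")
  vals <- readBin(payload, tinfo$what, n = n, size = tinfo$size,
                  signed = if (tinfo$size < 4L) tinfo$signed else TRUE,
                  endian = "little")
  if (length(vals) != n) stop("MetaImage payload truncated: ", path)
  arr <- array(as.numeric(vals), dim = dims)     # (x, y, z), x fastest
  list(voxels = aperm(arr, c(3, 2, 1)),          # -> (z, y, x)
       spacing = rev(sp), origin = rev(off))
}

write_metaimage <- function(voxels, spacing, origin, path,
                            element_type = "MET_FLOAT") {
  tinfo <- META_TYPES[[element_type]]
  if (is.null(tinfo)) stop("unsupported ElementType: ", element_type)
  d <- dim(voxels)
  ext <- tolower(tools::file_ext(path))
  arr <- aperm(voxels, c(3, 2, 1))               # (z,y,x) -> (x,y,z), x fastest
  vals <- if (tinfo$what == "integer") as.integer(round(arr)) else as.vector(arr)
  hdr <- c("ObjectType = Image",
           "NDims = 3",
           "BinaryData = True",
           "BinaryDataByteOrderMSB = False",
           "CompressedData = False",
           "TransformMatrix = 1 0 0 0 1 0 0 0 1",
           sprintf("Offset = %.17g %.17g %.17g", origin[3], origin[2], origin[1]),
           "CenterOfRotation = 0 0 0",
           sprintf("ElementSpacing = %.17g %.17g %.17g",
                   spacing[3], spacing[2], spacing[1]),
           sprintf("DimSize = %d %d %d", d[3], d[2], d[1]),
           sprintf("ElementType = %s", element_type))
  if (ext == "mha") {
    con <- file(path, "wb")
    on.exit(close(con))
    writeLines(c(hdr, "ElementDataFile = LOCAL"), con)
    writeBin(vals, con, size = tinfo$size, endian = "little")
  } else if (ext == "mhd") {
    rawname <- paste0(tools::file_path_sans_ext(basename(path)), ".raw")
    writeLines(c(hdr, paste("ElementDataFile =", rawname)), path)
    con <- file(file.path(dirname(path), rawname), "wb")
    on.exit(close(con))
    writeBin(vals, con, size = tinfo$size, endian = "little")
  } else stop("unsupported MetaImage extension: .", ext)
  invisible(NULL)
}
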