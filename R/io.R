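#' Read a CT volume
#'
#' Reads MetaImage (\code{.mha}/\code{.mhd}), NIfTI-1 (\code{.nii},
#' \code{.nii.gz}) files or a directory holding one uncompressed DICOM
#' series. DICOM stored values are converted to HU with RescaleSlope and
#' RescaleIntercept and slices are sorted along the patient axis. On ingest,
#' values are clamped to the plausible HU range [-1100, 3200] (a count of
#' clamped voxels is messaged); the -950 HU density-mask threshold is well
#' inside this range, so clamping never alters an emphysema score.
#'
#' @param path file path or DICOM directory.
#' @param clamp_hu clamp values to the plausible HU range (default TRUE).
#' @return a [ct_volume] with axis order (z, y, x) and spacing (sz, sy, sx)
#'   in mm.
#' @seealso [write_volume()], [read_mask()]
#' @export
read_volume <- function(path, clamp_hu = TRUE) {
  raw <- read_any_raster(path)
  ct_volume(raw$voxels, raw$spacing, raw$origin, clamp_hu = clamp_hu)
}

#' Write a CT volume
#'
#' Writes MetaImage (\code{.mha}/\code{.mhd}, float32 payload) or NIfTI
#' (\code{.nii}/\code{.nii.gz}, float32). [read_volume()] inverts the write
#' losslessly for values representable in float32. DICOM writing is not
#' supported.
#'
#' @param volume a [ct_volume].
#' @param path output path; the extension selects the format.
#' @export
write_volume <- function(volume, path) {
  stopifnot(inherits(volume, "ct_volume"))
  write_any_raster(volume$voxels, volume$spacing, volume$origin, path,
                   element_type = "MET_FLOAT", nifti_type = "float")
}

#' Read or write a binary mask
#'
#' Masks use the same raster formats as volumes; on read any value greater
#' than zero becomes \code{TRUE}. A mask of all zeros is read back empty
#' (and flagged with a message).
#'
#' @param path mask file path.
#' @return a [lung_mask].
#' @rdname mask_io
#' @export
read_mask <- function(path) {
  raw <- read_any_raster(path)
  m <- lung_mask(raw$voxels > 0, raw$spacing, raw$origin)
  if (!any(m$voxels)) message("mask read from ", path, " is empty")
  m
}

#' @param mask a [lung_mask].
#' @rdname mask_io
#' @export
write_mask <- function(mask, path) {
  stopifnot(inherits(mask, "lung_mask"))
  write_any_raster(mask$voxels + 0, mask$spacing, mask$origin, path,
                   element_type = "MET_UCHAR", nifti_type = "uint8")
}

read_any_raster <- function(path) {
  if (dir.exists(path)) return(read_dicom_series(path))
  if (!file.exists(path)) stop("file not found: ", path)
  low <- tolower(path)
  if (grepl("\\.(mha|mhd)$", low)) {
    read_metaimage(path)
  } else if (grepl("\\.nii(\\.gz)?$", low)) {
    img <- RNifti::readNifti(path)
    arr <- as.array(img)
    if (length(dim(arr)) != 3L) stop("NIfTI volume is not 3-D: ", path)
    pd <- RNifti::pixdim(img)                     # (x, y, z)
    x <- RNifti::xform(img)
    list(voxels = aperm(arr, c(3, 2, 1)), spacing = rev(pd[1:3]),
         origin = rev(unname(x[1:3, 4])))
  } else stop("unsupported volume format: ", basename(path),
              " (expected .mha, .mhd, .nii, .nii.gz or a DICOM directory)")
}

write_any_raster <- function(voxels, spacing, origin, path,
                             element_type, nifti_type) {
  if (!dir.exists(dirname(path)))
    stop("parent directory does not exist: ", dirname(path))
  low <- tolower(path)
  if (grepl("\\.(mha|mhd)$", low)) {
    write_metaimage(voxels, spacing, origin, path, element_type)
  } else if (grepl("\\.nii(\\.gz)?$", low)) {
    img <- RNifti::asNifti(aperm(voxels, c(3, 2, 1)))   # -> (x, y, z)
    RNifti::pixdim(img) <- rev(spacing)
    q <- structure(diag(c(rev(spacing), 1)), code = 2L)
    q[1:3, 4] <- rev(origin)
    img <- RNifti::`qform<-`(img, value = q)
    RNifti::writeNifti(img, path, datatype = nifti_type)
  } else stop("unsupported volume format: ", basename(path))
  invisible(NULL)
}
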