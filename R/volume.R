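#' CT volume container
#'
#' A \code{ct_volume} holds a 3-D grid of CT attenuation values in Hounsfield
#' Units together with its physical geometry. The axis order is fixed as
#' (slice z, row y, column x): \code{voxels[k, j, i]} sits at physical
#' position \code{origin + (k - 1, j - 1, i - 1) * spacing}, so every
#' per-slice operation in the package iterates over the first array axis.
#'
#' @param voxels numeric 3-D array, axis order (z, y, x).
#' @param spacing numeric length-3, voxel spacing (sz, sy, sx) in mm; all
#'   strictly positive.
#' @param origin numeric length-3, physical position (oz, oy, ox) of the
#'   first voxel centre in mm.
#' @param clamp_hu if \code{TRUE} (the ingest default), voxel values are
#'   clamped to the plausible HU range [-1100, 3200]; the number of clamped
#'   voxels is reported with a message.
#' @return an object of class \code{ct_volume}.
#' @export
ct_volume <- function(voxels, spacing, origin = c(0, 0, 0), clamp_hu = FALSE) {
  if (!is.array(voxels) || length(dim(voxels)) != 3L)
    stop("'voxels' must be a 3-D array (z, y, x)")
  storage.mode(voxels) <- "double"
  if (any(!is.finite(voxels)))
    stop("voxel values must be finite")
  d <- dim(voxels)
  if (d[1] < 2L || d[2] < 8L || d[3] < 8L)
    stop("volume too small: need at least 2 slices of 8x8 voxels")
  spacing <- as.numeric(spacing)
  origin <- as.numeric(origin)
  if (length(spacing) != 3L || any(!is.finite(spacing)) || any(spacing <= 0))
    stop("'spacing' must be 3 strictly positive values (sz, sy, sx)")
  if (length(origin) != 3L || any(!is.finite(origin)))
    stop("'origin' must be 3 finite values (oz, oy, ox)")
  if (clamp_hu) {
    n_out <- sum(voxels < HU_MIN | voxels > HU_MAX)
    if (n_out > 0L) {
      voxels[voxels < HU_MIN] <- HU_MIN
      voxels[voxels > HU_MAX] <- HU_MAX
      message(sprintf("clamped %d voxel(s) to the HU range [%d, %d]",
                      n_out, HU_MIN, HU_MAX))
    }
  }
  structure(list(voxels = voxels, spacing = spacing, origin = origin),
            class = "ct_volume")
}

HU_MIN <- -1100
HU_MAX <- 3200

#' @export
print.ct_volume <- function(x, ...) {
  d <- dim(x$voxels)
  cat(sprintf("ct_volume: %d x %d x %d voxels (z, y, x)\n", d[1], d[2], d[3]))
  cat(sprintf("  spacing %.4g x %.4g x %.4g mm, origin (%.4g, %.4g, %.4g) mm\n",
              x$spacing[1], x$spacing[2], x$spacing[3],
              x$origin[1], x$origin[2], x$origin[3]))
  cat(sprintf("  HU range [%.1f, %.1f]\n", min(x$voxels), max(x$voxels)))
  invisible(x)
}

#' Binary lung mask aligned to a CT volume
#'
#' @param voxels logical or 0/1 numeric 3-D array with the same shape as the
#'   parent volume.
#' @param spacing,origin geometry, normally copied from the parent volume.
#' @return an object of class \code{lung_mask}; \code{$voxels} is logical.
#' @export
lung_mask <- function(voxels, spacing, origin = c(0, 0, 0)) {
  if (!is.array(voxels) || length(dim(voxels)) != 3L)
    stop("'voxels' must be a 3-D array (z, y, x)")
  v <- voxels != 0
  spacing <- as.numeric(spacing)
  if (length(spacing) != 3L || any(spacing <= 0))
    stop("'spacing' must be 3 strictly positive values")
  structure(list(voxels = v, spacing = spacing, origin = as.numeric(origin)),
            class = "lung_mask")
}

#' @export
print.lung_mask <- function(x, ...) {
  d <- dim(x$voxels)
  cat(sprintf("lung_mask: %d x %d x %d voxels, %d set (%.2f%%)\n",
              d[1], d[2], d[3], sum(x$voxels),
              100 * mean(x$voxels)))
  invisible(x)
}

# mask must share the parent volume's raster
check_aligned <- function(volume, mask) {
  stopifnot(inherits(volume, "ct_volume"), inherits(mask, "lung_mask"))
  if (!identical(dim(volume$voxels), dim(mask$voxels)))
    stop("mask shape does not match its parent volume")
  if (max(abs(volume$spacing - mask$spacing)) > 1e-6)
    stop("mask spacing does not match its parent volume")
  invisible(TRUE)
}
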