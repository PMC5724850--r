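#' Resample a volume along z to a target slice thickness
#'
#' Models thick-slice acquisition as slab averaging: the input volume is
#' treated as a stack of piecewise-constant slabs of thickness \code{sz},
#' and every output slice is the overlap-weighted average of the input
#' slabs covered by its \code{target}-mm slab (a box filter along z,
#' sampled every \code{target} mm). The in-plane grid is unchanged; the
#' number of output slices is \code{round(extent / target)} (at least 1),
#' so the physical extent is preserved to within one slab. The same weights
#' are applied to the mask, which is then re-binarized at 0.5.
#'
#' @param volume a [ct_volume].
#' @param mask optional [lung_mask] aligned with \code{volume}.
#' @param target output slice thickness in mm (default 3).
#' @return a list with elements \code{volume} and (if a mask was supplied)
#'   \code{mask}.
#' @export
resample_z <- function(volume, mask = NULL, target = 3) {
  stopifnot(inherits(volume, "ct_volume"))
  if (!is.numeric(target) || length(target) != 1L || target <= 0)
    stop("'target' slice thickness must be a single positive number")
  if (!is.null(mask)) check_aligned(volume, mask)
  sz <- volume$spacing[1]
  if (abs(sz - target) < 1e-9)
    return(list(volume = volume, mask = mask))
  d <- dim(volume$voxels)
  W <- slab_weights(d[1], sz, target)
  vox <- array(W %*% matrix(volume$voxels, d[1]), c(nrow(W), d[2], d[3]))
  new_spacing <- c(target, volume$spacing[2:3])
  # keep the leading slab edge fixed: first voxel centre moves from
  # oz to oz - sz/2 + target/2
  new_origin <- c(volume$origin[1] - sz / 2 + target / 2, volume$origin[2:3])
  out <- list(volume = ct_volume(vox, new_spacing, new_origin))
  if (!is.null(mask)) {
    mfrac <- array(W %*% matrix(mask$voxels + 0, d[1]), c(nrow(W), d[2], d[3]))
    out$mask <- lung_mask(mfrac >= 0.5, new_spacing, new_origin)
  }
  out
}

# overlap weight matrix between n_in input slabs of thickness sz and output
# slabs of thickness target, both tiled from z = 0; rows normalized by the
# covered extent so a partial final slab averages only what it covers
slab_weights <- function(n_in, sz, target) {
  extent <- n_in * sz
  n_out <- max(1L, as.integer(round(extent / target)))
  lo_in <- (seq_len(n_in) - 1) * sz;    hi_in <- lo_in + sz
  lo_out <- (seq_len(n_out) - 1) * target
  hi_out <- pmin(lo_out + target, extent)
  W <- matrix(0, n_out, n_in)
  for (j in seq_len(n_out)) {
    ov <- pmin(hi_in, hi_out[j]) - pmax(lo_in, lo_out[j])
    ov[ov < 0] <- 0
    if (sum(ov) <= 0) stop("internal error: empty output slab in resample_z")
    W[j, ] <- ov / sum(ov)
  }
  W
}
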