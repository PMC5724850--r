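# Density-mask scoring and the per-slice bullae filter.

# 8-connected labeling of a binary matrix: EBImage::bwlabel (4-connected)
# followed by union-find merging of labels that touch diagonally
label_components_8 <- function(slice) {
  lab <- EBImage::bwlabel(slice)
  nlab <- max(lab)
  if (nlab <= 1L) return(lab)
  parent <- seq_len(nlab)
  find <- function(i) { while (parent[i] != i) i <- parent[i]; i }
  nr <- nrow(lab); nc <- ncol(lab)
  pairs <- rbind(
    cbind(as.vector(lab[-nr, -nc]), as.vector(lab[-1, -1])),   # down-right
    cbind(as.vector(lab[-nr, -1]), as.vector(lab[-1, -nc])))   # down-left
  pairs <- pairs[pairs[, 1] > 0 & pairs[, 2] > 0 &
                   pairs[, 1] != pairs[, 2], , drop = FALSE]
  if (nrow(pairs)) {
    pairs <- unique(pairs)
    for (r in seq_len(nrow(pairs))) {
      a <- find(pairs[r, 1]); b <- find(pairs[r, 2])
      if (a != b) parent[max(a, b)] <- min(a, b)
    }
  }
  root <- vapply(seq_len(nlab), find, 0L)
  relab <- match(root, sort(unique(root)))
  out <- lab
  out[lab > 0] <- relab[lab[lab > 0]]
  out
}

#' Filter out small low-attenuation clusters (bullae analysis)
#'
#' Air clusters below the density-mask threshold that are smaller than
#' \code{min_area} in a single axial slice are treated as noise and
#' discarded. Components are 2-D, 8-connected, measured per slice; a
#' component survives iff its area \code{n_pixels * sy * sx} is at least
#' \code{min_area} mm^2 (clusters strictly below the cutoff are dropped).
#'
#' @param low_mask logical (z, y, x) array of sub-threshold voxels (already
#'   intersected with the lung mask), or a 2-D matrix for a single slice.
#' @param spacing in-plane pixel spacing \code{c(sy, sx)} in mm.
#' @param min_area minimum surviving cluster area in mm^2 (default 5).
#' @return a logical array of the same shape: the union of kept components.
#' @export
filter_small_clusters <- function(low_mask, spacing, min_area = 5) {
  spacing <- as.numeric(spacing)
  if (length(spacing) != 2L || any(spacing <= 0))
    stop("'spacing' must be the in-plane pixel sizes c(sy, sx) in mm")
  if (min_area < 0) stop("'min_area' must be non-negative")
  px_area <- spacing[1] * spacing[2]
  filt2 <- function(m) {
    if (!any(m)) return(m != 0)
    lab <- label_components_8(m + 0)
    sizes <- tabulate(lab[lab > 0])
    keep <- which(sizes * px_area >= min_area)
    array(lab %in% keep, dim(m))
  }
  if (length(dim(low_mask)) == 2L || is.matrix(low_mask)) return(filt2(low_mask))
  out <- array(FALSE, dim(low_mask))
  for (k in seq_len(dim(low_mask)[1])) out[k, , ] <- filt2(low_mask[k, , ])
  out
}

#' Emphysema score (density mask)
#'
#' The emphysema score is the percentage of lung voxels with attenuation
#' strictly below the density-mask threshold (default -950 HU). With
#' \code{bullae_filter = TRUE} the sub-threshold voxels first pass
#' [filter_small_clusters()], discarding per-slice clusters smaller than
#' \code{config$min_cluster_area}.
#'
#' @param volume a [ct_volume].
#' @param mask a nonempty [lung_mask] on the same grid.
#' @param config a [quant_config].
#' @param bullae_filter apply the small-cluster filter (default FALSE).
#' @param mode label stored in the result (\code{"orig"} or \code{"norm"}).
#' @return an object of class \code{emphysema_result} with \code{score}
#'   (percent), \code{n_lung_voxels}, \code{n_emphysema_voxels},
#'   \code{n_clusters_kept}, \code{n_clusters_removed}, \code{mode}.
#' @export
emphysema_score <- function(volume, mask, config = quant_config(),
                            bullae_filter = FALSE, mode = "orig") {
  check_aligned(volume, mask)
  n_lung <- sum(mask$voxels)
  if (n_lung == 0L) stop("empty lung mask")
  low <- mask$voxels & (volume$voxels < config$density_threshold)
  kept <- removed <- NA_integer_
  if (bullae_filter) {
    surv <- filter_small_clusters(low, volume$spacing[2:3],
                                  config$min_cluster_area)
    cl <- count_clusters(low, surv)
    kept <- cl[1]; removed <- cl[2]
    low <- surv
  }
  n_emph <- sum(low)
  structure(list(score = 100 * n_emph / n_lung,
                 n_lung_voxels = n_lung, n_emphysema_voxels = n_emph,
                 n_clusters_kept = kept, n_clusters_removed = removed,
                 mode = mode),
            class = "emphysema_result")
}

count_clusters <- function(low, surviving) {
  kept <- 0L; removed <- 0L
  for (k in seq_len(dim(low)[1])) {
    lab <- label_components_8(low[k, , ] + 0)
    nlab <- max(lab)
    if (nlab == 0L) next
    alive <- unique(lab[surviving[k, , ] & lab > 0])
    kept <- kept + length(alive)
    removed <- removed + nlab - length(alive)
  }
  c(kept, removed)
}

#' @export
print.emphysema_result <- function(x, ...) {
  cat(sprintf("%sES = %.2f%% (%d of %d lung voxels below threshold)\n",
              x$mode, x$score, x$n_emphysema_voxels, x$n_lung_voxels))
  if (!is.na(x$n_clusters_kept))
    cat(sprintf("  bullae filter: %d cluster(s) kept, %d removed\n",
                x$n_clusters_kept, x$n_clusters_removed))
  invisible(x)
}

#' Conventional emphysema score (origES)
#'
#' The density-mask score on the unmodified scan: no resampling, no kernel
#' normalization, no bullae filtering.
#'
#' @inheritParams emphysema_score
#' @return an \code{emphysema_result} with \code{mode = "orig"}.
#' @export
compute_orig_es <- function(volume, mask, config = quant_config()) {
  emphysema_score(volume, mask, config, bullae_filter = FALSE, mode = "orig")
}

#' Normalized emphysema score (normES)
#'
#' The harmonized score: the scan (and its mask) is resampled to the target
#' slice thickness, normalized toward the reference kernel profile (band
#' energies are measured on the resampled scan), and scored with the bullae
#' filter on.
#'
#' @inheritParams emphysema_score
#' @param profile a [reference_profile].
#' @return an \code{emphysema_result} with \code{mode = "norm"}.
#' @export
compute_norm_es <- function(volume, mask, profile, config = quant_config()) {
  rs <- resample_z(volume, mask, config$target_slice_thickness)
  vn <- apply_normalization(rs$volume, rs$mask, profile, config)
  emphysema_score(vn, rs$mask, config, bullae_filter = TRUE, mode = "norm")
}
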