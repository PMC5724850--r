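#' Lung segmentation configuration
#'
#' @param air_threshold HU below which a voxel is air-like (default -500);
#'   must lie in (-1000, 0).
#' @param min_component_volume smallest candidate component kept, in ml
#'   (default 50).
#' @param closing_radius radius in mm of the spherical structuring element
#'   used for morphological closing (default 2).
#' @param keep_components number of largest interior components retained
#'   (default 2: the two lungs; they may merge into one component at the
#'   carina on some scans).
#' @return an object of class \code{segmentation_config}.
#' @export
segmentation_config <- function(air_threshold = -500,
                                min_component_volume = 50,
                                closing_radius = 2, keep_components = 2) {
  stopifnot(air_threshold > -1000, air_threshold < 0, closing_radius >= 0,
            min_component_volume >= 0, keep_components >= 1)
  structure(list(air_threshold = air_threshold,
                 min_component_volume = min_component_volume,
                 closing_radius = closing_radius,
                 keep_components = as.integer(keep_components)),
            class = "segmentation_config")
}

# 6-connected 3-D labeling: 4-connected 2-D labels per slice via
# EBImage::bwlabel, then union-find merging of labels that overlap
# between adjacent slices
label_components_3d <- function(binary) {
  d <- dim(binary)
  labs <- array(0L, d)
  offset <- 0L
  for (k in seq_len(d[1])) {
    lk <- EBImage::bwlabel(binary[k, , ] + 0)
    lk <- matrix(as.integer(lk), d[2], d[3])
    pos <- lk > 0L
    mx <- if (any(pos)) max(lk) else 0L
    lk[pos] <- lk[pos] + offset
    offset <- offset + mx
    labs[k, , ] <- lk
  }
  if (offset == 0L) return(labs)
  parent <- seq_len(offset)
  find <- function(i) { while (parent[i] != i) i <- parent[i]; i }
  for (k in seq_len(d[1] - 1L)) {
    a <- labs[k, , ]; b <- labs[k + 1L, , ]
    both <- a > 0L & b > 0L
    if (!any(both)) next
    pairs <- unique(cbind(a[both], b[both]))
    for (r in seq_len(nrow(pairs))) {
      ra <- find(pairs[r, 1]); rb <- find(pairs[r, 2])
      if (ra != rb) parent[max(ra, rb)] <- min(ra, rb)
    }
  }
  root <- vapply(seq_len(offset), find, 0L)
  relab <- match(root, sort(unique(root)))
  pos <- labs > 0L
  labs[pos] <- relab[labs[pos]]
  labs
}

#' Segment the lungs from a chest CT
#'
#' Threshold-based lung extraction with morphological smoothing: voxels
#' below \code{air_threshold} HU are air candidates; any candidate
#' component touching the volume's in-plane border is exterior air and is
#' removed; components smaller than \code{min_component_volume} ml are
#' removed; the \code{keep_components} largest remaining components form
#' the lungs, smoothed by morphological closing (spherical element of
#' \code{closing_radius} mm) and slice-wise hole filling.
#'
#' @param volume a [ct_volume] covering thorax-like content.
#' @param config a [segmentation_config].
#' @return a nonempty [lung_mask].
#' @export
segment_lungs <- function(volume, config = segmentation_config()) {
  stopifnot(inherits(volume, "ct_volume"),
            inherits(config, "segmentation_config"))
  air <- volume$voxels < config$air_threshold
  if (!any(air)) stop("no lung found: no voxels below the air threshold")
  labs <- label_components_3d(air)
  d <- dim(labs)
  border <- unique(c(labs[, c(1, d[2]), ], labs[, , c(1, d[3])]))
  border <- border[border > 0L]
  voxel_ml <- prod(volume$spacing) / 1000
  sizes <- tabulate(labs[labs > 0L])
  keep <- setdiff(which(sizes * voxel_ml >= config$min_component_volume),
                  border)
  if (length(keep) == 0L) stop("no lung found: no interior air component ",
                               "of at least ", config$min_component_volume,
                               " ml")
  keep <- keep[order(sizes[keep], decreasing = TRUE)]
  keep <- keep[seq_len(min(length(keep), config$keep_components))]
  m <- array(labs %in% keep, d)
  m <- close3(m, config$closing_radius, volume$spacing)
  for (k in seq_len(d[1])) {
    filled <- EBImage::fillHull(m[k, , ] + 0)
    m[k, , ] <- m[k, , ] | (filled > 0)
  }
  if (!any(m)) stop("no lung found")
  lung_mask(m, volume$spacing, volume$origin)
}
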