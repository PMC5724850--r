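#' Digital chest phantom specification
#'
#' Describes a simple thorax: exterior air around a soft-tissue body
#' cylinder holding two ellipsoidal lungs with Gaussian parenchymal
#' texture, into which spherical emphysematous low-attenuation clusters are
#' placed uniformly without overlap. Ground truth (lung mask, emphysema
#' mask, true emphysema fraction) is exact and machine-readable.
#'
#' @param shape grid size (nz, ny, nx); default c(60, 84, 84).
#' @param spacing voxel spacing (sz, sy, sx) mm; default c(1, 1.5, 1.5).
#' @param body_hu soft-tissue attenuation (default 40 HU).
#' @param parenchyma_mean,texture_sd lung texture N(mean, sd) in HU
#'   (defaults -860 and 40, an inflated-lung appearance whose -950 HU tail
#'   is about 1 percent of voxels).
#' @param texture_corr_mm correlation scale of the parenchymal texture in
#'   mm (default 2); 0 gives iid voxel noise. Correlated texture stands in
#'   for the vascular and septal structure of real parenchyma, which keeps
#'   mid-band energies anatomy-dominated the way real scans are.
#' @param n_clusters number of emphysema spheres (default 30).
#' @param cluster_radius radius range in mm (default c(2, 6)).
#' @param emphysema_hu attenuation inside clusters (default -985; must be
#'   below -950 while the parenchyma mean stays above it).
#' @param exterior_hu air outside the body (default -1000).
#' @param seed RNG seed; the phantom is bit-reproducible given the spec.
#' @return an object of class \code{phantom_spec}.
#' @export
phantom_spec <- function(shape = c(60, 84, 84), spacing = c(1, 1.5, 1.5),
                         body_hu = 40, parenchyma_mean = -860,
                         texture_sd = 40, texture_corr_mm = 2,
                         n_clusters = 30, cluster_radius = c(2, 6),
                         emphysema_hu = -985, exterior_hu = -1000,
                         seed = 1L) {
  stopifnot(length(shape) == 3L, all(shape >= c(2, 8, 8)),
            all(spacing > 0), texture_sd >= 0, texture_corr_mm >= 0,
            n_clusters >= 0,
            all(cluster_radius > 0), cluster_radius[1] <= cluster_radius[2],
            emphysema_hu < -950, parenchyma_mean > -950)
  structure(list(shape = as.integer(shape), spacing = as.numeric(spacing),
                 body_hu = body_hu, parenchyma_mean = parenchyma_mean,
                 texture_sd = texture_sd, texture_corr_mm = texture_corr_mm,
                 n_clusters = as.integer(n_clusters),
                 cluster_radius = as.numeric(cluster_radius),
                 emphysema_hu = emphysema_hu, exterior_hu = exterior_hu,
                 seed = as.integer(seed)),
            class = "phantom_spec")
}

#' Generate a digital chest phantom
#'
#' @param spec a [phantom_spec()].
#' @return a list: \code{volume} (clean [ct_volume]), \code{lung_mask}
#'   (ground-truth [lung_mask]), \code{emphysema_truth} (logical array),
#'   \code{true_es} (percent of lung voxels inside clusters),
#'   \code{clusters} (data frame of centres and radii in mm), \code{spec}.
#' @export
generate_phantom <- function(spec = phantom_spec()) {
  stopifnot(inherits(spec, "phantom_spec"))
  set.seed(spec$seed)
  d <- spec$shape; sp <- spec$spacing
  # physical coordinates centred on the grid
  z <- (seq_len(d[1]) - (d[1] + 1) / 2) * sp[1]
  y <- (seq_len(d[2]) - (d[2] + 1) / 2) * sp[2]
  x <- (seq_len(d[3]) - (d[3] + 1) / 2) * sp[3]
  ext <- d * sp
  # body: elliptic cylinder through all slices
  ry_b <- 0.42 * ext[2]; rx_b <- 0.46 * ext[3]
  Y <- array(rep(y, each = d[1]), d)
  X <- array(rep(x, each = d[1] * d[2]), d)
  Z <- array(z, d)
  body <- (Y / ry_b)^2 + (X / rx_b)^2 <= 1
  # two ellipsoidal lungs
  az <- 0.42 * ext[1]; ay <- 0.30 * ext[2]; ax <- 0.17 * ext[3]
  xoff <- 0.22 * ext[3]
  lungs <- ((Z / az)^2 + (Y / ay)^2 + ((X - xoff) / ax)^2 <= 1) |
    ((Z / az)^2 + (Y / ay)^2 + ((X + xoff) / ax)^2 <= 1)
  lungs <- lungs & body
  # emphysema spheres, uniform in the lungs, fully interior, no overlap
  clusters <- place_spheres(spec, c(az, ay, ax), xoff)
  emph <- array(FALSE, d)
  for (i in seq_len(nrow(clusters))) {
    cl <- clusters[i, ]
    emph <- emph | ((Z - cl$z)^2 + (Y - cl$y)^2 + (X - cl$x)^2 <= cl$r^2)
  }
  emph <- emph & lungs
  vox <- array(spec$exterior_hu, d)
  vox[body] <- spec$body_hu
  n_lung <- sum(lungs)
  vox[lungs] <- spec$parenchyma_mean
  if (spec$texture_sd > 0) {
    tex <- array(stats::rnorm(prod(d)), d)
    if (spec$texture_corr_mm > 0)
      tex <- gaussian_smooth(tex, sp, spec$texture_corr_mm)
    tl <- tex[lungs]
    tl <- (tl - mean(tl)) / stats::sd(tl) * spec$texture_sd
    vox[lungs] <- vox[lungs] + tl
  }
  vox[emph] <- spec$emphysema_hu
  list(volume = ct_volume(vox, sp),
       lung_mask = lung_mask(lungs, sp),
       emphysema_truth = emph,
       true_es = 100 * sum(emph) / n_lung,
       clusters = clusters, spec = spec)
}

# rejection-sample non-overlapping spheres interior to either lung ellipsoid
place_spheres <- function(spec, semi, xoff) {
  out <- data.frame(z = numeric(0), y = numeric(0), x = numeric(0),
                    r = numeric(0))
  if (spec$n_clusters == 0L) return(out)
  tries <- 0L
  while (nrow(out) < spec$n_clusters && tries < 200L * spec$n_clusters) {
    tries <- tries + 1L
    r <- stats::runif(1, spec$cluster_radius[1], spec$cluster_radius[2])
    side <- sample(c(-1, 1), 1)
    c_z <- stats::runif(1, -semi[1], semi[1])
    c_y <- stats::runif(1, -semi[2], semi[2])
    c_x <- side * xoff + stats::runif(1, -semi[3], semi[3])
    # interior with margin r: shrink the ellipsoid semi-axes by r
    s <- semi - r
    if (any(s <= 0)) next
    if ((c_z / s[1])^2 + (c_y / s[2])^2 + ((c_x - side * xoff) / s[3])^2 > 1)
      next
    if (nrow(out) > 0 &&
        any(sqrt((out$z - c_z)^2 + (out$y - c_y)^2 + (out$x - c_x)^2) <
              out$r + r)) next
    out[nrow(out) + 1L, ] <- c(c_z, c_y, c_x, r)
  }
  if (nrow(out) < spec$n_clusters)
    warning("placed only ", nrow(out), " of ", spec$n_clusters,
            " emphysema clusters")
  out
}
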