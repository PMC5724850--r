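# Separable Gaussian smoothing at physical (mm) scales on anisotropic grids.
#
# Each axis is filtered with a discrete Gaussian truncated at 3 sigma and
# renormalized, applied as a banded row-stochastic matrix with replicated
# (nearest) boundary handling, so a constant volume is reproduced exactly.

gauss_matrix_1d <- function(n, sigma_mm, spacing_mm) {
  if (sigma_mm <= 0) return(NULL)
  r <- max(1L, ceiling(3 * sigma_mm / spacing_mm))
  k <- (-r):r
  w <- exp(-(k * spacing_mm)^2 / (2 * sigma_mm^2))
  w <- w / sum(w)
  K <- matrix(0, n, n)
  i <- seq_len(n)
  for (j in seq_along(k)) {
    idx <- pmin(pmax(i + k[j], 1L), n)
    ij <- cbind(i, idx)
    K[ij] <- K[ij] + w[j]
  }
  K
}

apply_axis <- function(a, axis, K) {
  if (is.null(K)) return(a)
  d <- dim(a)
  perm <- c(axis, setdiff(1:3, axis))
  p <- aperm(a, perm)
  m <- K %*% matrix(p, d[axis])
  p <- array(m, d[perm])
  aperm(p, order(perm))
}

# Gaussian smoothing of a (z, y, x) array at one physical scale
gaussian_smooth <- function(a, spacing, sigma_mm) {
  if (sigma_mm <= 0) return(a)
  d <- dim(a)
  for (ax in 1:3)
    a <- apply_axis(a, ax, gauss_matrix_1d(d[ax], sigma_mm, spacing[ax]))
  a
}

# binary shift with zero fill, for morphology
shift_fill <- function(a, dz, dy, dx) {
  d <- dim(a)
  out <- array(FALSE, d)
  src <- function(n, s) {
    from <- max(1L, 1L - s); to <- min(n, n - s)
    if (from > to) integer(0) else from:to
  }
  iz <- src(d[1], dz); iy <- src(d[2], dy); ix <- src(d[3], dx)
  if (!length(iz) || !length(iy) || !length(ix)) return(out)
  out[iz + dz, iy + dy, ix + dx] <- a[iz, iy, ix]
  out
}

sphere_offsets <- function(radius_mm, spacing) {
  r <- floor(radius_mm / spacing)
  g <- expand.grid(dz = -r[1]:r[1], dy = -r[2]:r[2], dx = -r[3]:r[3])
  keep <- (g$dz * spacing[1])^2 + (g$dy * spacing[2])^2 +
    (g$dx * spacing[3])^2 <= radius_mm^2
  g[keep, , drop = FALSE]
}

dilate3 <- function(a, offsets) {
  out <- array(FALSE, dim(a))
  for (i in seq_len(nrow(offsets)))
    out <- out | shift_fill(a, offsets$dz[i], offsets$dy[i], offsets$dx[i])
  out
}

erode3 <- function(a, offsets) {
  out <- array(TRUE, dim(a))
  for (i in seq_len(nrow(offsets)))
    out <- out & shift_fill(a, offsets$dz[i], offsets$dy[i], offsets$dx[i])
  out
}

close3 <- function(a, radius_mm, spacing) {
  if (radius_mm <= 0) return(a)
  off <- sphere_offsets(radius_mm, spacing)
  if (nrow(off) <= 1L) return(a)
  erode3(dilate3(a, off), off)
}
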