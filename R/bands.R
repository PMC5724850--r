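#' Emphysema quantification configuration
#'
#' Collects the tunable parameters of the scoring pipeline: the density-mask
#' threshold, the bullae-filter minimum cluster area, the target slice
#' thickness, and the frequency-band schedule used for kernel normalization.
#' Bands live at physical Gaussian scales
#' \code{sigma_i = sigma0 * sigma_growth^(i-1)} mm.
#'
#' @param density_threshold HU threshold; voxels strictly below it count as
#'   emphysema (default -950).
#' @param min_cluster_area minimum in-plane cluster area in mm^2 kept by the
#'   bullae filter (default 5).
#' @param target_slice_thickness slice thickness in mm that scans are
#'   resampled to before normalization (default 3).
#' @param n_bands number of difference-of-Gaussian bands (default 6).
#' @param sigma0 finest band scale in mm (default 1).
#' @param sigma_growth scale ratio between consecutive bands (default 2).
#' @param scale_clamp band gains are clamped to
#'   \code{[1/scale_clamp, scale_clamp]} (default 4).
#' @return an object of class \code{quant_config}.
#' @export
quant_config <- function(density_threshold = -950, min_cluster_area = 5,
                         target_slice_thickness = 3, n_bands = 6,
                         sigma0 = 1, sigma_growth = 2, scale_clamp = 4) {
  stopifnot(density_threshold < 0, min_cluster_area >= 0,
            target_slice_thickness > 0, n_bands >= 2, sigma0 > 0,
            sigma_growth > 1, scale_clamp >= 1)
  structure(list(density_threshold = density_threshold,
                 min_cluster_area = min_cluster_area,
                 target_slice_thickness = target_slice_thickness,
                 n_bands = as.integer(n_bands), sigma0 = sigma0,
                 sigma_growth = sigma_growth, scale_clamp = scale_clamp),
            class = "quant_config")
}

band_sigmas <- function(config) {
  config$sigma0 * config$sigma_growth^(seq_len(config$n_bands) - 1)
}

#' Decompose a volume into frequency bands
#'
#' Splits the image \code{I} into a Laplacian-style stack of
#' difference-of-Gaussian bands at physical scales \code{sigma_1 < ... <
#' sigma_N} (filtering respects anisotropic spacing):
#' \code{b_1 = I - G_1(I)}, \code{b_i = G_(i-1)(I) - G_i(I)}, and a lowpass
#' residual \code{G_N(I)}. By telescoping, \code{lowpass + sum(bands)}
#' reconstructs the input exactly (to floating-point rounding).
#'
#' @param volume a [ct_volume].
#' @param config a [quant_config].
#' @return an object of class \code{band_decomposition} with elements
#'   \code{lowpass} (array), \code{bands} (list of arrays, finest first),
#'   \code{sigmas}, \code{spacing}.
#' @export
decompose_bands <- function(volume, config = quant_config()) {
  stopifnot(inherits(volume, "ct_volume"), inherits(config, "quant_config"))
  sig <- band_sigmas(config)
  ext <- dim(volume$voxels) * volume$spacing
  if (max(sig) > max(ext) / 2)
    warning(sprintf(paste0("coarsest band scale (%.3g mm) exceeds half the ",
                           "volume extent; its energy is unreliable"),
                    max(sig)))
  prev <- volume$voxels
  bands <- vector("list", config$n_bands)
  for (i in seq_along(sig)) {
    g <- gaussian_smooth(volume$voxels, volume$spacing, sig[i])
    bands[[i]] <- prev - g
    prev <- g
  }
  structure(list(lowpass = prev, bands = bands, sigmas = sig,
                 spacing = volume$spacing),
            class = "band_decomposition")
}

#' In-lung energy (standard deviation) per band
#'
#' The energy of a band is the population standard deviation of its values
#' over the lung-mask voxels.
#'
#' @param decomp a [decompose_bands()] result.
#' @param mask a [lung_mask] on the same grid.
#' @return numeric vector of per-band HU standard deviations.
#' @export
measure_band_energies <- function(decomp, mask) {
  stopifnot(inherits(decomp, "band_decomposition"), inherits(mask, "lung_mask"))
  if (!identical(dim(decomp$lowpass), dim(mask$voxels)))
    stop("mask shape does not match the decomposition")
  idx <- which(mask$voxels)
  if (length(idx) == 0L) stop("empty lung mask")
  vapply(decomp$bands, function(b) {
    v <- b[idx]
    sqrt(mean((v - mean(v))^2))
  }, 0)
}

#' Reference energy profile for kernel normalization
#'
#' The per-band target in-lung standard deviations that define the
#' appearance of the reference reconstruction kernel: the element-wise
#' median of the measured band energies across one or more scans
#' reconstructed with that kernel. Volumes are expected at the pipeline's
#' target slice thickness (see [resample_z()]), the stage at which
#' normalization measures energies.
#'
#' @param volumes list of [ct_volume] reference-kernel scans.
#' @param masks list of matching [lung_mask]s.
#' @param config a [quant_config].
#' @return an object of class \code{reference_profile} with \code{energies},
#'   \code{sigmas}, \code{n_bands}.
#' @export
compute_reference_profile <- function(volumes, masks, config = quant_config()) {
  if (length(volumes) == 0L) stop("need at least one reference scan")
  if (length(volumes) != length(masks))
    stop("'volumes' and 'masks' must have the same length")
  e <- mapply(function(v, m) {
    measure_band_energies(decompose_bands(v, config), m)
  }, volumes, masks)
  e <- matrix(e, nrow = config$n_bands)
  energies <- apply(e, 1, stats::median)
  reference_profile(energies, band_sigmas(config))
}

#' @rdname compute_reference_profile
#' @param energies per-band HU standard deviations (all positive).
#' @param sigmas band scales in mm.
#' @export
reference_profile <- function(energies, sigmas) {
  energies <- as.numeric(energies); sigmas <- as.numeric(sigmas)
  if (length(energies) != length(sigmas))
    stop("'energies' and 'sigmas' must have the same length")
  if (any(energies <= 0)) stop("reference energies must be strictly positive")
  structure(list(energies = energies, sigmas = sigmas,
                 n_bands = length(energies)),
            class = "reference_profile")
}

#' @export
print.reference_profile <- function(x, ...) {
  cat("reference_profile:", x$n_bands, "bands\n")
  print(data.frame(sigma_mm = x$sigmas, energy_hu = x$energies))
  invisible(x)
}

#' Save or load a reference profile (JSON)
#'
#' @param profile a [reference_profile].
#' @param path JSON file path.
#' @rdname profile_io
#' @export
write_profile <- function(profile, path) {
  stopifnot(inherits(profile, "reference_profile"))
  jsonlite::write_json(list(sigmas = profile$sigmas,
                            energies = profile$energies,
                            n_bands = profile$n_bands),
                       path, auto_unbox = TRUE, digits = NA)
}

#' @rdname profile_io
#' @export
read_profile <- function(path) {
  p <- jsonlite::read_json(path, simplifyVector = TRUE)
  reference_profile(p$energies, p$sigmas)
}

#' Normalize a scan toward a reference kernel
#'
#' Rescales every frequency band so that its in-lung energy matches the
#' reference profile: \code{I_hat = lowpass + sum_i s_i * b_i} with
#' \code{s_i = E_ref_i / E_i}, where \code{E_i} is measured over the lung
#' mask. Gains are clamped to \code{[1/scale_clamp, scale_clamp]}; a band
#' with zero measured energy keeps gain 1 (with a warning). Scaling is
#' applied to the whole band grid (energies are measured in-lung only) and
#' the output is clamped to the plausible HU range.
#'
#' @param volume a [ct_volume] (already at the target slice thickness).
#' @param mask a [lung_mask] on the same grid.
#' @param profile a [reference_profile] with matching band count.
#' @param config a [quant_config].
#' @return the normalized [ct_volume].
#' @export
apply_normalization <- function(volume, mask, profile,
                                config = quant_config()) {
  stopifnot(inherits(profile, "reference_profile"))
  check_aligned(volume, mask)
  if (profile$n_bands != config$n_bands)
    stop("profile has ", profile$n_bands, " bands but config expects ",
         config$n_bands)
  dec <- decompose_bands(volume, config)
  e <- measure_band_energies(dec, mask)
  s <- rep(1, config$n_bands)
  pos <- e > 1e-8         # an energy below 1e-8 HU is numerically zero
  s[pos] <- pmin(pmax(profile$energies[pos] / e[pos],
                      1 / config$scale_clamp), config$scale_clamp)
  if (any(!pos))
    warning("band(s) ", paste(which(!pos), collapse = ", "),
            " have zero in-lung energy; gain kept at 1")
  out <- dec$lowpass
  for (i in seq_len(config$n_bands)) out <- out + s[i] * dec$bands[[i]]
  out[out < HU_MIN] <- HU_MIN
  out[out > HU_MAX] <- HU_MAX
  v <- ct_volume(out, volume$spacing, volume$origin)
  attr(v, "band_gains") <- s
  v
}
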