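test_that("a constant volume decomposes to zero bands and itself as lowpass", {
  v <- ct_volume(array(-700, c(12, 24, 24)), c(1.5, 1.5, 1.5))
  dec <- decompose_bands(v, small_config())
  for (b in dec$bands) expect_lt(max(abs(b)), 1e-10)
  expect_equal(dec$lowpass, v$voxels, tolerance = 1e-12)
})

test_that("lowpass plus all bands reconstructs the input", {
  ph <- tiny_phantom(seed = 3)
  dec <- decompose_bands(ph$volume, small_config())
  rec <- dec$lowpass
  for (b in dec$bands) rec <- rec + b
  expect_lt(max(abs(rec - ph$volume$voxels)), 1e-4)
})

test_that("an impulse reproduces the explicit difference-of-Gaussians kernel", {
  d <- c(17, 25, 25)
  sp <- c(1.5, 1.5, 1.5)
  A <- 500
  a <- array(-800, d)
  ctr <- c(9, 13, 13)
  a[ctr[1], ctr[2], ctr[3]] <- -800 + A
  cfg <- small_config()
  dec <- decompose_bands(ct_volume(a, sp), cfg)
  # oracle: build each Gaussian kernel directly (truncation at 3 sigma,
  # normalized) and take outer products; away from boundaries the clamped
  # filter equals plain convolution, and the impulse response is the kernel
  kern1 <- function(sigma, h) {
    r <- max(1, ceiling(3 * sigma / h))
    w <- exp(-(((-r):r) * h)^2 / (2 * sigma^2))
    w / sum(w)
  }
  kern3_at <- function(sigma) {
    kz <- kern1(sigma, sp[1]); ky <- kern1(sigma, sp[2]); kx <- kern1(sigma, sp[3])
    out <- array(0, d)
    rz <- (length(kz) - 1) / 2; ry <- (length(ky) - 1) / 2; rx <- (length(kx) - 1) / 2
    for (iz in -rz:rz) for (iy in -ry:ry) for (ix in -rx:rx)
      out[ctr[1] + iz, ctr[2] + iy, ctr[3] + ix] <-
        kz[iz + rz + 1] * ky[iy + ry + 1] * kx[ix + rx + 1]
    out
  }
  sig <- cfg$sigma0 * cfg$sigma_growth^(0:(cfg$n_bands - 1))
  prev <- array(0, d); prev[ctr[1], ctr[2], ctr[3]] <- 1   # delta
  for (i in 1:2) {      # finest two bands fit well inside the grid
    g <- kern3_at(sig[i])
    expect_lt(max(abs(dec$bands[[i]] - A * (prev - g))), 1e-6 * A)
    prev <- g
  }
})

test_that("band energies are in-mask population standard deviations", {
  d <- c(8, 40, 40)
  msk <- lung_mask(array(TRUE, d), c(1, 1, 1))
  set.seed(5)
  noise <- array(rnorm(prod(d), 0, 25), d)
  dec <- structure(list(lowpass = array(0, d),
                        bands = list(noise, array(3, d)),
                        sigmas = c(1, 2), spacing = c(1, 1, 1)),
                   class = "band_decomposition")
  e <- measure_band_energies(dec, msk)
  expect_equal(e[1], 25, tolerance = 1 / 25)   # 25 +/- 1
  expect_equal(e[2], 0)                        # constant band
  expect_error(measure_band_energies(dec, lung_mask(array(FALSE, d), c(1, 1, 1))),
               "empty")
})

test_that("band energies are invariant to adding a constant to the volume", {
  ph <- tiny_phantom(seed = 9)
  cfg <- small_config()
  e1 <- measure_band_energies(decompose_bands(ph$volume, cfg), ph$lung_mask)
  shifted <- ct_volume(ph$volume$voxels + 100, ph$volume$spacing)
  e2 <- measure_band_energies(decompose_bands(shifted, cfg), ph$lung_mask)
  expect_equal(e1, e2, tolerance = 1e-10)
})

test_that("normalizing against the scan's own profile is a no-op", {
  ph <- tiny_phantom(seed = 13)
  cfg <- small_config()
  e <- measure_band_energies(decompose_bands(ph$volume, cfg), ph$lung_mask)
  prof <- reference_profile(e, cfg$sigma0 * cfg$sigma_growth^(0:3))
  out <- apply_normalization(ph$volume, ph$lung_mask, prof, cfg)
  expect_lt(max(abs(out$voxels - ph$volume$voxels)), 1e-4)
  es0 <- emphysema_score(ph$volume, ph$lung_mask, cfg)$score
  es1 <- emphysema_score(out, ph$lung_mask, cfg)$score
  expect_lt(abs(es1 - es0), 0.1)
})

test_that("doubling the reference energies doubles every band contribution", {
  ph <- tiny_phantom(seed = 17)
  cfg <- small_config(scale_clamp = 16)   # keep gains away from the clamp
  dec <- decompose_bands(ph$volume, cfg)
  e <- measure_band_energies(dec, ph$lung_mask)
  sig <- dec$sigmas
  o1 <- apply_normalization(ph$volume, ph$lung_mask,
                            reference_profile(e, sig), cfg)
  o2 <- apply_normalization(ph$volume, ph$lung_mask,
                            reference_profile(2 * e, sig), cfg)
  hp1 <- o1$voxels - dec$lowpass
  hp2 <- o2$voxels - dec$lowpass
  interior <- o2$voxels > -1099.9 & o2$voxels < 3199.9  # away from the HU clamp
  expect_equal(hp2[interior], 2 * hp1[interior], tolerance = 1e-8)
})

test_that("gains clamp and zero-energy bands fall back to unity with warning", {
  v <- ct_volume(array(-700, c(12, 24, 24)), c(1.5, 1.5, 1.5))
  msk <- lung_mask(array(TRUE, c(12, 24, 24)), c(1.5, 1.5, 1.5))
  cfg <- small_config()
  prof <- reference_profile(rep(10, 4), cfg$sigma0 * cfg$sigma_growth^(0:3))
  expect_warning(out <- apply_normalization(v, msk, prof, cfg),
                 "zero in-lung energy")
  expect_equal(out$voxels, v$voxels, tolerance = 1e-10)

  ph <- tiny_phantom(seed = 21)
  e <- measure_band_energies(decompose_bands(ph$volume, cfg), ph$lung_mask)
  big <- reference_profile(1000 * e, cfg$sigma0 * cfg$sigma_growth^(0:3))
  outb <- apply_normalization(ph$volume, ph$lung_mask, big, cfg)
  g <- attr(outb, "band_gains")
  expect_true(all(g <= cfg$scale_clamp + 1e-12))
})

test_that("profile construction takes per-band medians across scans", {
  cfg <- small_config()
  phs <- lapply(1:3, function(i) tiny_phantom(seed = 30 + i))
  prof <- compute_reference_profile(lapply(phs, `[[`, "volume"),
                                    lapply(phs, `[[`, "lung_mask"), cfg)
  em <- sapply(phs, function(p)
    measure_band_energies(decompose_bands(p$volume, cfg), p$lung_mask))
  expect_equal(prof$energies, apply(em, 1, function(r) sort(r)[2]))
  one <- compute_reference_profile(list(phs[[1]]$volume),
                                   list(phs[[1]]$lung_mask), cfg)
  expect_equal(one$energies, em[, 1])
  expect_error(compute_reference_profile(list(), list(), cfg), "at least one")
})

test_that("profiles survive a JSON round trip and mismatches are caught", {
  prof <- reference_profile(c(12.5, 8.25, 4.125), c(1, 2, 4))
  f <- tempfile(fileext = ".json")
  write_profile(prof, f)
  r <- read_profile(f)
  expect_equal(r$energies, prof$energies)
  expect_equal(r$sigmas, prof$sigmas)
  ph <- tiny_phantom(seed = 2)
  expect_error(apply_normalization(ph$volume, ph$lung_mask, r, small_config()),
               "bands")
})

test_that("an oversized coarse scale triggers a warning, not an error", {
  v <- ct_volume(array(rnorm(10 * 12 * 12, -800, 30), c(10, 12, 12)),
                 c(1, 1, 1))
  expect_warning(decompose_bands(v, quant_config(n_bands = 6)),
                 "unreliable")
})
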