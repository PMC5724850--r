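test_that("ct_volume enforces geometry and value invariants", {
  a <- array(-800, c(4, 8, 8))
  v <- ct_volume(a, c(3, 0.7, 0.7), c(1, 2, 3))
  expect_s3_class(v, "ct_volume")
  expect_error(ct_volume(array(0, c(1, 8, 8)), c(1, 1, 1)), "at least 2 slices")
  expect_error(ct_volume(array(0, c(4, 4, 8)), c(1, 1, 1)), "at least 2 slices")
  expect_error(ct_volume(a, c(0, 1, 1)), "strictly positive")
  b <- a; b[1, 1, 1] <- NA
  expect_error(ct_volume(b, c(1, 1, 1)), "finite")
})

test_that("HU values outside the plausible range are clamped with a count", {
  a <- array(-800, c(2, 8, 8))
  a[1, 1, 1] <- -3000; a[2, 2, 2] <- 9000; a[2, 3, 3] <- 4000
  f <- tempfile(fileext = ".mha")
  write_metaimage <- normES:::write_metaimage
  write_metaimage(a, c(1, 1, 1), c(0, 0, 0), f)
  expect_message(v <- read_volume(f), "clamped 3 voxel")
  expect_equal(range(v$voxels), c(-1100, 3200))
  # the density-mask threshold is interior to the clamp range
  expect_equal(sum(v$voxels < -950), 1)
})

test_that("MetaImage round trip is lossless for float32 payloads", {
  set.seed(1)
  a <- array(as.numeric(sample(-1000:2000, 5 * 9 * 11, TRUE)), c(5, 9, 11))
  v <- ct_volume(a, c(2.5, 0.664, 0.664), c(-10, 5.25, 7.5))
  for (ext in c(".mha", ".mhd")) {
    f <- tempfile(fileext = ext)
    write_volume(v, f)
    r <- read_volume(f)
    expect_identical(r$voxels, a, label = ext)
    expect_identical(r$spacing, v$spacing)
    expect_identical(r$origin, v$origin)
  }
})

test_that("NIfTI round trip preserves voxels, spacing and origin", {
  a <- array(as.numeric(sample(-1024:500, 4 * 8 * 10, TRUE)), c(4, 8, 10))
  v <- ct_volume(a, c(3, 0.7, 0.8), c(4, -3, 12))
  for (ext in c(".nii", ".nii.gz")) {
    f <- tempfile(fileext = ext)
    write_volume(v, f)
    r <- read_volume(f)
    expect_equal(r$voxels, a, tolerance = 0, label = ext)
    expect_equal(r$spacing, v$spacing, tolerance = 1e-6)
    expect_equal(r$origin, v$origin, tolerance = 1e-4)
  }
})

test_that("axis convention maps index (k,j,i) to physical z,y,x", {
  a <- array(0, c(3, 8, 9))
  a[2, 5, 7] <- 111
  v <- ct_volume(a, c(2, 1.5, 1.25), c(10, 0, -5))
  f <- tempfile(fileext = ".mha")
  write_volume(v, f)
  r <- read_volume(f)
  expect_equal(which(r$voxels == 111, arr.ind = TRUE)[1, ],
               c(dim1 = 2, dim2 = 5, dim3 = 7))
  # physical position of that voxel: origin + (index - 1) * spacing
  expect_equal(r$origin + (c(2, 5, 7) - 1) * r$spacing, c(12, 6, 2.5))
})

test_that("DICOM series reads with rescale, slice sorting and spacing", {
  dir <- file.path(tempdir(), "dcm_ok")
  # slices written out of z order; stored 24 with intercept -1024 -> -1000
  write_test_dicom_series(dir, values = c(100, 24, 500), z = c(2.5, 0, 5))
  v <- read_volume(dir)
  expect_equal(dim(v$voxels), c(3, 8, 8))
  expect_equal(v$voxels[1, 1, 1], -1000)       # stored 24, slope 1, icpt -1024
  expect_equal(v$voxels[2, 1, 1], -924)
  expect_equal(v$spacing, c(2.5, 0.7, 0.7))
  expect_equal(v$origin, c(0, 2, 1))
  unlink(dir, recursive = TRUE)
})

test_that("DICOM errors name the problem: mixed series, missing spacing", {
  dir <- file.path(tempdir(), "dcm_mixed")
  write_test_dicom_series(dir, values = c(0, 0), z = c(0, 1), series = "1.1")
  write_test_dicom_slice(file.path(dir, "other.dcm"), matrix(0, 8, 8),
                         ipp = c(0, 0, 9), series = "2.2")
  expect_error(read_volume(dir), "more than one DICOM series")
  unlink(dir, recursive = TRUE)

  dir2 <- file.path(tempdir(), "dcm_nospacing")
  write_test_dicom_series(dir2, values = c(0, 0), z = c(0, 1),
                          omit_pixel_spacing = TRUE)
  expect_error(read_volume(dir2), "PixelSpacing")
  unlink(dir2, recursive = TRUE)

  expect_error(read_volume(tempfile(fileext = ".xyz")), "not found")
  f <- tempfile(fileext = ".txt")
  writeLines("hello", f)
  expect_error(read_volume(f), "unsupported volume format")
})

test_that("masks binarize on read and an empty mask is flagged", {
  m <- array(0, c(3, 8, 8))
  m[2, 3:5, 3:5] <- 255
  msk <- lung_mask(m, c(2, 1, 1))
  f <- tempfile(fileext = ".mha")
  write_mask(msk, f)
  r <- read_mask(f)
  expect_type(r$voxels, "logical")
  expect_identical(r$voxels, m > 0)

  z <- lung_mask(array(0, c(2, 8, 8)), c(1, 1, 1))
  fz <- tempfile(fileext = ".mha")
  write_mask(z, fz)
  expect_message(rz <- read_mask(fz), "empty")
  expect_false(any(rz$voxels))
})

test_that("phantom volumes survive the volume_io round trip", {
  ph <- tiny_phantom(seed = 7, n_clusters = 4)
  f <- tempfile(fileext = ".mha")
  fm <- tempfile(fileext = ".mha")
  # float32 write: round to 1/64 HU so the payload is exactly representable
  vq <- ct_volume(round(ph$volume$voxels * 64) / 64, ph$volume$spacing)
  write_volume(vq, f)
  write_mask(ph$lung_mask, fm)
  r <- read_volume(f, clamp_hu = FALSE)
  expect_identical(r$voxels, vq$voxels)
  expect_identical(r$spacing, ph$spec$spacing)
  rm <- read_mask(fm)
  expect_identical(rm$voxels, ph$lung_mask$voxels)
})
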