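lung_box <- function(fill_hu, d = c(6, 16, 16), sp = c(3, 1.5, 1.5)) {
  v <- ct_volume(array(fill_hu, d), sp)
  m <- lung_mask(array(TRUE, d), sp)
  list(v = v, m = m)
}

test_that("the density mask score is an exact voxel percentage", {
  allair <- lung_box(-1000)
  expect_equal(emphysema_score(allair$v, allair$m)$score, 100)
  tissue <- lung_box(-850)
  expect_equal(emphysema_score(tissue$v, tissue$m)$score, 0)
  # 123 of 1000 voxels below threshold in one big cluster -> 12.3 exactly
  a <- array(-850, c(10, 10, 10))
  a[1, , ] <- -980                        # 100 voxels
  a[2, 1:2, 1:10] <- -980                 # +20
  a[3, 1, 1:3] <- -980                    # +3
  v <- ct_volume(a, c(3, 1.5, 1.5))
  m <- lung_mask(array(TRUE, dim(a)), v$spacing)
  res <- emphysema_score(v, m)
  expect_equal(res$score, 12.3)
  expect_equal(res$n_emphysema_voxels, 123L)
  expect_equal(res$score * res$n_lung_voxels / 100, res$n_emphysema_voxels)
})

test_that("the threshold is strict: exactly -950 HU does not count", {
  at <- lung_box(-950)
  expect_equal(emphysema_score(at$v, at$m)$score, 0)
  below <- lung_box(-950.0001)
  expect_equal(emphysema_score(below$v, below$m)$score, 100)
})

test_that("empty masks and misaligned inputs are rejected", {
  b <- lung_box(-850)
  empty <- lung_mask(array(FALSE, c(6, 16, 16)), b$v$spacing)
  expect_error(emphysema_score(b$v, empty), "empty")
  wrong <- lung_mask(array(TRUE, c(5, 16, 16)), b$v$spacing)
  expect_error(emphysema_score(b$v, wrong), "shape")
})

test_that("origES delegates to the unfiltered density mask", {
  ph <- tiny_phantom(seed = 41)
  r <- compute_orig_es(ph$volume, ph$lung_mask)
  expect_equal(r$mode, "orig")
  direct <- 100 * sum(ph$lung_mask$voxels &
                        ph$volume$voxels < -950) / sum(ph$lung_mask$voxels)
  expect_equal(r$score, direct)
  expect_true(is.na(r$n_clusters_kept))
})

test_that("the bullae filter inside scoring counts kept and removed clusters", {
  a <- array(-850, c(2, 20, 20))
  a[1, 2, 2] <- -980                      # isolated: 2.25 mm2, removed
  a[1, 10:13, 10:13] <- -980              # 16 px = 36 mm2, kept
  v <- ct_volume(a, c(3, 1.5, 1.5))
  m <- lung_mask(array(TRUE, dim(a)), v$spacing)
  r <- emphysema_score(v, m, bullae_filter = TRUE)
  expect_equal(r$n_emphysema_voxels, 16L)
  expect_equal(r$n_clusters_kept, 1L)
  expect_equal(r$n_clusters_removed, 1L)
  expect_equal(r$score, 100 * 16 / (2 * 400))
})

test_that("normES equals origES when every pipeline stage is the identity", {
  # already at 3 mm, no sub-threshold small clusters, self profile
  ph <- generate_phantom(phantom_spec(shape = c(12, 48, 48),
                                      spacing = c(3, 1.5, 1.5),
                                      texture_sd = 0, n_clusters = 5,
                                      cluster_radius = c(3, 5), seed = 51))
  cfg <- small_config()
  prof <- compute_reference_profile(list(ph$volume), list(ph$lung_mask), cfg)
  orig <- compute_orig_es(ph$volume, ph$lung_mask, cfg)
  norm <- compute_norm_es(ph$volume, ph$lung_mask, prof, cfg)
  expect_equal(norm$mode, "norm")
  expect_lt(abs(norm$score - orig$score), 0.1)
})

test_that("scattered single-voxel noise scores zero after the bullae rule", {
  a <- array(-860, c(4, 24, 24))
  idx <- expand.grid(z = 1:4, y = seq(2, 22, by = 4), x = seq(2, 22, by = 4))
  a[as.matrix(idx)] <- -980               # isolated voxels only
  v <- ct_volume(a, c(3, 1.5, 1.5))
  m <- lung_mask(array(TRUE, dim(a)), v$spacing)
  cfg <- small_config()
  prof <- compute_reference_profile(list(v), list(m), cfg)
  expect_gt(compute_orig_es(v, m, cfg)$score, 0)
  expect_equal(compute_norm_es(v, m, prof, cfg)$score, 0)
})

test_that("raising min_cluster_area never raises normES", {
  ph <- tiny_phantom(seed = 61, n_clusters = 10)
  prev <- Inf
  for (area in c(0, 5, 15)) {
    cfg <- small_config(min_cluster_area = area)
    prof <- compute_reference_profile(list(ph$volume), list(ph$lung_mask), cfg)
    s <- compute_norm_es(ph$volume, ph$lung_mask, prof, cfg)$score
    expect_lte(s, prev + 1e-12)
    prev <- s
  }
  # area 0 makes the filtered score equal the unfiltered one
  cfg0 <- small_config(min_cluster_area = 0)
  r0 <- emphysema_score(ph$volume, ph$lung_mask, cfg0, bullae_filter = TRUE)
  r1 <- emphysema_score(ph$volume, ph$lung_mask, cfg0, bullae_filter = FALSE)
  expect_equal(r0$score, r1$score)
})
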