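test_that("empty and degenerate specs behave", {
  spec <- synth_spec(3, 0, 16, n_stains = 2)
  ps <- generate_patch_dataset(spec)
  expect_s3_class(ps, "stain_patchset")
  expect_length(ps, 0)
  expect_length(ps$labels, 0)
  expect_error(synth_spec(3, 10, 4), "patch_size")
  expect_error(synth_spec(3, 10, 16, n_stains = 0), "n_stains")
  expect_error(synth_spec(0, 10, 16), "n_classes")
  expect_error(synth_spec(3, 10, 16, separation = -1), "non-negative")
})

test_that("generation is deterministic and conserves channel count", {
  spec <- synth_spec(3, 12, 16, n_stains = 2, seed = 42)
  a <- generate_patch_dataset(spec)
  b <- generate_patch_dataset(spec)
  expect_identical(a$data, b$data)
  expect_identical(a$labels, b$labels)
  expect_equal(dim(a$data)[3], 6)
  for (ns in c(1, 4, 7)) {
    ps <- generate_patch_dataset(synth_spec(2, 2, 8, n_stains = ns))
    expect_equal(dim(ps$data)[3], 3 * ns)
  }
  expect_true(all(a$data >= 0 & a$data <= 1))
})

test_that("labels are near-uniform over classes", {
  ps <- quick_patchset(n = 100, k = 4)
  counts <- tabulate(ps$labels + 1, 4)
  expect_true(max(counts) - min(counts) <= 1)
})

test_that("separated classes are recoverable by a nearest-centroid oracle", {
  ps <- quick_patchset(n = 200, side = 16, k = 4, n_stains = 5,
                       separation = 1, noise_sd = 0.05, seed = 3)
  f <- patch_channel_means(ps)
  cent <- t(sapply(0:3, function(k) colMeans(f[ps$labels == k, , drop = FALSE])))
  # per-class mean channel vectors are pairwise distinct
  dc <- as.matrix(dist(cent))
  expect_true(min(dc[upper.tri(dc)]) > 0.1)
  pred <- apply(f, 1, function(r) which.min(colSums((t(cent) - r)^2)) - 1)
  expect_gt(mean(pred == ps$labels), 0.95)
})

test_that("silhouette on pixel-mean features is non-decreasing in separation", {
  skip_if_not_installed("cluster")
  sil <- sapply(c(0.2, 0.6, 1.2), function(sep) {
    ps <- quick_patchset(n = 90, side = 16, k = 3, separation = sep,
                         noise_sd = 0.05, seed = 9)
    f <- patch_channel_means(ps)
    mean(cluster::silhouette(ps$labels + 1, dist(f))[, "sil_width"])
  })
  expect_true(all(diff(sil) > 0))
})

test_that("classes are statistically indistinguishable at zero separation", {
  ps <- quick_patchset(n = 120, side = 16, k = 3, separation = 0, seed = 5)
  f <- patch_channel_means(ps)
  # class means should coincide up to noise: between-class F-ratio near 1
  fr <- summary(stats::aov(rowMeans(f) ~ factor(ps$labels)))[[1]]$`F value`[1]
  expect_lt(fr, 5)
})

test_that("synthetic WSI geometry, round trip and determinism hold", {
  spec <- synth_spec(3, 0, 16, n_stains = 2, seed = 2)
  cmap <- matrix(c(0L, 1L, 2L, 0L), 2, 2)
  wspec <- synth_wsi_spec(128, 128, 64, class_map = cmap)
  wsi <- generate_synthetic_wsi(wspec, spec)
  expect_equal(dim(wsi$image), c(128, 128, 6))
  expect_identical(wsi$class_map, cmap)
  # re-cutting recovers tiles pixel-identically and twice gives the same
  tiles1 <- cut_tiles(wsi$image, 64)
  tiles2 <- cut_tiles(generate_synthetic_wsi(wspec, spec)$image, 64)
  expect_identical(tiles1$data, tiles2$data)
  expect_error(synth_wsi_spec(50, 50, 64), "tile_size")
  expect_error(synth_wsi_spec(128, 128, 64, class_map = matrix(0L, 3, 3)),
               "class_map")
})

test_that("single-class WSI tiles vary no more than resampled patches", {
  spec <- synth_spec(2, 0, 16, n_stains = 2, seed = 8)
  wspec <- synth_wsi_spec(96, 96, 32, class_map = matrix(0L, 3, 3))
  wsi <- generate_synthetic_wsi(wspec, spec)
  tiles <- cut_tiles(wsi$image, 32)
  v_wsi <- var(apply(tiles$data, 4, mean))
  # resampling oracle: patches of the same class under the same spec give
  # the noise-only variance of per-tile means; the WSI tiles (9 of them)
  # must stay within an F-bound of that reference
  ps <- generate_patch_dataset(synth_spec(2, 120, 32, n_stains = 2, seed = 8))
  v_ref <- var(apply(ps$data[, , , ps$labels == 0L, drop = FALSE], 4, mean))
  expect_lt(v_wsi, v_ref * stats::qf(0.999, 8, sum(ps$labels == 0L) - 1))
})
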