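test_that("voxelwise r and t maps follow the closed-form relationship", {
  coh <- simulate_cohort(tiny_spec(n = 100, seed = 21))
  v <- coh$latents$values[, 1]
  lm0 <- voxel_loadings(coh$dataset, v)
  for (nm in names(lm0$maps)) {
    m <- lm0$maps[[nm]]
    ok <- !is.na(m$r) & abs(m$r) < 1
    expect_true(all(abs(m$r[ok]) <= 1))
    expect_equal(m$t[ok], m$r[ok] * sqrt((100 - 2) / (1 - m$r[ok]^2)),
                 tolerance = 1e-12)
  }
  expect_error(voxel_loadings(coh$dataset, rep(1, 100)), "constant")
})

test_that("degenerate voxels: perfect copies give r = 1 / infinite t, noise stays small", {
  n <- 200
  v <- with_seed(22, rnorm(n))
  blk <- with_seed(23, cbind(v, -v, matrix(rnorm(n * 40), n, 40)))
  ds <- multimodal_dataset(list(m = list(data = blk, grid_dims = c(42, 1, 1),
                                         voxel_size_mm = c(1, 1, 1),
                                         mask_idx = 1:42, kind = "volume")))
  lm0 <- voxel_loadings(ds, v)
  expect_equal(lm0$maps$m$r[1], 1, tolerance = 1e-12)
  expect_true(is.infinite(lm0$maps$m$t[1]) && lm0$maps$m$t[1] > 0)
  expect_true(is.infinite(lm0$maps$m$t[2]) && lm0$maps$m$t[2] < 0)
  expect_lt(max(abs(lm0$maps$m$r[-(1:2)])), 0.25)
  # exactly orthogonalized voxel has t = 0
  o <- resid(lm(blk[, 3] ~ v))
  ds2 <- multimodal_dataset(list(m = list(data = cbind(blk[, 1], o),
                                          grid_dims = c(2, 1, 1),
                                          voxel_size_mm = c(1, 1, 1),
                                          mask_idx = 1:2, kind = "volume")))
  lm2 <- voxel_loadings(ds2, v)
  expect_equal(lm2$maps$m$t[2], 0, tolerance = 1e-10)
})

test_that("max-statistic correction dominates uncorrected p and respects symmetry", {
  coh <- simulate_cohort(tiny_spec(n = 80, seed = 24))
  v <- coh$latents$values[, 1]
  lm0 <- voxel_loadings(coh$dataset, v)
  lm1 <- fwe_correct(lm0, coh$dataset, P = 199, seed = 1)
  for (nm in names(lm1$maps)) {
    m <- lm1$maps[[nm]]
    # uncorrected parametric p at each voxel is never larger than p_fwe
    punc <- 2 * pt(abs(m$t), df = 78, lower.tail = FALSE)
    ok <- is.finite(m$t)
    expect_true(all(m$p_fwe[ok] >= punc[ok] - 0.02))
    expect_true(all(m$p_fwe[ok] >= 1 / 200))
  }
  # identical voxels receive identical corrected p
  n <- 60
  v2 <- with_seed(25, rnorm(n))
  same <- with_seed(26, 0.4 * v2 + rnorm(n, sd = 1))
  ds <- multimodal_dataset(list(m = list(data = cbind(same, same, same),
                                         grid_dims = c(3, 1, 1),
                                         voxel_size_mm = c(1, 1, 1),
                                         mask_idx = 1:3, kind = "volume")))
  lm2 <- fwe_correct(voxel_loadings(ds, v2), ds, P = 199, seed = 2)
  expect_equal(lm2$maps$m$p_fwe[1], lm2$maps$m$p_fwe[2])
  expect_equal(lm2$maps$m$p_fwe[1], lm2$maps$m$p_fwe[3])
})

test_that("enlarging the voxel family never shrinks corrected p-values", {
  n <- 80
  v <- with_seed(27, rnorm(n))
  blk_small <- with_seed(28, cbind(0.5 * v + rnorm(n), matrix(rnorm(n * 20), n, 20)))
  blk_big <- cbind(blk_small, with_seed(29, matrix(rnorm(n * 200), n, 200)))
  mk <- function(b) multimodal_dataset(list(m = list(
    data = b, grid_dims = c(ncol(b), 1, 1), voxel_size_mm = c(1, 1, 1),
    mask_idx = seq_len(ncol(b)), kind = "volume")))
  ds1 <- mk(blk_small); ds2 <- mk(blk_big)
  p1 <- fwe_correct(voxel_loadings(ds1, v), ds1, P = 199, seed = 3)$maps$m$p_fwe
  p2 <- fwe_correct(voxel_loadings(ds2, v), ds2, P = 199, seed = 3)$maps$m$p_fwe
  expect_true(all(p2[seq_along(p1)] >= p1 - 1e-12))
})

test_that("thresholding separates positive and negative associations", {
  coh <- simulate_cohort(tiny_spec(n = 150, seed = 30, noise_sd = 0.3))
  v <- coh$latents$values[, 1]
  lm1 <- fwe_correct(voxel_loadings(coh$dataset, v), coh$dataset,
                     P = 199, seed = 4)
  th <- threshold_maps(lm1, alpha = 1)
  expect_true(all(sapply(th$maps, function(m) all(m$sig_mask))))
  th0 <- threshold_maps(lm1, alpha = 1 / 1000)   # below the attainable floor
  expect_true(all(sapply(th0$maps, function(m) !any(m$sig_mask))))
  th2 <- threshold_maps(lm1, alpha = 0.01)
  for (m in th2$maps) {
    expect_true(all(m$sign_map[m$sig_mask] %in% c(-1, 1)))
    expect_true(all(m$sign_map[!m$sig_mask] == 0))
    expect_true(all(sign(m$r[m$sig_mask]) == m$sign_map[m$sig_mask]))
  }
  # a planted blob is largely detected
  sup <- attr(coh$maps[["modA"]], "supports")[[1]]
  expect_gt(mean(th2$maps[["modA"]]$sig_mask[sup]), 0.8)
})

test_that("small P triggers the attainability warning", {
  coh <- simulate_cohort(tiny_spec(n = 60, seed = 31))
  lm0 <- voxel_loadings(coh$dataset, coh$latents$values[, 1])
  expect_warning(fwe_correct(lm0, coh$dataset, P = 100, seed = 1,
                             alpha = 0.001), "no voxel can pass")
})
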