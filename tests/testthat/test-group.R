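# Group inference: t maps, cluster-extent thresholding, cognitive load,
# overlap, subsample stability and the extent permutation test.

test_that("one-sample t maps match the textbook formula and edge cases", {
  g <- c(5L, 5L, 5L)
  # all-zero maps: t = 0, p = 0.5 (zero SD sentinel path reports mean 0)
  zs <- replicate(6, array(0, g), simplify = FALSE)
  suppressMessages(gm <- one_sample_t_map(zs, cluster_min = 0L))
  expect_true(all(gm$t == 0))
  expect_true(all(gm$p == 0.5))
  # known draws vs direct formula
  set.seed(12)
  zs <- replicate(20, array(rnorm(prod(g)), g), simplify = FALSE)
  gm <- one_sample_t_map(zs, cluster_min = 0L)
  Z <- sapply(zs, as.vector)
  t_oracle <- apply(Z, 1, function(v) mean(v) / (sd(v) / sqrt(length(v))))
  expect_equal(as.vector(gm$t), t_oracle, tolerance = 1e-12)
  expect_equal(as.vector(gm$p),
               pt(t_oracle, 19, lower.tail = FALSE), tolerance = 1e-12)
  # a NaN subject decrements n at that voxel
  zs[[1]][1, 1, 1] <- NaN
  gm2 <- one_sample_t_map(zs, cluster_min = 0L)
  expect_equal(gm2$n[1, 1, 1], 19L)
  expect_equal(gm2$n[2, 1, 1], 20L)
  # zero-SD positive mean: +Inf sentinel with p = 0
  zs <- replicate(5, array(0.3, g), simplify = FALSE)
  suppressMessages(gm3 <- one_sample_t_map(zs, cluster_min = 0L))
  expect_true(all(gm3$t == Inf))
  expect_true(all(gm3$p == 0))
})

test_that("cluster-extent thresholding retains only large components", {
  g <- c(12L, 12L, 12L)
  p <- array(1, g)
  p[2, 2, 2] <- 0.001                 # isolated voxel
  p[5:7, 5:6, 5:6] <- 0.001           # 12-voxel face-connected blob
  keep <- threshold_clusters(p, 0.05, cluster_min = 10L)
  expect_false(keep[2, 2, 2])
  expect_true(all(keep[5:7, 5:6, 5:6]))
  expect_equal(sum(keep), 12L)
  # strict inequality: a 10-voxel blob does not survive ">10"
  p2 <- array(1, g)
  p2[1:10, 1, 1] <- 0.001
  expect_equal(sum(threshold_clusters(p2, 0.05, 10L)), 0L)
  p2[1:11, 1, 1] <- 0.001
  expect_equal(sum(threshold_clusters(p2, 0.05, 10L)), 11L)
  # cluster_min = 0 equals the voxel threshold
  expect_identical(threshold_clusters(p, 0.05, 0L),
                   !is.na(p) & p < 0.05)
})

test_that("component labeling agrees with a flood-fill oracle", {
  set.seed(33)
  for (i in 1:10) {
    mask <- array(runif(15^3) < 0.25, c(15L, 15L, 15L))
    for (conn in c(6L, 18L, 26L)) {
      expect_true(same_partition(label_clusters(mask, conn),
                                 flood_fill_labels(mask, conn)))
    }
  }
})

test_that("significance masks are nested under shrinking alpha", {
  set.seed(41)
  zs <- replicate(8, array(rnorm(10^3, 0.3), c(10L, 10L, 10L)),
                  simplify = FALSE)
  alphas <- c(0.2, 0.05, 0.01)
  masks <- lapply(alphas, function(a) {
    one_sample_t_map(zs, alpha = a, cluster_min = 2L)$sig
  })
  expect_true(all(masks[[2]] <= masks[[1]]))
  expect_true(all(masks[[3]] <= masks[[2]]))
})

test_that("cognitive load sums z over the significance mask", {
  z <- array(0, c(4L, 4L, 4L))
  sig <- array(FALSE, c(4L, 4L, 4L))
  expect_equal(cognitive_load(z, sig), list(load = 0, n_sig_voxels = 0L))
  z[1:5] <- 0.2
  sig[1:5] <- TRUE
  expect_equal(cognitive_load(z, sig), list(load = 1, n_sig_voxels = 5L))
  z[2] <- NaN
  expect_error(cognitive_load(z, sig), "non-finite")
})

test_that("loads grow with the planted effect size", {
  # group-level load across effect sizes 0.3 / 0.6 / 0.9
  loads <- vapply(c(0.3, 0.6, 0.9), function(r) {
    cfg <- sim_config(n_subjects = 3L, n_trials_per_condition = 15L,
                      grid_shape = c(11L, 11L, 11L), n_regions = 1L,
                      n_background = 64L,
                      effect_map = data.frame(region = 1L,
                                              condition = "chinese_word",
                                              component = "logo", r = r),
                      subject_sd = 0, seed = 29L)
    ds <- suppressWarnings(simulate_dataset(cfg))
    mean(vapply(ds$beta, function(bs) {
      sm <- searchlight_map(bs, ds$rdms$chinese_word, "chinese_word")
      cognitive_load(sm$logo$z, sm$logo$sig)$load
    }, 0))
  }, 0)
  expect_true(all(diff(loads) > 0))
})

test_that("overlap maps intersect masks and count per region", {
  g <- c(10L, 10L, 10L)
  atlas <- array(0L, g)
  atlas[2:4, 2:4, 2:4] <- 1L
  atlas[7:9, 7:9, 7:9] <- 2L
  a <- array(FALSE, g); b <- array(FALSE, g)
  a[2:4, 2:4, 2] <- TRUE               # 9 voxels in region 1
  b[2:4, 2:3, 2] <- TRUE               # 6 voxels, 6 shared... constrain to 4
  b[, , ] <- FALSE
  b[2:3, 2:3, 2] <- TRUE               # shares 4 voxels with a, region 1
  ov <- overlap_map(a, b, atlas)
  expect_equal(sum(ov$mask), 4L)
  expect_equal(ov$roi_counts$n_voxels[ov$roi_counts$index == 1L], 4L)
  expect_equal(ov$roi_counts$n_voxels[ov$roi_counts$index == 2L], 0L)
  expect_equal(ov$peaks$size, 4L)
  # identity and disjointness
  expect_equal(overlap_map(a, a, atlas)$mask, a)
  expect_equal(sum(overlap_map(a, !a & atlas > 0L, atlas)$mask), 0L)
  expect_error(overlap_map(a, array(FALSE, c(5L, 5L, 5L)), atlas),
               "grids")
})

test_that("overlap peaks map through the affine", {
  g <- c(10L, 10L, 10L)
  atlas <- array(1L, g)
  a <- array(FALSE, g)
  a[3, 4, 5] <- TRUE
  aff <- diag(c(2, 2, 2, 1)); aff[1:3, 4] <- c(-10, -10, -10)
  ov <- overlap_map(a, a, atlas, affine = aff)
  expect_equal(c(ov$peaks$x_mm, ov$peaks$y_mm, ov$peaks$z_mm),
               c(2 * 2 - 10, 3 * 2 - 10, 4 * 2 - 10))
})

test_that("subsample stability is exact at full size and improves with n", {
  loads <- make_loads(30L, effects = data.frame(
    condition = c("chinese_word", "english_word"),
    component = c("logo", "phonology"), delta = c(2, 1)), seed = 61L)
  full <- subsample_stability(loads, sizes = 30L, n_rep = 5L, seed = 1L)
  expect_true(all(abs(full$correlation - 1) < 1e-12))
  res <- subsample_stability(loads, sizes = c(5L, 15L, 25L),
                             n_rep = 100L, seed = 2L)
  meds <- tapply(res$correlation, res$size, median)
  expect_true(all(diff(meds) >= 0))
  # determinism
  res2 <- subsample_stability(loads, sizes = c(5L, 15L, 25L),
                              n_rep = 100L, seed = 2L)
  expect_identical(res, res2)
  expect_error(subsample_stability(loads, sizes = 2L), ">= 3")
})

test_that("extent permutation test is calibrated and detects differences", {
  g <- c(10L, 10L, 10L)
  set.seed(77)
  null_maps <- replicate(12, array(rnorm(prod(g), 0, 1), g),
                         simplify = FALSE)
  # identical groups: p should be unremarkable
  res0 <- permutation_extent_test(null_maps[1:6], null_maps[7:12],
                                  n_perm = 200L, seed = 3L)
  expect_gt(res0$p, 0.05)
  # planted extent difference: group 2 carries a strong blob
  alt_maps <- lapply(1:6, function(i) {
    m <- array(rnorm(prod(g), 0, 1), g)
    m[3:7, 3:7, 3:7] <- m[3:7, 3:7, 3:7] + 2
    m
  })
  res1 <- permutation_extent_test(null_maps[1:6], alt_maps,
                                  n_perm = 500L, seed = 4L)
  expect_lt(res1$p, 0.05)
  # reproducible under the same seed
  res2 <- permutation_extent_test(null_maps[1:6], alt_maps,
                                  n_perm = 500L, seed = 4L)
  expect_identical(res1$p, res2$p)
  expect_warning(permutation_extent_test(null_maps[1:6], alt_maps,
                                         n_perm = 50L, seed = 1L),
                 "coarse")
})
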