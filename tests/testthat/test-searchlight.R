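# Searchlight machinery: variation filter, sphere geometry, neural RDMs,
# partial Spearman correlation, Fisher z, and whole-volume maps.

mini_beta <- function(data, mask = NULL, voxel = 2) {
  g <- dim(data)[1:3]
  if (is.null(mask)) mask <- array(TRUE, g)
  aff <- diag(c(voxel, voxel, voxel, 1))
  n <- dim(data)[4]
  tt <- data.frame(trial_index = seq_len(n),
                   condition = rep("chinese_word", n),
                   item_id = sprintf("it%02d", seq_len(n)))
  beta_set(data, aff, mask, tt, subject = "S01")
}

test_that("variation filter discards flat voxels and matches enumeration", {
  set.seed(4)
  d <- array(rnorm(4 * 4 * 4 * 12), c(4, 4, 4, 12))
  d[1, 1, 1, ] <- 5                      # constant: SD 0, mean 5
  d[2, 1, 1, ] <- c(rep(0, 6), rep(8, 6))  # SD = 4.17 > mean/8
  bs <- mini_beta(d)
  keep <- variation_filter(bs, 1 / 8)
  expect_false(keep[1, 1, 1])
  expect_true(keep[2, 1, 1])
  # brute-force per-voxel check
  oracle <- array(FALSE, c(4, 4, 4))
  for (i in 1:4) for (j in 1:4) for (k in 1:4) {
    v <- d[i, j, k, ]
    oracle[i, j, k] <- sd(v) >= abs(mean(v)) / 8
  }
  expect_identical(keep, oracle)
  # SD >= |mean| survives even at fraction 1
  d2 <- array(0, c(2, 2, 2, 12))
  d2[, , , 7:12] <- 2  # every voxel: mean 1, SD sqrt(12/11) > 1
  expect_true(all(variation_filter(mini_beta(d2), fraction = 1)))
  expect_error(variation_filter(mini_beta(array(5, c(2, 2, 2, 12)))),
               "every voxel")
})

test_that("6-mm spheres on a 2-mm grid equal the lattice-count oracle", {
  off <- sphere_offsets(6, 2)
  # brute force: integer offsets with i^2 + j^2 + k^2 <= 9
  cnt <- 0L
  for (i in -3:3) for (j in -3:3) for (k in -3:3) {
    if (i^2 + j^2 + k^2 <= 9) cnt <- cnt + 1L
  }
  expect_equal(nrow(off), cnt)
  expect_true(all(rowSums(off^2) <= 9))
  # radius below half a voxel: just the centre
  expect_equal(nrow(sphere_offsets(0.9, 2)), 1L)
})

test_that("sphere indices respect mask and edges", {
  mask <- array(TRUE, c(9, 9, 9))
  deep <- sphere_indices(c(5L, 5L, 5L), 6, diag(c(2, 2, 2, 1)), mask)
  expect_equal(nrow(deep), nrow(sphere_offsets(6, 2)))
  edge <- sphere_indices(c(1L, 5L, 5L), 6, diag(c(2, 2, 2, 1)), mask)
  expect_lt(nrow(edge), nrow(deep))
  keys <- function(m) paste(m[, 1], m[, 2], m[, 3])
  expect_true(all(keys(edge) %in%
                    keys(sweep(deep, 2L, c(-4L, 0L, 0L), "+"))))
  # mask holes are excluded
  mask[5, 5, 6] <- FALSE
  holed <- sphere_indices(c(5L, 5L, 5L), 6, diag(c(2, 2, 2, 1)), mask)
  expect_equal(nrow(holed), nrow(deep) - 1L)
})

test_that("neural RDMs are one minus Spearman rho of trial patterns", {
  set.seed(8)
  X <- matrix(rnorm(20 * 6), 20, 6)
  X[, 2] <- X[, 1] * 2 + 5          # same ranks as column 1
  X[, 3] <- -X[, 1]                 # reversed ranks
  m <- neural_rdm(X)
  expect_equal(m[1, 2], 0)
  expect_equal(m[1, 3], 2)
  # rank-then-Pearson oracle
  R <- apply(X, 2, rank)
  oracle <- 1 - cor(R)
  diag(oracle) <- 0
  expect_equal(unclass(m), oracle, tolerance = 1e-12, ignore_attr = TRUE)
  # constant pattern: undefined entries with warning
  X[, 4] <- 3
  expect_warning(m2 <- neural_rdm(X), "constant")
  expect_true(all(is.na(unclass(m2)[4, -4])))
})

test_that("partial Spearman agrees with its two independent formulations", {
  # residual-regression implementation vs inverse-correlation oracle
  for (i in 1:100) {
    n <- 12L
    x <- rand_rdm(n, seed = 300 + i)
    y <- rand_rdm(n, seed = 400 + i)
    z1 <- rand_rdm(n, seed = 500 + i)
    z2 <- rand_rdm(n, seed = 600 + i)
    got <- partial_spearman(x, y, list(z1, z2))$rho
    R <- cor(cbind(rank(rdm_vec(x)), rank(rdm_vec(y)),
                   rank(rdm_vec(z1)), rank(rdm_vec(z2))))
    P <- solve(R)
    oracle <- -P[1, 2] / sqrt(P[1, 1] * P[2, 2])
    expect_equal(got, oracle, tolerance = 1e-10)
  }
})

test_that("partial Spearman boundary contracts hold", {
  x <- rand_rdm(15, seed = 31)
  y <- rand_rdm(15, seed = 32)
  # empty control list reduces to plain Spearman
  expect_equal(partial_spearman(x, y)$rho,
               cor(rdm_vec(x), rdm_vec(y), method = "spearman"))
  # target identical to a control is fully explained
  expect_lt(abs(partial_spearman(x, y, list(y))$rho), 1e-10)
  # collinear controls are named errors
  expect_error(partial_spearman(x, y, list(y, y)), "collinear")
  # permutation p is reproducible and consistent with the parametric p
  p1 <- partial_spearman(x, y, perm = 200L, seed = 9L)$p
  p2 <- partial_spearman(x, y, perm = 200L, seed = 9L)$p
  expect_identical(p1, p2)
})

test_that("Fisher z is the odd atanh transform with clamping", {
  expect_equal(fisher_z(0), 0)
  expect_equal(fisher_z(0.5), atanh(0.5))
  # series oracle: atanh(r) = sum r^(2k+1)/(2k+1)
  r <- 0.5
  expect_equal(fisher_z(r), sum(r^(2 * (0:50) + 1) / (2 * (0:50) + 1)),
               tolerance = 1e-12)
  rs <- seq(-0.9, 0.9, by = 0.3)
  expect_equal(fisher_z(-rs), -fisher_z(rs))
  expect_warning(z <- fisher_z(1), "clamped")
  expect_true(is.finite(z))
})

test_that("searchlight maps respect thresholding contracts", {
  tp <- tiny_planted()
  ds <- tp$ds
  bs <- ds$beta[[1]]
  # alpha = 1, cluster_min = 0: every computed voxel is significant
  sm <- searchlight_map(bs, ds$rdms$chinese_word, "chinese_word",
                        alpha = 1, cluster_min = 0L)
  computed <- is.finite(sm$logo$p)
  expect_identical(sm$logo$sig, computed)
  # planted region stands out against the background
  sm2 <- tp$maps[[1]]$chinese_word
  zin <- sm2$logo$z[ds$atlas == 1L]
  zout <- sm2$logo$z[ds$mask & ds$atlas == 0L]
  expect_gt(median(zin, na.rm = TRUE), median(zout, na.rm = TRUE))
  expect_error(searchlight_map(bs, ds$rdms$chinese_word, "nonexistent"),
               "absent")
})

test_that("maps are invariant under monotone transforms of the betas", {
  tp <- tiny_planted()
  ds <- tp$ds
  bs <- ds$beta[[1]]
  shifted <- (bs$data - min(bs$data) + 1)^3
  bs2 <- beta_set(shifted, bs$affine, bs$mask, bs$trial_table, "S01")
  a <- searchlight_map(bs, ds$rdms$chinese_word, "chinese_word",
                       fraction = 1e-9)
  b <- searchlight_map(bs2, ds$rdms$chinese_word, "chinese_word",
                       fraction = 1e-9)
  expect_equal(a$logo$z, b$logo$z, tolerance = 1e-10)
  expect_equal(a$semantics$p, b$semantics$p, tolerance = 1e-10)
})

test_that("maps are invariant under trial reordering", {
  tp <- tiny_planted()
  ds <- tp$ds
  bs <- ds$beta[[1]]
  perm <- sample(seq_len(dim(bs$data)[4]))
  tt2 <- bs$trial_table[perm, ]
  tt2$trial_index <- seq_len(nrow(tt2))
  bs2 <- beta_set(bs$data[, , , perm, drop = FALSE], bs$affine, bs$mask,
                  tt2, "S01")
  a <- searchlight_map(bs, ds$rdms$chinese_word, "chinese_word")
  b <- searchlight_map(bs2, ds$rdms$chinese_word, "chinese_word")
  expect_equal(a$logo$z, b$logo$z, tolerance = 1e-10)
})

test_that("a searchlight smaller than its minimum voxel count yields NaN", {
  tp <- tiny_planted()
  ds <- tp$ds
  bs <- ds$beta[[1]]
  expect_message(
    sm <- searchlight_map(bs, ds$rdms$chinese_word, "chinese_word",
                          radius_mm = 1),
    "skipped")
  expect_true(all(is.nan(sm$logo$z[ds$mask])))
})
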