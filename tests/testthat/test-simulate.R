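# Synthetic-data generator: stimulus inventories, dataset geometry,
# determinism, planted-effect calibration and detectability.

small_cfg <- function(...) {
  sim_config(n_subjects = 2L, n_trials_per_condition = 10L,
             grid_shape = c(11L, 11L, 11L), n_regions = 2L,
             n_background = 64L, seed = 3L, ...)
}

test_that("stimulus generation honours counts, uniqueness and determinism", {
  st <- generate_stimuli(sim_config(n_subjects = 1L, seed = 2L))
  expect_equal(nrow(st), 120L)
  expect_equal(unname(table(st$condition)[conditions_vec <- unique(st$condition)]),
               rep(40L, 3L), ignore_attr = TRUE)
  expect_false(any(duplicated(st$id)))
  # unit multisets sized 3-8, embeddings unit-norm
  expect_true(all(lengths(st$logo_units) %in% 3:8))
  expect_true(all(abs(vapply(st$embedding,
                             function(v) sqrt(sum(v^2)), 0) - 1) < 1e-12))
  # no two items share all decompositions
  sig <- vapply(seq_len(nrow(st)), function(i) {
    paste(c(st$logo_units[[i]], "/", st$phon_units[[i]]), collapse = ",")
  }, "")
  expect_false(any(duplicated(sig)))
  # determinism: byte-identical on the same seed
  expect_identical(st, generate_stimuli(sim_config(n_subjects = 1L,
                                                   seed = 2L)))
})

test_that("an undersized alphabet is rejected with the required size", {
  expect_error(generate_stimuli(sim_config(n_subjects = 1L,
                                           alphabet_size = 5L)),
               "at least")
})

test_that("configuration invariants are enforced", {
  expect_error(sim_config(grid_shape = c(5L, 5L, 5L)), ">= 1000")
  expect_error(sim_config(n_trials_per_condition = 4L), ">= 8")
  expect_error(sim_config(effect_map = data.frame(
    region = 1L, condition = "chinese_word", component = "logo",
    r = 1.2)), "\\[0, 1\\]")
  expect_error(sim_config(n_regions = 40L), "1\\.\\.30")
})

test_that("dataset geometry satisfies its invariants", {
  ds <- simulate_dataset(small_cfg())
  expect_equal(dim(ds$beta[[1]]$data)[4], 30L)
  expect_true(all(sort(unique(as.integer(ds$atlas))) %in% 0:2))
  # mask covers every atlas region
  expect_true(all(ds$mask[ds$atlas > 0L]))
  # trial table covers every volume and each condition in RDM item order
  tt <- ds$beta[[1]]$trial_table
  expect_setequal(tt$trial_index, 1:30)
  for (cond in unique(ds$stimuli$condition)) {
    expect_setequal(tt$item_id[tt$condition == cond],
                    rownames(ds$rdms[[cond]]$logo))
  }
})

test_that("identical config and seed reproduce the dataset bit for bit", {
  cfg <- small_cfg(effect_map = data.frame(
    region = 1L, condition = "chinese_word", component = "logo", r = 0.5))
  d1 <- simulate_dataset(cfg)
  d2 <- simulate_dataset(cfg)
  expect_identical(d1$beta[[1]]$data, d2$beta[[1]]$data)
  expect_identical(d1$behavior, d2$behavior)
  expect_identical(d1$atlas, d2$atlas)
})

test_that("behavior tables show the RT ordering and ceiling accuracy", {
  ds <- simulate_dataset(sim_config(n_subjects = 30L,
                                    grid_shape = c(10L, 10L, 10L),
                                    n_regions = 1L, n_background = 27L,
                                    seed = 9L))
  b <- ds$behavior
  means <- tapply(b$rt_ms, b$condition, mean)
  expect_lt(means["chinese_word"], means["english_word"])
  expect_lt(means["english_word"], means["chinese_pinyin"])
  expect_gt(mean(b$accuracy), 0.95)
  expect_setequal(unique(b$aoa_group), c("early", "late"))
})

test_that("mixing-weight calibration hits requested rank correlations", {
  st <- generate_stimuli(sim_config(n_subjects = 1L, seed = 13L))
  target_rdm <- build_behavioral_rdm(st, "semantics", "chinese_word")
  for (r in c(0.3, 0.6)) {
    lam <- calibrate_mixing(r, target_rdm, n_voxels = 60L,
                            n_draws = 100L, seed = 5L)
    expect_lt(abs(attr(lam, "achieved") - r), 0.05 + 0.03)  # MC noise
  }
  expect_identical(as.numeric(calibrate_mixing(0, target_rdm, 60L)), 0)
})

test_that("in-region searchlight z is monotone in the planted effect size", {
  meds <- vapply(c(0, 0.3, 0.6, 0.9), function(r) {
    em <- if (r > 0) data.frame(region = 1L, condition = "chinese_word",
                                component = "logo", r = r) else NULL
    cfg <- sim_config(n_subjects = 2L, n_trials_per_condition = 15L,
                      grid_shape = c(11L, 11L, 11L), n_regions = 1L,
                      n_background = 64L, effect_map = em,
                      subject_sd = 0, seed = 17L)
    # at high targets the calibration may clamp at its ceiling; the
    # monotonicity property is unaffected
    ds <- suppressWarnings(simulate_dataset(cfg))
    zin <- unlist(lapply(ds$beta, function(bs) {
      sm <- searchlight_map(bs, ds$rdms$chinese_word, "chinese_word")
      sm$logo$z[ds$atlas == 1L]
    }))
    median(zin, na.rm = TRUE)
  }, 0)
  expect_true(all(diff(meds) > -0.02))  # non-decreasing up to noise
  expect_gt(meds[4] - meds[1], 0.3)     # and clearly increasing overall
})

test_that("null data yield near-zero mean searchlight z", {
  tp <- tiny_planted()
  ds <- tp$ds
  # unplanted condition: english words carry no signal anywhere
  z <- unlist(lapply(tp$maps, function(m) {
    m$english_word$logo$z[is.finite(m$english_word$logo$z)]
  }))
  se <- sd(z) / sqrt(length(z))
  expect_lt(abs(mean(z)), 3 * se + 0.02)
})

test_that("planting one component does not inflate the others' maps", {
  tp <- tiny_planted()
  ds <- tp$ds
  in_region <- ds$atlas == 1L
  med <- function(comp) {
    median(unlist(lapply(tp$maps, function(m) {
      m$chinese_word[[comp]]$z[in_region]
    })), na.rm = TRUE)
  }
  expect_gt(med("logo"), 0.25)
  # partial correlation controls keep the unplanted components near zero
  expect_lt(abs(med("phonology")), 0.12)
  expect_lt(abs(med("semantics")), 0.12)
})

test_that("dataset round-trips through the on-disk layout", {
  dir <- withr::local_tempdir()
  ds <- simulate_dataset(small_cfg())
  write_dataset(ds, dir)
  expect_true(all(file.exists(file.path(dir, c(
    "stimuli.tsv", "embeddings.tsv", "mask.nii.gz", "atlas.nii.gz",
    "labels.tsv", "behavior.tsv", "truth.json",
    "S01_beta.nii.gz", "S01_events.tsv")))))
  st2 <- read_stimuli(file.path(dir, "stimuli.tsv"),
                      file.path(dir, "embeddings.tsv"))
  expect_identical(st2$logo_units, ds$stimuli$logo_units)
  expect_equal(do.call(rbind, st2$embedding),
               do.call(rbind, ds$stimuli$embedding), tolerance = 1e-6)
  bs <- read_beta_set(file.path(dir, "S01_beta.nii.gz"),
                      file.path(dir, "S01_events.tsv"),
                      file.path(dir, "mask.nii.gz"), subject = "S01")
  expect_equal(bs$data, ds$beta$S01$data, tolerance = 1e-6)
  expect_identical(bs$trial_table$item_id, ds$beta$S01$trial_table$item_id)
  expect_identical(bs$mask, ds$mask)
})
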