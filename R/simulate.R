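# Synthetic-data generator: stimulus inventories, toy atlas/mask geometry,
# and trial-wise beta volumes whose local pattern geometry correlates with a
# chosen behavioral RDM at a chosen effect size inside designated regions,
# pure white noise elsewhere.

# Evaluate expr with a temporary RNG state seeded by `seed`, restoring the
# caller's state afterwards. All generator randomness flows through this.
with_seed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(rm(".Random.seed", envir = globalenv()), add = TRUE)
  }
  set.seed(seed)
  expr
}

# deterministic sub-stream seed, kept inside 32-bit integer range
sub_seed <- function(seed, offset) {
  as.integer((as.double(seed) * 48271 + offset * 7919) %% 2147483399) + 1L
}

#' Simulation configuration
#'
#' Describes one synthetic study: how many subjects and trials, the voxel
#' grid, how many toy atlas regions, where representational geometry is
#' planted and how strongly, and the noise structure. The defaults mirror
#' the study design the pipeline targets: 3 writing-system conditions with
#' 40 trials each on a 2-mm isotropic grid.
#'
#' @param n_subjects number of subjects.
#' @param n_trials_per_condition trials per condition (>= 8 so rank
#'   correlations over the stimulus pairs are meaningful).
#' @param grid_shape integer triple, voxels per axis (volume >= 1000).
#' @param voxel_size_mm isotropic voxel size in mm.
#' @param n_regions number of toy atlas regions (<= 30).
#' @param region_radius_vox radius of each spherical region, in voxels.
#' @param effect_map data frame with columns `region`, `condition`,
#'   `component`, `r`: the target rank correlation (`r` in `[0, 1]`)
#'   between local neural RDMs inside that region and the named behavioral
#'   RDM for that condition. `NULL` means pure noise everywhere.
#' @param noise_sd standard deviation of the voxel noise.
#' @param subject_sd between-subject SD of the planted effect size.
#' @param n_background number of mask voxels outside any region (a compact
#'   block, so searchlights centred there are valid and carry no signal).
#' @param embedding_dim dimension of synthetic semantic embedding vectors.
#' @param alphabet_size symbols in each per-condition unit alphabet.
#' @param seed integer seed; identical config + seed reproduces the
#'   dataset bit for bit.
#' @return A list of class `"sim_config"`.
#' @export
sim_config <- function(n_subjects = 20L,
                       n_trials_per_condition = 40L,
                       grid_shape = c(20L, 20L, 20L),
                       voxel_size_mm = 2,
                       n_regions = 10L,
                       region_radius_vox = 2L,
                       effect_map = NULL,
                       noise_sd = 1,
                       subject_sd = 0.05,
                       n_background = 500L,
                       embedding_dim = 50L,
                       alphabet_size = 30L,
                       seed = 1L) {
  cfg <- list(n_subjects = as.integer(n_subjects),
              n_trials_per_condition = as.integer(n_trials_per_condition),
              grid_shape = as.integer(grid_shape),
              voxel_size_mm = voxel_size_mm,
              n_regions = as.integer(n_regions),
              region_radius_vox = as.integer(region_radius_vox),
              effect_map = effect_map,
              noise_sd = noise_sd,
              subject_sd = subject_sd,
              n_background = as.integer(n_background),
              embedding_dim = as.integer(embedding_dim),
              alphabet_size = as.integer(alphabet_size),
              seed = as.integer(seed))
  validate_sim_config(cfg)
  structure(cfg, class = "sim_config")
}

validate_sim_config <- function(cfg) {
  stopifnot(length(cfg$grid_shape) == 3L, cfg$voxel_size_mm > 0,
            cfg$noise_sd > 0, cfg$subject_sd >= 0, cfg$n_subjects >= 1L)
  if (prod(cfg$grid_shape) < 1000L) {
    stop("sim_config: grid volume must be >= 1000 voxels")
  }
  if (cfg$n_trials_per_condition < 8L) {
    stop("sim_config: need >= 8 trials per condition")
  }
  if (cfg$n_regions < 1L || cfg$n_regions > 30L) {
    stop("sim_config: n_regions must be in 1..30")
  }
  em <- cfg$effect_map
  if (!is.null(em)) {
    stopifnot(all(c("region", "condition", "component", "r") %in% names(em)))
    if (any(em$r < 0 | em$r > 1)) {
      stop("sim_config: every planted effect size must lie in [0, 1]")
    }
    if (any(!em$condition %in% conditions()) ||
        any(!em$component %in% components())) {
      stop("sim_config: unknown condition or component in effect_map")
    }
    if (any(em$region < 1L | em$region > cfg$n_regions)) {
      stop("sim_config: effect_map region outside 1..n_regions")
    }
  }
  invisible(cfg)
}

#' Generate a synthetic stimulus set
#'
#' Draws `3 * n_trials_per_condition` stimuli: for each item a
#' logo-grapheme unit multiset (size 3-8 from a finite per-condition
#' alphabet, so pairwise overlap varies), a phonetic unit multiset (the
#' Chinese word and pinyin conditions share one phonetic inventory, as the
#' two scripts share a phonology), and a unit-norm embedding vector drawn
#' from a per-condition cluster centre plus noise. No two items are
#' identical.
#'
#' @param config a [sim_config()].
#' @return Stimulus data frame (see [read_stimuli()] for the columns).
#' @export
generate_stimuli <- function(config) {
  validate_sim_config(config)
  n <- config$n_trials_per_condition
  a <- config$alphabet_size
  # required so that 100 resampling attempts almost surely find distinct items
  min_alpha <- ceiling(max(10, 1.5 * sqrt(3 * n)))
  if (a < min_alpha) {
    stop("generate_stimuli: alphabet_size ", a, " too small to guarantee ",
         3 * n, " distinct items; need at least ", min_alpha)
  }
  with_seed(sub_seed(config$seed, 1L), {
    logo_alpha <- lapply(c(cw = "cw", ew = "ew", py = "py"),
                         function(p) sprintf("%s%03d", p, seq_len(a)))
    phon_alpha <- list(cw = sprintf("zh%03d", seq_len(a)),
                       ew = sprintf("en%03d", seq_len(a)),
                       py = sprintf("zh%03d", seq_len(a)))  # shared phonology
    centers <- lapply(1:3, function(i) {
      v <- stats::rnorm(config$embedding_dim)
      v / sqrt(sum(v^2))
    })
    out <- vector("list", 3L)
    for (ci in seq_along(conditions())) {
      cond <- conditions()[ci]
      key <- c("cw", "ew", "py")[ci]
      seen <- character(0)
      items <- vector("list", n)
      for (i in seq_len(n)) {
        for (attempt in 1:100) {
          lu <- sort(sample(logo_alpha[[key]], sample(3:8, 1L),
                            replace = TRUE))
          pu <- sort(sample(phon_alpha[[key]], sample(3:8, 1L),
                            replace = TRUE))
          sig <- paste(c(lu, "/", pu), collapse = ",")
          if (!sig %in% seen) break
          if (attempt == 100L) {
            stop("generate_stimuli: could not draw distinct items; ",
                 "increase alphabet_size to at least ", 2L * a)
          }
        }
        seen <- c(seen, sig)
        e <- centers[[ci]] + stats::rnorm(config$embedding_dim, sd = 0.6)
        items[[i]] <- list(id = sprintf("%s_%03d", key, i), condition = cond,
                           logo_units = lu, phon_units = pu,
                           embedding = e / sqrt(sum(e^2)))
      }
      out[[ci]] <- items
    }
    items <- do.call(c, out)
    df <- data.frame(id = vapply(items, `[[`, "", "id"),
                     condition = vapply(items, `[[`, "", "condition"),
                     stringsAsFactors = FALSE)
    df$logo_units <- lapply(items, `[[`, "logo_units")
    df$phon_units <- lapply(items, `[[`, "phon_units")
    df$embedding <- lapply(items, `[[`, "embedding")
    df
  })
}

# Place n_regions non-overlapping spherical blobs on the grid, avoiding the
# corner block reserved for background mask voxels. Returns integer 3D array.
make_atlas <- function(config) {
  g <- config$grid_shape
  r <- config$region_radius_vox
  bg_side <- ceiling(config$n_background^(1 / 3))
  atlas <- array(0L, g)
  coords <- as.matrix(expand.grid(x = seq_len(g[1]), y = seq_len(g[2]),
                                  z = seq_len(g[3])))
  with_seed(sub_seed(config$seed, 2L), {
    centers <- matrix(NA_real_, 0L, 3L)
    for (k in seq_len(config$n_regions)) {
      placed <- FALSE
      for (attempt in 1:500) {
        c_k <- vapply(g, function(gd) sample((r + 1L):(gd - r), 1L), 0L)
        # keep out of the background corner block (with a one-voxel margin)
        if (all(c_k - r <= bg_side + 1L)) next
        if (nrow(centers) == 0L ||
            min(sqrt(rowSums(sweep(centers, 2L, c_k)^2))) > 2 * r + 1) {
          centers <- rbind(centers, c_k)
          placed <- TRUE
          break
        }
      }
      if (!placed) {
        stop("make_atlas: could not place ", config$n_regions,
             " non-overlapping regions of radius ", r, " on grid ",
             paste(g, collapse = "x"))
      }
      d2 <- rowSums(sweep(coords, 2L, centers[k, ])^2)
      atlas[coords[d2 <= r^2, , drop = FALSE]] <- k
    }
  })
  atlas
}

make_mask <- function(config, atlas) {
  mask <- atlas > 0L
  bg_side <- ceiling(config$n_background^(1 / 3))
  bg <- as.matrix(expand.grid(x = seq_len(bg_side), y = seq_len(bg_side),
                              z = seq_len(bg_side)))
  bg <- bg[seq_len(min(nrow(bg), config$n_background)), , drop = FALSE]
  mask[bg] <- TRUE
  mask
}

make_affine <- function(config) {
  v <- config$voxel_size_mm
  aff <- diag(c(v, v, v, 1))
  aff[1:3, 4] <- -v * (config$grid_shape / 2)
  aff
}

# Latent configuration embedding a target RDM: classical metric MDS with
# k = min(10, n-1) dimensions; if the RDM is too non-metric for cmdscale a
# rank-preserving (non-metric) embedding is used instead, with a message.
latent_config <- function(target_rdm, k = NULL) {
  d <- unclass(as.matrix(target_rdm))
  n <- nrow(d)
  if (is.null(k)) k <- min(10L, n - 1L)
  L <- tryCatch({
    fit <- stats::cmdscale(d, k = k)
    if (is.null(dim(fit)) || ncol(fit) < 2L || any(!is.finite(fit))) {
      stop("degenerate")
    }
    fit
  }, error = function(e) {
    message("latent_config: metric MDS failed to embed the RDM; ",
            "falling back to rank-preserving (non-metric) embedding")
    init <- stats::cmdscale(d + 1e-8, k = 2L)
    utils::capture.output(
      fit <- MASS::isoMDS(d + 1e-8 * (1 - diag(n)), y = init, k = 2L))
    fit$points
  })
  # drop numerically dead axes; keep the eigenvalue scaling of the rest,
  # which carries the embedded distance geometry
  sds <- apply(L, 2L, stats::sd)
  L[, sds > 1e-8 * max(sds), drop = FALSE]
}

# signal patterns: random linear readouts of the latent configuration,
# standardized per voxel (columns = voxels, rows = trials)
readout_signal <- function(L, n_voxels) {
  W <- matrix(stats::rnorm(ncol(L) * n_voxels), ncol(L), n_voxels)
  S <- L %*% W
  sweep(S, 2L, apply(S, 2L, stats::sd), "/")
}

# Expected rank correlation between a searchlight neural RDM and the target
# RDM, as a function of the signal/noise mixing weight lambda, estimated by
# Monte Carlo.
mc_rdm_corr <- function(lambda, L, rank_target, n_voxels, n_draws, seed) {
  n <- nrow(L)
  with_seed(seed, {
    mean(vapply(seq_len(n_draws), function(i) {
      S <- readout_signal(L, n_voxels)
      X <- sqrt(lambda) * S +
        sqrt(1 - lambda) * matrix(stats::rnorm(n * n_voxels), n, n_voxels)
      nr <- 1 - stats::cor(t(X), method = "spearman")
      stats::cor(rank(nr[lower.tri(nr)]), rank_target)
    }, 0))
  })
}

#' Calibrate the signal/noise mixing weight for a target effect size
#'
#' The generator plants signal by mixing standardized latent-readout
#' patterns with white noise: `x = sqrt(lambda) * signal +
#' sqrt(1 - lambda) * noise`. The expected rank correlation between the
#' resulting local neural RDM and the target behavioral RDM is an
#' increasing but analytically intractable function of `lambda`, so the
#' weight is calibrated empirically: monotone bisection against a
#' Monte-Carlo estimate (200 draws by default, common random numbers),
#' to within `tol` of the requested correlation.
#'
#' @param target requested rank correlation in `[0, 1]`.
#' @param target_rdm the behavioral RDM whose geometry is planted.
#' @param n_voxels voxels per searchlight used in the calibration draws
#'   (use the sphere size at the analysis radius).
#' @param n_draws Monte-Carlo draws per evaluation.
#' @param tol calibration tolerance on the rank correlation.
#' @param seed RNG seed for the calibration draws.
#' @return `lambda` in `[0, 1]`, with the achieved correlation as
#'   attribute `"achieved"`.
#' @export
calibrate_mixing <- function(target, target_rdm, n_voxels,
                             n_draws = 200L, tol = 0.05, seed = 1L) {
  stopifnot(target >= 0, target <= 1)
  if (target == 0) return(structure(0, achieved = 0))
  L <- latent_config(target_rdm)
  rank_target <- rank(rdm_vec(target_rdm))
  g <- function(lambda) {
    mc_rdm_corr(lambda, L, rank_target, n_voxels, n_draws, seed)
  }
  hi_val <- g(1)
  if (hi_val < target - tol) {
    warning("calibrate_mixing: target rank correlation ", target,
            " exceeds the maximum achievable ", round(hi_val, 3),
            " for this RDM; using lambda = 1")
    return(structure(1, achieved = hi_val))
  }
  lo <- 0; hi <- 1; val <- hi_val; lam <- 1
  for (i in 1:12) {
    lam <- (lo + hi) / 2
    val <- g(lam)
    if (abs(val - target) <= tol * 0.5) break
    if (val < target) lo <- lam else hi <- lam
  }
  structure(lam, achieved = val)
}

#' Plant beta volumes with known representational geometry
#'
#' Builds the full synthetic dataset around a stimulus set: toy atlas and
#' analysis mask, per-subject 4D beta volumes, and a behavioral table.
#' Inside each region named in `config$effect_map`, voxel responses for
#' the named condition are a mix of white noise and random linear readouts
#' of a metric-MDS embedding of the target behavioral RDM, with the mixing
#' weight calibrated (see [calibrate_mixing()]) so the expected rank
#' correlation between local neural RDMs and the target equals the planted
#' effect size. All other voxels are pure noise. Reaction-time means are
#' ordered Chinese word < English word < Chinese pinyin with log-normal
#' subject variation; accuracy is near ceiling.
#'
#' @param stimuli stimulus set from [generate_stimuli()].
#' @param config the [sim_config()] that produced it.
#' @return A list of class `"synthetic_dataset"`: `stimuli`, `rdms`
#'   (nested behavioral RDMs), `beta` (per-subject `beta_set`s), `mask`,
#'   `atlas`, `labels`, `affine`, `behavior`, `truth` (the effect map) and
#'   `calibration` (lambda per planted effect).
#' @export
plant_beta_volumes <- function(stimuli, config) {
  validate_sim_config(config)
  n <- config$n_trials_per_condition
  stopifnot(nrow(stimuli) == 3L * n)
  g <- config$grid_shape
  nvox <- prod(g)
  atlas <- make_atlas(config)
  mask <- make_mask(config, atlas)
  affine <- make_affine(config)
  rdms <- behavioral_rdms(stimuli)

  em <- config$effect_map
  if (is.null(em)) {
    em <- data.frame(region = integer(0), condition = character(0),
                     component = character(0), r = numeric(0))
  }
  em <- em[em$r > 0, , drop = FALSE]

  # calibrate one mixing weight per planted effect, at the sphere size of a
  # 6-mm searchlight on this grid
  sphere_n <- nrow(sphere_offsets(6, config$voxel_size_mm))
  lambdas <- numeric(nrow(em))
  latents <- vector("list", nrow(em))
  if (nrow(em) > 0L) {
    for (i in seq_len(nrow(em))) {
      tr <- rdms[[em$condition[i]]][[em$component[i]]]
      lambdas[i] <- calibrate_mixing(em$r[i], tr, sphere_n,
                                     seed = sub_seed(config$seed, 100L + i))
      latents[[i]] <- latent_config(tr)
    }
  }
  calibration <- cbind(em, lambda = lambdas)

  subjects <- sprintf("S%02d", seq_len(config$n_subjects))
  beta_sets <- vector("list", config$n_subjects)
  names(beta_sets) <- subjects
  cond_of_item <- stimuli$condition
  for (s in seq_len(config$n_subjects)) {
    beta_sets[[s]] <- with_seed(sub_seed(config$seed, 1000L + s), {
      beta <- array(stats::rnorm(nvox * 3L * n), c(g, 3L * n))
      # trial presentation order randomized per subject
      order_perm <- sample(3L * n)
      trial_table <- data.frame(trial_index = seq_len(3L * n),
                                condition = cond_of_item[order_perm],
                                item_id = stimuli$id[order_perm],
                                stringsAsFactors = FALSE)
      if (nrow(em) > 0L) {
        groups <- split(seq_len(nrow(em)),
                        paste(em$region, em$condition, sep = "/"))
        for (grp in groups) {
          region <- em$region[grp[1L]]
          cond <- em$condition[grp[1L]]
          vox <- which(atlas == region)
          trials <- which(trial_table$condition == cond)
          # trials reordered to the behavioral RDM's item order
          item_order <- stimuli$id[stimuli$condition == cond]
          trials <- trials[match(item_order, trial_table$item_id[trials])]
          lam_s <- pmin(1, pmax(0, lambdas[grp] *
            (1 + stats::rnorm(length(grp), 0, config$subject_sd))))
          if (sum(lam_s) > 1) lam_s <- lam_s / sum(lam_s)
          block <- sqrt(1 - sum(lam_s)) *
            matrix(stats::rnorm(n * length(vox)), n, length(vox))
          for (j in seq_along(grp)) {
            block <- block + sqrt(lam_s[j]) *
              readout_signal(latents[[grp[j]]], length(vox))
          }
          flat <- matrix(beta, nvox, 3L * n)
          flat[vox, trials] <- t(block)
          beta <- array(flat, c(g, 3L * n))
        }
      }
      beta_set(beta * config$noise_sd, affine, mask, trial_table,
               subject = subjects[s])
    })
  }

  behavior <- with_seed(sub_seed(config$seed, 3L), {
    base_rt <- c(chinese_word = 750, english_word = 900,
                 chinese_pinyin = 1050)
    rows <- expand.grid(subject = subjects, condition = conditions(),
                        stringsAsFactors = FALSE)
    subj_off <- stats::rnorm(length(subjects), 0, 0.08)
    names(subj_off) <- subjects
    rows$accuracy <- stats::rbinom(nrow(rows), n, 0.98) / n
    rows$rt_ms <- exp(log(base_rt[rows$condition]) +
                        subj_off[rows$subject] +
                        stats::rnorm(nrow(rows), 0, 0.05))
    rows$aoa_group <- ifelse(match(rows$subject, subjects) <=
                               ceiling(length(subjects) / 2),
                             "early", "late")
    rows[order(rows$subject, rows$condition), ]
  })
  rownames(behavior) <- NULL

  labels <- data.frame(index = seq_len(config$n_regions),
                       name = sprintf("region_%02d",
                                      seq_len(config$n_regions)))
  structure(list(config = config, stimuli = stimuli, rdms = rdms,
                 beta = beta_sets, mask = mask, atlas = atlas,
                 labels = labels, affine = affine, behavior = behavior,
                 truth = config$effect_map, calibration = calibration),
            class = "synthetic_dataset")
}

#' @rdname plant_beta_volumes
#' @param config a [sim_config()].
#' @export
simulate_dataset <- function(config) {
  plant_beta_volumes(generate_stimuli(config), config)
}

#' Trial-wise beta volume set for one subject
#'
#' @param data 4D array (x, y, z, trial) of response amplitudes.
#' @param affine 4x4 voxel-to-mm map.
#' @param mask 3D logical analysis mask.
#' @param trial_table data frame `trial_index`, `condition`, `item_id`
#'   covering every 4th-dimension index.
#' @param subject subject id label.
#' @return A list of class `"beta_set"`.
#' @export
beta_set <- function(data, affine, mask, trial_table, subject = NA_character_) {
  stopifnot(length(dim(data)) == 4L,
            all(dim(data)[1:3] == dim(mask)),
            nrow(trial_table) == dim(data)[4L],
            all(sort(trial_table$trial_index) == seq_len(dim(data)[4L])))
  structure(list(data = data, affine = affine, mask = mask,
                 trial_table = trial_table, subject = subject),
            class = "beta_set")
}

#' Write a synthetic dataset to disk
#'
#' Emits the on-disk layout the pipeline consumes: one 4D NIfTI + events
#' TSV per subject, 3D NIfTI mask and atlas, stimulus/embedding/label/
#' behavior TSVs, and JSON files recording the config and the planted
#' truth.
#'
#' @param ds a `synthetic_dataset`.
#' @param dir output directory (created if needed).
#' @export
write_dataset <- function(ds, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_stimuli(ds$stimuli, dir)
  write_nifti_vol(ds$mask * 1L, ds$affine, file.path(dir, "mask.nii.gz"))
  write_nifti_vol(ds$atlas, ds$affine, file.path(dir, "atlas.nii.gz"))
  utils::write.table(ds$labels, file.path(dir, "labels.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  utils::write.table(ds$behavior, file.path(dir, "behavior.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  for (s in names(ds$beta)) {
    bs <- ds$beta[[s]]
    write_nifti_vol(bs$data, bs$affine,
                    file.path(dir, sprintf("%s_beta.nii.gz", s)))
    utils::write.table(bs$trial_table,
                       file.path(dir, sprintf("%s_events.tsv", s)),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  }
  cfg <- ds$config
  cfg$effect_map <- NULL
  jsonlite::write_json(list(config = unclass(cfg),
                            effect_map = ds$truth),
                       file.path(dir, "truth.json"), auto_unbox = TRUE,
                       digits = NA, null = "null")
  invisible(dir)
}

#' Write a 3D/4D array as NIfTI with an explicit affine
#'
#' @param arr numeric array.
#' @param affine 4x4 voxel-to-mm map (stored as the sform).
#' @param path output `.nii.gz` path.
#' @export
write_nifti_vol <- function(arr, affine, path) {
  im <- RNifti::asNifti(arr)
  im <- RNifti::`sform<-`(im, structure(affine, code = 2L))
  RNifti::writeNifti(im, path)
  invisible(path)
}

#' Read a subject's beta volumes and events back from disk
#'
#' @param beta_path 4D NIfTI of trial-wise betas.
#' @param events_path events TSV (`trial_index`, `condition`, `item_id`).
#' @param mask_path 3D NIfTI analysis mask.
#' @param subject subject label.
#' @return A [beta_set()].
#' @export
read_beta_set <- function(beta_path, events_path, mask_path,
                          subject = NA_character_) {
  im <- RNifti::readNifti(beta_path)
  affine <- structure(RNifti::xform(im), code = NULL)
  mask <- array(as.vector(RNifti::readNifti(mask_path)) > 0,
                dim(im)[1:3])
  events <- utils::read.delim(events_path, colClasses = c(
    trial_index = "integer", condition = "character", item_id = "character"))
  beta_set(array(as.vector(im), dim(im)), as.matrix(affine), mask, events,
           subject = subject)
}
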