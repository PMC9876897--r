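# End-to-end driver: simulate -> behavioral RDMs -> searchlight -> group
# inference -> classification -> associations, writing every declared
# artifact under an output directory. The numbered scripts in analysis/
# run these stages individually with narrative output.

#' Run the full analysis pipeline on a synthetic dataset
#'
#' Executes every stage on one simulated study and writes its artifacts:
#' the dataset (NIfTI betas, mask, atlas; TSV stimuli, events, behavior;
#' JSON truth), behavioral RDMs and their intercorrelations, per-subject
#' searchlight z/p/significance maps, group t maps, the cognitive-load
#' table, cross-language overlap tables, LOSO SVR accuracies with RFE,
#' the repeated-measures ANOVA and load-RT associations, plus a
#' `summary.json` of the headline numbers.
#'
#' @param config a [sim_config()]; the default plants a distinct
#'   component effect per condition in three regions so that every
#'   downstream stage has structure to find.
#' @param out_dir output directory.
#' @param radius_mm,alpha,cluster_min,connectivity searchlight and
#'   thresholding settings.
#' @param write_subject_maps write per-subject NIfTI maps (many small
#'   files; disable for quick runs).
#' @return Invisibly, a list with the in-memory results of every stage.
#' @export
run_pipeline <- function(config = default_pipeline_config(),
                         out_dir, radius_mm = 6, alpha = 0.05,
                         cluster_min = 10L, connectivity = 18L,
                         write_subject_maps = TRUE) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)

  ds <- simulate_dataset(config)
  write_dataset(ds, file.path(out_dir, "data"))

  rdm_dir <- file.path(out_dir, "rdms")
  dir.create(rdm_dir, showWarnings = FALSE)
  for (cond in conditions()) {
    for (comp in components()) {
      write_rdm(ds$rdms[[cond]][[comp]],
                file.path(rdm_dir, sprintf("%s_%s.tsv", cond, comp)))
    }
  }
  rdm_cors <- do.call(rbind, lapply(conditions(), function(cond) {
    out <- rdm_correlations(ds$rdms[[cond]])
    cbind(condition = cond, out)
  }))
  utils::write.table(rdm_cors, file.path(out_dir, "rdm_correlations.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)

  maps <- searchlight_all(ds, radius_mm = radius_mm, alpha = alpha,
                          cluster_min = cluster_min,
                          connectivity = connectivity)
  if (write_subject_maps) {
    map_dir <- file.path(out_dir, "maps")
    dir.create(map_dir, showWarnings = FALSE)
    for (s in names(maps)) {
      for (cond in conditions()) {
        for (comp in components()) {
          rm_ <- maps[[s]][[cond]][[comp]]
          base <- sprintf("%s_%s_%s", s, cond, comp)
          write_nifti_vol(rm_$z, ds$affine,
                          file.path(map_dir, paste0(base, "_z.nii.gz")))
          write_nifti_vol(rm_$p, ds$affine,
                          file.path(map_dir, paste0(base, "_p.nii.gz")))
          write_nifti_vol(rm_$sig * 1L, ds$affine,
                          file.path(map_dir, paste0(base, "_sig.nii.gz")))
        }
      }
    }
  }

  group_dir <- file.path(out_dir, "group")
  dir.create(group_dir, showWarnings = FALSE)
  group_maps <- setNames(lapply(conditions(), function(cond) {
    setNames(lapply(components(), function(comp) {
      gm <- one_sample_t_map(lapply(maps, function(m) m[[cond]][[comp]]$z),
                             alpha = alpha, cluster_min = cluster_min,
                             connectivity = connectivity)
      base <- file.path(group_dir, sprintf("%s_%s", cond, comp))
      write_nifti_vol(gm$t, ds$affine, paste0(base, "_t.nii.gz"))
      write_nifti_vol(gm$sig * 1L, ds$affine, paste0(base, "_sig.nii.gz"))
      gm
    }), components())
  }), conditions())

  loads <- load_table(maps, ds$behavior)
  utils::write.table(loads, file.path(out_dir, "loads.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)

  pairs <- utils::combn(conditions(), 2L, simplify = FALSE)
  overlaps <- do.call(rbind, lapply(components(), function(comp) {
    do.call(rbind, lapply(pairs, function(pr) {
      ov <- overlap_map(group_maps[[pr[1L]]][[comp]]$sig,
                        group_maps[[pr[2L]]][[comp]]$sig,
                        ds$atlas, ds$labels, ds$affine,
                        stat_map = group_maps[[pr[1L]]][[comp]]$t,
                        connectivity = connectivity)
      cbind(component = comp, condition_a = pr[1L], condition_b = pr[2L],
            ov$roi_counts)
    }))
  }))
  utils::write.table(overlaps, file.path(out_dir, "overlap_rois.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)

  fold_fms <- fold_feature_matrices(maps, ds$atlas, alpha = alpha,
                                    cluster_min = cluster_min,
                                    connectivity = connectivity)
  accuracies <- c(
    vapply(pairs, function(pr) {
      loso_svr_foldwise(maps, ds$atlas, pair = pr,
                        fold_features = fold_fms)$accuracy
    }, 0),
    three_class = loso_svr_foldwise(maps, ds$atlas,
                                    fold_features = fold_fms)$accuracy)
  names(accuracies)[1:3] <- vapply(pairs, paste, "", collapse = "_vs_")
  fm <- build_features(maps, ds$atlas, alpha = alpha,
                       cluster_min = cluster_min,
                       connectivity = connectivity)
  rfe <- rfe_rank_and_select(fm)
  jsonlite::write_json(
    list(accuracies = as.list(accuracies),
         rfe = list(knee = rfe$knee, has_knee = rfe$has_knee,
                    ranking = rfe$ranking,
                    selected_features = rfe$selected_features,
                    curve = rfe$curve)),
    file.path(out_dir, "classification.json"), auto_unbox = TRUE,
    digits = NA)

  anova_res <- rm_anova_two_way(loads)
  utils::write.table(anova_res$effects, file.path(out_dir, "anova.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(anova_res$posthoc,
                     file.path(out_dir, "anova_posthoc.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  adj <- adjusted_rt(ds$behavior)
  assoc <- load_rt_partial_correlation(loads, adj)
  utils::write.table(assoc, file.path(out_dir, "load_rt_association.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  jsonlite::write_json(
    list(bonferroni_family = unique(assoc$family_size),
         controls = "other two components' loads within the condition (assumed)",
         adjusted_rt = "additive subject offsets removed"),
    file.path(out_dir, "association_meta.json"), auto_unbox = TRUE)

  summary <- list(
    n_subjects = config$n_subjects,
    n_mask_voxels = sum(ds$mask),
    accuracies = as.list(accuracies),
    anova_p = setNames(as.list(anova_res$effects$p),
                       anova_res$effects$term),
    mean_load = mean(loads$load))
  jsonlite::write_json(summary, file.path(out_dir, "summary.json"),
                       auto_unbox = TRUE, digits = NA)

  invisible(list(dataset = ds, maps = maps, group_maps = group_maps,
                 loads = loads, overlaps = overlaps,
                 accuracies = accuracies, rfe = rfe, anova = anova_res,
                 associations = assoc, rdm_correlations = rdm_cors))
}

#' Read per-subject searchlight maps back from disk
#'
#' Reconstructs the nested `maps[[subject]][[condition]][[component]]`
#' structure from the NIfTI files written by [run_pipeline()] (or the
#' analysis scripts), so downstream stages can run without recomputing
#' the searchlight.
#'
#' @param map_dir directory holding `<subject>_<condition>_<component>_{z,p,sig}.nii.gz`.
#' @param subjects subject ids to read.
#' @return Nested list of `rep_map`-shaped lists (`z`, `p`, `sig`).
#' @export
read_rep_maps <- function(map_dir, subjects) {
  vol <- function(f) {
    im <- RNifti::readNifti(file.path(map_dir, f))
    array(as.vector(im), dim(im))
  }
  setNames(lapply(subjects, function(s) {
    setNames(lapply(conditions(), function(cond) {
      setNames(lapply(components(), function(comp) {
        base <- sprintf("%s_%s_%s", s, cond, comp)
        list(z = vol(paste0(base, "_z.nii.gz")),
             p = vol(paste0(base, "_p.nii.gz")),
             sig = vol(paste0(base, "_sig.nii.gz")) > 0,
             subject = s, condition = cond, component = comp)
      }), components())
    }), conditions())
  }), subjects)
}

#' Default pipeline configuration
#'
#' The study conditions the shipped analysis runs under: 20 subjects, 40
#' trials per condition on a 20x20x20 2-mm grid, 10 regions, and one
#' planted component effect per condition (logo-grapheme geometry for
#' Chinese words in region 1, phonology for English words in region 2,
#' semantics for Chinese pinyin in region 3, all at effect size 0.6),
#' with a shared logo effect for Chinese words in region 4 to give the
#' cross-language overlap stage structure.
#'
#' @param n_subjects number of subjects.
#' @param seed RNG seed.
#' @return A [sim_config()].
#' @export
default_pipeline_config <- function(n_subjects = 20L, seed = 1L) {
  sim_config(
    n_subjects = n_subjects,
    effect_map = data.frame(
      region = c(1L, 2L, 3L, 4L, 4L),
      condition = c("chinese_word", "english_word", "chinese_pinyin",
                    "chinese_word", "chinese_pinyin"),
      component = c("logo", "phonology", "semantics", "logo", "logo"),
      r = c(0.6, 0.6, 0.6, 0.5, 0.5)),
    seed = seed)
}
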