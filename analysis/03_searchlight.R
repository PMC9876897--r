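#!/usr/bin/env Rscript
# Stage 3 — searchlight RSA.
#
# For every subject, condition and voxel: the neural RDM of the 6-mm
# sphere around the voxel is correlated with each behavioral RDM,
# controlling the other two (partial Spearman, Fisher r-to-z). Voxels
# with flat responses (SD < 1/8 of |mean|) are discarded first.
# Subject-level significance: one-tailed p < 0.05 in clusters > 10
# voxels.

library(readrsa)

out <- "results/pipeline"
data_dir <- file.path(out, "data")
map_dir <- file.path(out, "maps")
dir.create(map_dir, showWarnings = FALSE)

stimuli <- read_stimuli(file.path(data_dir, "stimuli.tsv"),
                        file.path(data_dir, "embeddings.tsv"))
rdms <- behavioral_rdms(stimuli)
subjects <- sub("_beta\\.nii\\.gz$", "",
                list.files(data_dir, pattern = "_beta\\.nii\\.gz$"))
affine <- NULL
for (s in subjects) {
  bs <- read_beta_set(file.path(data_dir, paste0(s, "_beta.nii.gz")),
                      file.path(data_dir, paste0(s, "_events.tsv")),
                      file.path(data_dir, "mask.nii.gz"), subject = s)
  affine <- bs$affine
  for (cond in names(rdms)) {
    sm <- searchlight_map(bs, rdms[[cond]], cond)
    for (comp in names(sm)) {
      base <- file.path(map_dir, sprintf("%s_%s_%s", s, cond, comp))
      m <- sm[[comp]]
      write_nifti_vol(m$z, affine, paste0(base, "_z.nii.gz"))
      write_nifti_vol(m$p, affine, paste0(base, "_p.nii.gz"))
      write_nifti_vol(m$sig * 1L, affine, paste0(base, "_sig.nii.gz"))
    }
  }
  cat(s, "done\n")
}
cat("\nMaps for", length(subjects), "subjects written under",
    map_dir, "\n")
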