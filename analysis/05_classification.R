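#!/usr/bin/env Rscript
# Stage 5 — language-type classification.
#
# Leave-one-subject-out support vector regression on (region, component)
# load features, with the group significance masks rebuilt from the
# training subjects of every fold so nothing leaks from the held-out
# subject. Reports pairwise and 3-class accuracies, then the
# absence-rMSE recursive feature elimination on a unified mask with its
# knee-selected feature set.

library(readrsa)

out <- "results/pipeline"
map_dir <- file.path(out, "maps")
data_dir <- file.path(out, "data")

atlas_img <- RNifti::readNifti(file.path(data_dir, "atlas.nii.gz"))
atlas <- array(as.integer(as.vector(atlas_img)), dim(atlas_img))
subjects <- sort(unique(sub("_.*$", "",
                            list.files(map_dir, pattern = "_z\\.nii"))))
maps <- read_rep_maps(map_dir, subjects)

cat("Building fold-specific features for", length(subjects),
    "folds...\n")
fold_fms <- fold_feature_matrices(maps, atlas)

conds <- c("chinese_word", "english_word", "chinese_pinyin")
pairs <- combn(conds, 2L, simplify = FALSE)
acc <- vapply(pairs, function(pr) {
  loso_svr_foldwise(maps, atlas, pair = pr,
                    fold_features = fold_fms)$accuracy
}, 0)
names(acc) <- vapply(pairs, paste, "", collapse = "_vs_")
acc3 <- loso_svr_foldwise(maps, atlas, fold_features = fold_fms)$accuracy

cat("\nLOSO SVR accuracies:\n")
for (nm in names(acc)) cat(sprintf("  %-35s %.3f\n", nm, acc[nm]))
cat(sprintf("  %-35s %.3f\n", "three_class", acc3))

cat("\nRecursive feature elimination (unified mask)...\n")
fm <- build_features(maps, atlas)
rfe <- rfe_rank_and_select(fm)
cat("Full-model rMSE:", round(rfe$full_rmse, 3), "| knee at",
    rfe$knee, "features",
    if (rfe$has_knee) "" else "(no informative knee)", "\n")
cat("Top 5 features by absence-rMSE:\n")
print(head(sort(rfe$absence_rmse, decreasing = TRUE), 5), digits = 3)

jsonlite::write_json(
  list(accuracies = c(as.list(acc), list(three_class = acc3)),
       rfe = list(knee = rfe$knee, has_knee = rfe$has_knee,
                  full_rmse = rfe$full_rmse, ranking = rfe$ranking,
                  selected_features = rfe$selected_features,
                  curve = rfe$curve)),
  file.path(out, "classification.json"), auto_unbox = TRUE, digits = NA)
cat("\nWrote", file.path(out, "classification.json"), "\n")
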