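#!/usr/bin/env Rscript
# Stage 2 — behavioral dissimilarity matrices.
#
# Builds the three behavioral RDMs (logo-grapheme, phonology, semantics)
# for each writing system from the stimulus decompositions written by
# stage 1, and reports how strongly the three models correlate — the
# collinearity these models carry is exactly why the searchlight stage
# uses partial rather than plain rank correlations.

library(readrsa)

out <- "results/pipeline"
stimuli <- read_stimuli(file.path(out, "data", "stimuli.tsv"),
                        file.path(out, "data", "embeddings.tsv"))
cat("Read", nrow(stimuli), "stimuli,",
    length(unique(stimuli$condition)), "conditions\n")

rdms <- behavioral_rdms(stimuli)
dir.create(file.path(out, "rdms"), showWarnings = FALSE)
for (cond in names(rdms)) {
  for (comp in names(rdms[[cond]])) {
    write_rdm(rdms[[cond]][[comp]],
              file.path(out, "rdms", sprintf("%s_%s.tsv", cond, comp)))
  }
}

cors <- do.call(rbind, lapply(names(rdms), function(cond) {
  cbind(condition = cond, rdm_correlations(rdms[[cond]]))
}))
write.table(cors, file.path(out, "rdm_correlations.tsv"), sep = "\t",
            quote = FALSE, row.names = FALSE)

cat("\nModel intercorrelations (Spearman rho on 780 pairs):\n")
print(cors, digits = 3)
cat("\n9 RDMs written under", file.path(out, "rdms"), "\n")
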