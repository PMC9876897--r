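Package: readrsa
Title: Searchlight Representational Similarity Analysis of Reading Across
    Writing Systems
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for relating behavioral dissimilarity structure of reading
    stimuli (logo-grapheme, phonological, and semantic components) to
    trial-wise fMRI response patterns. Builds behavioral representational
    dissimilarity matrices from unit decompositions and word embeddings,
    computes searchlight neural dissimilarity matrices and their Fisher-z
    partial Spearman correlations with each behavioral model, performs
    subject- and group-level cluster-extent inference, summarises per-region
    cognitive load, classifies writing systems from load features with
    leave-one-subject-out support vector regression and absence-rMSE
    recursive feature elimination, and associates loads with reaction times.
    Includes a synthetic-data generator that plants representational
    geometry at controlled effect sizes so the full pipeline can be
    exercised and validated without access to raw imaging data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    RNifti,
    e1071,
    MASS,
    stringi,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
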