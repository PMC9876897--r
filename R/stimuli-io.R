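#' Read and write stimulus tables
#'
#' The stimulus TSV dialect has columns `id`, `condition`,
#' `logo_units` and `phon_units` (unit tokens joined by `|`), and
#' `embedding_ref` (row id in a separate embedding table). The embedding
#' table is a TSV whose first column is the id and remaining columns the
#' vector dimensions. Embedding vectors are consumed as inputs; the
#' word2vec training provenance (skip-gram, window 5, 300 dims) is
#' metadata of the upstream data preparation, not reproduced here.
#'
#' @param path stimulus TSV path.
#' @param embedding_path embedding table TSV path.
#' @return A stimulus data frame with list-columns `logo_units`,
#'   `phon_units`, `embedding`.
#' @export
read_stimuli <- function(path, embedding_path) {
  df <- utils::read.delim(path, colClasses = "character")
  req <- c("id", "condition", "logo_units", "phon_units", "embedding_ref")
  missing <- setdiff(req, names(df))
  if (length(missing) > 0L) {
    stop("read_stimuli: missing columns: ", paste(missing, collapse = ", "))
  }
  emb <- utils::read.delim(embedding_path)
  emb_mat <- as.matrix(emb[, -1L, drop = FALSE])
  rownames(emb_mat) <- as.character(emb[[1L]])
  unknown <- setdiff(df$embedding_ref, rownames(emb_mat))
  if (length(unknown) > 0L) {
    stop("read_stimuli: embedding_ref not in embedding table: ",
         paste(utils::head(unknown), collapse = ", "))
  }
  out <- data.frame(id = df$id, condition = df$condition,
                    stringsAsFactors = FALSE)
  out$logo_units <- strsplit(df$logo_units, "|", fixed = TRUE)
  out$phon_units <- strsplit(df$phon_units, "|", fixed = TRUE)
  out$embedding <- lapply(df$embedding_ref, function(r) unname(emb_mat[r, ]))
  out
}

#' @rdname read_stimuli
#' @param stimuli a stimulus data frame.
#' @param dir output directory; writes `stimuli.tsv` and `embeddings.tsv`.
#' @export
write_stimuli <- function(stimuli, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  df <- data.frame(
    id = stimuli$id,
    condition = stimuli$condition,
    logo_units = vapply(stimuli$logo_units, paste, "", collapse = "|"),
    phon_units = vapply(stimuli$phon_units, paste, "", collapse = "|"),
    embedding_ref = stimuli$id)
  utils::write.table(df, file.path(dir, "stimuli.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  emb <- do.call(rbind, stimuli$embedding)
  emb_df <- data.frame(id = stimuli$id, emb)
  names(emb_df) <- c("id", paste0("d", seq_len(ncol(emb))))
  utils::write.table(emb_df, file.path(dir, "embeddings.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(dir)
}
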