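#' Overlap dissimilarity between two unit multisets
#'
#' Dissimilarity between two stimuli decomposed into basic units
#' (logo-graphemes for Chinese words, letters/tone symbols for pinyin and
#' English, or phonetic units such as initials/finals/tones). Defined as
#' one minus the ratio of shared units to the summed multiset sizes:
#' `1 - s / (|a| + |b|)`, where `s` is the multiset intersection size
#' (sum over distinct tokens of the smaller count). For example a 6-unit
#' and a 5-unit word sharing 2 units give `1 - 2/11 = 0.818`.
#'
#' Tokens are compared by exact string equality after Unicode NFC
#' normalization, since decompositions arrive as text.
#'
#' @param units_a,units_b character vectors of unit tokens (multisets:
#'   repeated tokens count with multiplicity). Must be non-empty.
#' @return A single dissimilarity in `[0, 1]`; 1 iff the multisets are
#'   disjoint. Note the formula gives 0.5 (not 0) for identical multisets;
#'   RDM diagonals are forced to zero separately by convention.
#' @seealso [build_behavioral_rdm()]
#' @export
#' @examples
#' overlap_dissimilarity(c("a", "b", "c"), c("a", "d"))  # 1 - 1/5
overlap_dissimilarity <- function(units_a, units_b) {
  if (length(units_a) == 0L || length(units_b) == 0L) {
    stop("overlap_dissimilarity: unit multisets must be non-empty")
  }
  a <- stringi::stri_trans_nfc(as.character(units_a))
  b <- stringi::stri_trans_nfc(as.character(units_b))
  ta <- table(a)
  tb <- table(b)
  shared_tokens <- intersect(names(ta), names(tb))
  s <- sum(pmin(ta[shared_tokens], tb[shared_tokens]))
  1 - s / (length(a) + length(b))
}

#' Cosine dissimilarity between two embedding vectors
#'
#' One minus the cosine similarity of two semantic feature vectors
#' (e.g. word embeddings). Ranges over `[0, 2]`: 0 for identical
#' directions, 1 for orthogonal vectors, 2 for opposite directions.
#'
#' @param vec_a,vec_b numeric vectors of equal length with non-zero norm.
#' @return One minus the cosine of the angle between the vectors.
#' @export
semantic_dissimilarity <- function(vec_a, vec_b) {
  if (length(vec_a) != length(vec_b)) {
    stop("semantic_dissimilarity: vectors must have equal dimension")
  }
  na <- sqrt(sum(vec_a^2))
  nb <- sqrt(sum(vec_b^2))
  if (!is.finite(na) || !is.finite(nb) || na == 0 || nb == 0) {
    stop("semantic_dissimilarity: vectors must be finite with non-zero norm")
  }
  1 - sum(vec_a * vec_b) / (na * nb)
}

#' Construct a dissimilarity-matrix object
#'
#' @param values symmetric numeric matrix with zero diagonal.
#' @param item_ids character ids for rows/columns.
#' @param component one of `"logo"`, `"phonology"`, `"semantics"`, `"neural"`.
#' @param condition condition label (writing system) or `NA`.
#' @return A matrix of class `"rdm"` with `component` and `condition`
#'   attributes and item ids as dimnames.
#' @export
rdm <- function(values, item_ids = rownames(values),
                component = c("logo", "phonology", "semantics", "neural"),
                condition = NA_character_) {
  component <- match.arg(component)
  values <- as.matrix(values)
  stopifnot(nrow(values) == ncol(values))
  if (is.null(item_ids)) item_ids <- as.character(seq_len(nrow(values)))
  dimnames(values) <- list(item_ids, item_ids)
  if (max(abs(values - t(values)), na.rm = TRUE) > 1e-10) {
    stop("rdm: values must be symmetric")
  }
  diag(values) <- 0
  structure(values, class = c("rdm", "matrix", "array"),
            component = component, condition = condition)
}

#' Lower-triangle vector of an RDM
#'
#' Vectorizes the `n(n-1)/2` unique off-diagonal dissimilarities in
#' column-major lower-triangle order; all pairwise RDM comparisons in the
#' pipeline operate on this vector.
#'
#' @param x an `rdm` or square matrix.
#' @return Numeric vector of length `n(n-1)/2`.
#' @export
rdm_vec <- function(x) {
  x <- unclass(as.matrix(x))
  x[lower.tri(x)]
}

# condition labels used throughout
conditions <- function() c("chinese_word", "english_word", "chinese_pinyin")
components <- function() c("logo", "phonology", "semantics")

#' Build one behavioral RDM for one writing system
#'
#' Assembles the n-by-n dissimilarity matrix over the stimuli of a single
#' condition for one linguistic component: `"logo"` uses
#' [overlap_dissimilarity()] on logo-grapheme units, `"phonology"` the same
#' formula on phonetic units, and `"semantics"`
#' [semantic_dissimilarity()] on embedding vectors. RDMs are per writing
#' system: mixing conditions is an error.
#'
#' @param stimuli a stimulus table as returned by [generate_stimuli()] or
#'   [read_stimuli()]: columns `id`, `condition`, list-columns `logo_units`,
#'   `phon_units`, `embedding`.
#' @param component `"logo"`, `"phonology"` or `"semantics"`.
#' @param condition optional condition to subset to; if `NULL` the input
#'   must already be single-condition.
#' @return An [rdm()] with items in stable id order of the input.
#' @export
build_behavioral_rdm <- function(stimuli,
                                 component = c("logo", "phonology", "semantics"),
                                 condition = NULL) {
  component <- match.arg(component)
  if (!is.null(condition)) {
    stimuli <- stimuli[stimuli$condition == condition, , drop = FALSE]
    if (nrow(stimuli) == 0L) {
      stop("build_behavioral_rdm: no stimuli with condition '", condition, "'")
    }
  }
  cond <- unique(stimuli$condition)
  if (length(cond) != 1L) {
    stop("build_behavioral_rdm: stimuli span multiple conditions (",
         paste(cond, collapse = ", "), "); RDMs are per writing system")
  }
  n <- nrow(stimuli)
  if (n < 2L) stop("build_behavioral_rdm: need at least 2 stimuli")
  feats <- switch(component,
                  logo = stimuli$logo_units,
                  phonology = stimuli$phon_units,
                  semantics = stimuli$embedding)
  dfun <- if (component == "semantics") semantic_dissimilarity else
    overlap_dissimilarity
  v <- matrix(0, n, n)
  for (i in seq_len(n - 1L)) {
    for (j in (i + 1L):n) {
      v[i, j] <- v[j, i] <- dfun(feats[[i]], feats[[j]])
    }
  }
  rdm(v, item_ids = stimuli$id, component = component, condition = cond)
}

#' All nine behavioral RDMs of a stimulus set
#'
#' Convenience wrapper producing one RDM per (condition, component) cell.
#'
#' @param stimuli full stimulus table covering the three conditions.
#' @return Nested list `rdms[[condition]][[component]]`.
#' @export
behavioral_rdms <- function(stimuli) {
  out <- lapply(conditions(), function(cond) {
    setNames(lapply(components(), function(comp) {
      build_behavioral_rdm(stimuli, comp, cond)
    }), components())
  })
  setNames(out, conditions())
}

#' Pairwise Spearman correlations among RDMs
#'
#' Spearman rank correlation between the lower-triangle vectors of every
#' pair of RDMs, with two-sided p-values. Used to characterise how
#' collinear the behavioral models are before they serve as mutual
#' controls in the partial-correlation searchlight.
#'
#' @param rdms named list of [rdm()] objects with identical item order.
#' @return Data frame with columns `rdm_a`, `rdm_b`, `rho`, `p`. A
#'   zero-variance RDM yields `NA` with a warning.
#' @export
rdm_correlations <- function(rdms) {
  if (is.null(names(rdms))) names(rdms) <- paste0("rdm", seq_along(rdms))
  vecs <- lapply(rdms, rdm_vec)
  m <- lengths(vecs)
  if (length(unique(m)) != 1L) {
    stop("rdm_correlations: RDMs must have identical size")
  }
  pairs <- utils::combn(names(rdms), 2L)
  res <- apply(pairs, 2L, function(pr) {
    x <- vecs[[pr[1L]]]; y <- vecs[[pr[2L]]]
    if (stats::sd(x) == 0 || stats::sd(y) == 0) {
      warning("rdm_correlations: zero-variance RDM (", pr[1L], " vs ",
              pr[2L], "); correlation undefined")
      return(c(NA_real_, NA_real_))
    }
    ct <- suppressWarnings(
      stats::cor.test(x, y, method = "spearman", exact = FALSE))
    c(unname(ct$estimate), ct$p.value)
  })
  data.frame(rdm_a = pairs[1L, ], rdm_b = pairs[2L, ],
             rho = res[1L, ], p = res[2L, ], row.names = NULL)
}

#' Write / read an RDM as square TSV
#'
#' Square tab-separated layout with item ids as header row and first
#' column, the on-disk interchange format for all RDMs.
#'
#' @param x an [rdm()].
#' @param path file path.
#' @export
write_rdm <- function(x, path) {
  df <- data.frame(id = rownames(x), unclass(as.matrix(x)),
                   check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_rdm
#' @param component,condition metadata restored on read.
#' @export
read_rdm <- function(path, component = "neural", condition = NA_character_) {
  df <- utils::read.delim(path, check.names = FALSE)
  m <- as.matrix(df[, -1L, drop = FALSE])
  rownames(m) <- df[[1L]]
  rdm(m, component = component, condition = condition)
}
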