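# word tokens of >= 2 characters, lowercased
tfidf_tokenize <- function(text) {
  m <- gregexpr("\\b\\w\\w+\\b", tolower(text), perl = TRUE)
  regmatches(tolower(text), m)
}

#' Fit a TF-IDF model on a cohort
#'
#' Documents are the concatenation of the selected text fields (all six by
#' default, for parity with the flag featurizer; narrative-only is a
#' config choice). Uses the smoothed inverse-document-frequency dialect
#' `idf(t) = ln((1 + N) / (1 + df(t))) + 1`, and drops terms with document
#' frequency below `min_df`.
#'
#' @param cohort an `ems_cohort`.
#' @param fields text fields to concatenate.
#' @param min_df minimum document frequency for a term to enter the
#'   vocabulary.
#' @return A `tfidf_model` with `vocabulary`, `idf`, `doc_count`, `params`.
#' @export
fit_tfidf <- function(cohort, fields = ems_text_fields(), min_df = 1L) {
  stopifnot(min_df >= 1L)
  docs <- do.call(paste, c(lapply(fields, function(f) cohort[[f]]), sep = " "))
  if (!any(nzchar(trimws(docs)))) stop("empty corpus: no non-empty documents")
  toks <- tfidf_tokenize(docs)
  df_counts <- table(unlist(lapply(toks, unique)))
  keep <- names(df_counts)[df_counts >= min_df]
  vocab <- sort(keep)
  n_docs <- length(docs)
  idf <- log((1 + n_docs) / (1 + as.numeric(df_counts[vocab]))) + 1
  structure(list(vocabulary = stats::setNames(seq_along(vocab), vocab),
                 idf = stats::setNames(idf, vocab),
                 doc_count = n_docs,
                 params = list(lowercase = TRUE, token_pattern = "\\b\\w\\w+\\b",
                               min_df = as.integer(min_df), norm = "l2",
                               fields = fields)),
            class = "tfidf_model")
}

#' @export
print.tfidf_model <- function(x, ...) {
  cat(sprintf("tfidf_model: %d terms over %d documents (min_df = %d, fields: %s)\n",
              length(x$vocabulary), x$doc_count, x$params$min_df,
              paste(x$params$fields, collapse = ", ")))
  invisible(x)
}

#' Transform a cohort with a fitted TF-IDF model
#'
#' Row vectors are `tf * idf` with the training idf (so test-set rows use
#' training document frequencies), L2-normalized unless identically zero.
#' Out-of-vocabulary terms are ignored.
#'
#' @param model a [fit_tfidf()] model.
#' @param cohort an `ems_cohort`.
#' @return Numeric matrix, rows named by `record_id`, columns `tf_<term>`.
#' @export
transform_tfidf <- function(model, cohort) {
  stopifnot(inherits(model, "tfidf_model"))
  docs <- do.call(paste, c(lapply(model$params$fields, function(f) cohort[[f]]),
                           sep = " "))
  toks <- tfidf_tokenize(docs)
  vocab <- names(model$vocabulary)
  mat <- matrix(0, nrow = length(docs), ncol = length(vocab),
                dimnames = list(cohort$record_id, paste0("tf_", vocab)))
  for (i in seq_along(toks)) {
    tt <- toks[[i]][toks[[i]] %in% vocab]
    if (!length(tt)) next
    tf <- table(tt)
    mat[i, paste0("tf_", names(tf))] <- as.numeric(tf) * model$idf[names(tf)]
    nrm <- sqrt(sum(mat[i, ]^2))
    if (nrm > 0) mat[i, ] <- mat[i, ] / nrm
  }
  mat
}

#' Construct a concept lexicon
#'
#' Maps lowercase-normalized surface strings (multi-word allowed) to
#' concept identifiers, standing in for a UMLS-style surface-to-CUI map.
#'
#' @param surfaces character vector of surface forms.
#' @param concept_ids parallel vector of concept ids.
#' @return A `concept_lexicon`.
#' @export
concept_lexicon <- function(surfaces, concept_ids) {
  stopifnot(length(surfaces) == length(concept_ids), length(surfaces) > 0)
  surfaces <- tolower(trimws(surfaces))
  if (anyDuplicated(surfaces)) stop("lexicon surfaces must be unique")
  structure(list(map = stats::setNames(as.character(concept_ids), surfaces)),
            class = "concept_lexicon")
}

#' Construct a concept embedding table
#' @param vectors numeric matrix with one row per concept, rownames =
#'   concept ids.
#' @return An `embedding_table`.
#' @export
embedding_table <- function(vectors) {
  vectors <- as.matrix(vectors)
  if (!nrow(vectors)) stop("empty embedding table")
  if (is.null(rownames(vectors))) stop("embedding table needs concept-id rownames")
  if (!all(is.finite(vectors))) stop("embedding table entries must be finite")
  structure(list(vectors = vectors, dimension = ncol(vectors)),
            class = "embedding_table")
}

#' Read a lexicon from TSV (surface <TAB> concept-id)
#' @param path file path.
#' @return A [concept_lexicon()].
#' @export
read_lexicon <- function(path) {
  df <- utils::read.delim(path, header = FALSE, colClasses = "character",
                          col.names = c("surface", "concept_id"))
  concept_lexicon(df$surface, df$concept_id)
}

#' Read an embedding table from TSV (concept-id, then d floats)
#' @param path file path.
#' @return An [embedding_table()].
#' @export
read_embeddings <- function(path) {
  df <- utils::read.delim(path, header = FALSE)
  mat <- as.matrix(df[, -1, drop = FALSE])
  rownames(mat) <- as.character(df[[1]])
  colnames(mat) <- NULL
  embedding_table(mat)
}

#' Extract concept ids from a text
#'
#' Case-insensitive, longest-match-first, non-overlapping left-to-right
#' scan against the lexicon's surfaces (word-boundary aware). Duplicate
#' matches are preserved in order.
#'
#' @param text a single string.
#' @param lexicon a [concept_lexicon()].
#' @return Character vector of concept ids (possibly empty).
#' @export
extract_concepts <- function(text, lexicon) {
  stopifnot(inherits(lexicon, "concept_lexicon"))
  if (is.na(text) || !nzchar(text)) return(character())
  surf <- names(lexicon$map)
  esc <- gsub("([][{}()+*^$|\\\\?.])", "\\\\\\1", surf)
  esc <- gsub("\\s+", "\\\\s+", esc)
  ord <- order(-nchar(surf), seq_along(surf))
  pat <- paste0("\\b(?:", paste(paste0(esc[ord], "\\b"), collapse = "|"), ")")
  m <- gregexpr(pat, text, ignore.case = TRUE, perl = TRUE)[[1]]
  if (m[1] == -1L) return(character())
  hits <- tolower(gsub("\\s+", " ", regmatches(text, list(m))[[1]]))
  unname(lexicon$map[hits])
}

#' Concept-embedding vectorization of chief narratives
#'
#' For each record, matches lexicon surfaces in the chief narrative only
#' (the field intended as a complete encounter summary) and averages the
#' matched concepts' embedding vectors with multiplicity. Records with no
#' match get a zero vector; concepts absent from the table are skipped and
#' their total count reported in a message.
#'
#' @param cohort an `ems_cohort`.
#' @param lexicon a [concept_lexicon()].
#' @param embeddings an [embedding_table()].
#' @return Numeric matrix (n x dimension), rows named by `record_id`,
#'   columns `cv_1..cv_d`.
#' @export
vectorize_narrative <- function(cohort, lexicon, embeddings) {
  stopifnot(inherits(embeddings, "embedding_table"))
  d <- embeddings$dimension
  mat <- matrix(0, nrow = nrow(cohort), ncol = d,
                dimnames = list(cohort$record_id, paste0("cv_", seq_len(d))))
  n_skipped <- 0L
  known <- rownames(embeddings$vectors)
  for (i in seq_len(nrow(cohort))) {
    ids <- extract_concepts(cohort$chief_narrative[i], lexicon)
    miss <- !(ids %in% known)
    n_skipped <- n_skipped + sum(miss)
    ids <- ids[!miss]
    if (length(ids)) {
      mat[i, ] <- colMeans(embeddings$vectors[ids, , drop = FALSE])
    }
  }
  if (n_skipped > 0) {
    message(sprintf("vectorize_narrative: skipped %d concept mention(s) absent from the embedding table",
                    n_skipped))
  }
  mat
}

#' Synthetic concept lexicon and embedding table
#'
#' A small, deterministic stand-in for a clinical concept model: every
#' curated keyword plus common clinical filler words maps to a synthetic
#' concept id, and each concept gets a fixed random Gaussian vector. Only
#' meant to exercise the concept-vectorization pathway on synthetic
#' cohorts; it carries no real clinical semantics.
#'
#' @param dimension embedding dimension.
#' @return `list(lexicon = , embeddings = )`.
#' @export
synthetic_concept_resources <- function(dimension = 20L) {
  ts <- default_term_sets()
  surfaces <- unique(c(ts$opioid$terms, ts$overdose$terms,
                       default_filler_vocab(), behavioral_health_vocab(),
                       "unknown pain pills"))
  ids <- sprintf("C%07d", seq_along(surfaces))
  lex <- concept_lexicon(surfaces, ids)
  vecs <- with_rng(424243L, {
    matrix(stats::rnorm(length(ids) * dimension), nrow = length(ids),
           dimnames = list(ids, NULL))
  })
  list(lexicon = lex, embeddings = embedding_table(vecs))
}
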