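#' Define a keyword term set
#'
#' A named list of keywords with its matching policy. Terms are normalized
#' to lowercase and de-duplicated; multi-word terms are allowed and match
#' across any single run of whitespace. Every term requires a word boundary
#' on both sides except `prefix_terms`, which require only a left boundary
#' (so `"intox"` also matches "intoxicated" and "intoxication"). Word
#' boundaries treat numerals as word characters, so "Tylenol 3" is bounded
#' on both sides.
#'
#' @param name set name, used in feature column names.
#' @param terms character vector of keywords.
#' @param prefix_terms subset of `terms` matched as left-anchored prefixes.
#' @return A `term_set` object.
#' @export
term_set <- function(name, terms, prefix_terms = character()) {
  stopifnot(is.character(name), length(name) == 1L, nzchar(name))
  if (!length(terms)) stop("terms must be non-empty")
  terms <- unique(tolower(trimws(terms)))
  prefix_terms <- unique(tolower(trimws(prefix_terms)))
  if (!all(prefix_terms %in% terms)) {
    stop("prefix_terms must be a subset of terms")
  }
  structure(list(name = name, terms = terms, prefix_terms = prefix_terms,
                 boundary_policy = "word_boundaries"),
            class = "term_set")
}

#' @export
print.term_set <- function(x, ...) {
  cat(sprintf("term_set '%s': %d terms", x$name, length(x$terms)))
  if (length(x$prefix_terms)) {
    cat(sprintf(" (prefix-matched: %s)", paste(x$prefix_terms, collapse = ", ")))
  }
  cat("\n  ", paste(x$terms, collapse = ", "), "\n")
  invisible(x)
}

#' The curated opioid and overdose term sets
#'
#' The empirically identified keyword lists used for flag featurization:
#' 18 opioid terms (including, verbatim, "crack" and "cocaine" — kept for
#' fidelity to the curated list despite being pharmacologically
#' non-opioid) and 7 overdose terms, with `"intox"` matched as a prefix.
#'
#' @return Named list with `opioid` and `overdose` [term_set()] objects.
#' @export
default_term_sets <- function() {
  list(
    opioid = term_set("opioid", c(
      "opioid", "opiate", "Narcan", "naloxone", "heroin", "methadone",
      "fentanyl", "Percocet", "oxycontin", "oxycodone", "Vicodin",
      "morphine", "crack", "cocaine", "Tylenol 3", "codeine", "oxy",
      "tramadol")),
    overdose = term_set("overdose", c(
      "ingestion", "substance", "abuse", "intox", "poisoning", "OD",
      "overdose"), prefix_terms = "intox")
  )
}

# Compile a term set to a single PCRE alternation. Alternatives are ordered
# longest-first so that at any position the longest term wins ("oxycodone"
# before "oxy"); gregexpr's non-overlapping scan then guarantees each text
# position feeds at most one term.
term_set_regex <- function(ts) {
  esc <- gsub("([][{}()+*^$|\\\\?.])", "\\\\\\1", ts$terms)
  esc <- gsub("\\s+", "\\\\s+", esc)
  alt <- ifelse(ts$terms %in% ts$prefix_terms, esc, paste0(esc, "\\b"))
  ord <- order(-nchar(ts$terms), seq_along(ts$terms))
  paste0("\\b(?:", paste(alt[ord], collapse = "|"), ")")
}

#' Count keyword matches in a text
#'
#' Case-insensitive, boundary-aware, non-overlapping count of a term set's
#' keywords summed over terms. Prefix terms need only a left boundary;
#' everything else needs both ("OD" does not fire inside "body"). Nested
#' terms are resolved longest-first, so "oxycodone" counts once, not as
#' "oxy" plus a remainder.
#'
#' @param text character vector (empty strings allowed).
#' @param ts a [term_set()].
#' @return Integer vector of match counts, one per element of `text`.
#' @export
count_term_matches <- function(text, ts) {
  stopifnot(inherits(ts, "term_set"))
  text <- as.character(text)
  out <- integer(length(text))
  nz <- which(!is.na(text) & nzchar(text))
  if (length(nz)) {
    m <- gregexpr(term_set_regex(ts), text[nz], ignore.case = TRUE, perl = TRUE)
    out[nz] <- vapply(m, function(mi) if (mi[1] == -1L) 0L else length(mi), integer(1))
  }
  out
}

#' Flag featurization of a cohort
#'
#' One integer column per (term set x field) pair, named
#' `"<set>__<field>"`: with the default sets and all six text fields this
#' is the 12-column flags feature matrix. Empty fields contribute zero.
#'
#' @param cohort an `ems_cohort`.
#' @param term_sets list of [term_set()] objects (default: the curated
#'   opioid and overdose sets).
#' @param fields text fields to count over; subset of [ems_text_fields()].
#' @return Numeric matrix, rows named by `record_id`.
#' @export
featurize_flags <- function(cohort, term_sets = default_term_sets(),
                            fields = ems_text_fields()) {
  unknown <- setdiff(fields, ems_text_fields())
  if (length(unknown)) {
    stop(sprintf("unknown field name(s): %s", paste(unknown, collapse = ", ")))
  }
  stopifnot(length(term_sets) >= 1)
  cols <- list()
  for (ts in term_sets) {
    for (f in fields) {
      cols[[paste0(ts$name, "__", f)]] <- count_term_matches(cohort[[f]], ts)
    }
  }
  mat <- do.call(cbind, cols)
  rownames(mat) <- cohort$record_id
  storage.mode(mat) <- "double"
  mat
}

#' Load term sets from a YAML file
#'
#' The file is a list of entries with keys `name`, `terms`, and optional
#' `prefix_terms`, allowing the curated lists to be overridden without
#' code changes.
#'
#' @param path YAML file path.
#' @return Named list of [term_set()] objects.
#' @export
read_term_sets <- function(path) {
  raw <- yaml::read_yaml(path)
  out <- lapply(raw, function(e) {
    term_set(e$name, unlist(e$terms), unlist(e$prefix_terms) %||% character())
  })
  stats::setNames(out, vapply(out, function(ts) ts$name, character(1)))
}

#' Write term sets to a YAML file
#' @param term_sets named list of [term_set()] objects.
#' @param path output path.
#' @export
write_term_sets <- function(term_sets, path) {
  yaml::write_yaml(lapply(unname(term_sets), function(ts) {
    list(name = ts$name, terms = as.list(ts$terms),
         prefix_terms = as.list(ts$prefix_terms))
  }), path)
  invisible(path)
}
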