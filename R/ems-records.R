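#' The six narrative fields of an EMS encounter record
#'
#' Call nature (the 9-1-1 dispatcher's description), primary impression (the
#' on-scene provider's broad assessment), chief complaint, chief narrative
#' (the responder's free-text summary of the whole encounter), medication
#' list, and medical history. These are the minimum fields subject-matter
#' experts consider sufficient to classify an encounter as an overdose, and
#' the fields all featurizers in this package operate on.
#'
#' @return Character vector of the six canonical field names.
#' @export
ems_text_fields <- function() {
  c("call_nature", "primary_impression", "chief_complaint",
    "chief_narrative", "medication_list", "medical_history")
}

ems_core_columns <- function() {
  c("record_id", "county", ems_text_fields(),
    "ethnicity", "gender", "age", "label", "phase")
}

#' Construct an EMS cohort from a data frame
#'
#' An `ems_cohort` is a data frame with one row per encounter and the
#' canonical column set (`record_id`, `county`, the six text fields,
#' `ethnicity`, `gender`, `age`, `label`, `phase`). Missing text fields are
#' filled with empty strings, never dropped: downstream featurizers then
#' yield zero counts for them. Labels are a three-state value
#' (`"positive"`, `"negative"`, `NA` = unlabeled) so an unscored annotation
#' pool can be represented. Extra columns are preserved as pass-through
#' metadata.
#'
#' @param df data frame containing at least a `record_id` column.
#' @param provenance free-text descriptor of where the records came from.
#' @return An `ems_cohort` (a classed data frame).
#' @export
as_cohort <- function(df, provenance = "unspecified") {
  df <- as.data.frame(df, stringsAsFactors = FALSE)
  if (!"record_id" %in% names(df)) stop("cohort input must contain a 'record_id' column")
  df$record_id <- as.character(df$record_id)
  dup <- df$record_id[duplicated(df$record_id)]
  if (length(dup)) {
    stop(sprintf("duplicate record_id in cohort: %s", paste(unique(dup), collapse = ", ")))
  }
  missing_text <- character()
  for (f in ems_text_fields()) {
    if (!f %in% names(df)) {
      df[[f]] <- rep("", nrow(df))
    } else {
      v <- as.character(df[[f]])
      if (anyNA(v)) missing_text <- c(missing_text, f)
      v[is.na(v)] <- ""
      df[[f]] <- v
    }
  }
  if (length(missing_text)) {
    warning(sprintf("missing text values filled with empty strings in: %s",
                    paste(unique(missing_text), collapse = ", ")))
  }
  for (f in c("county", "ethnicity", "gender", "phase")) {
    if (!f %in% names(df)) {
      df[[f]] <- rep(NA_character_, nrow(df))
    } else {
      v <- as.character(df[[f]])
      v[!is.na(v) & v == ""] <- NA_character_
      df[[f]] <- v
    }
  }
  if (!"age" %in% names(df)) df$age <- rep(NA_real_, nrow(df))
  df$age <- suppressWarnings(as.numeric(ifelse(df$age %in% c("", "NA"), NA, df$age)))
  bad_age <- which(!is.na(df$age) & (df$age < 0 | df$age > 130))
  if (length(bad_age)) {
    stop(sprintf("age out of [0, 130] at row(s): %s", paste(bad_age, collapse = ", ")))
  }
  if (!"label" %in% names(df)) df$label <- rep(NA_character_, nrow(df))
  df$label <- parse_labels(df$label)
  df <- df[c(ems_core_columns(), setdiff(names(df), ems_core_columns()))]
  rownames(df) <- NULL
  attr(df, "provenance") <- provenance
  class(df) <- c("ems_cohort", "data.frame")
  df
}

# Parse the label dialects seen in EMS exports: {0,1}, {true,false},
# {OOD, Non-OOD}, {positive,negative}; blank/NA means unlabeled.
parse_labels <- function(x) {
  x_chr <- tolower(trimws(as.character(x)))
  out <- rep(NA_character_, length(x_chr))
  pos <- c("1", "true", "ood", "positive", "pos", "yes")
  neg <- c("0", "false", "non-ood", "negative", "neg", "no")
  out[x_chr %in% pos] <- "positive"
  out[x_chr %in% neg] <- "negative"
  unk <- !(x_chr %in% c(pos, neg, "", "na", "unlabeled")) & !is.na(x_chr)
  if (any(unk)) {
    stop(sprintf("unparseable label value %s at row %d",
                 dQuote(as.character(x)[which(unk)[1]]), which(unk)[1]))
  }
  out
}

#' Read EMS encounter records from CSV or JSON-lines
#'
#' Both formats carry the canonical column names; unknown columns are kept
#' as pass-through metadata. Duplicated `record_id`s and unparseable label
#' values are hard errors; absent text values become empty strings with a
#' warning. Row order is preserved.
#'
#' @param path file path.
#' @param format `"csv"` (RFC-4180, header row) or `"jsonl"` (one JSON
#'   object per line). Defaults from the file extension.
#' @return An [as_cohort()] object.
#' @export
read_encounters <- function(path, format = c("auto", "csv", "jsonl")) {
  format <- match.arg(format)
  if (!file.exists(path)) stop(sprintf("file not found: %s", path))
  if (format == "auto") {
    format <- if (grepl("\\.jsonl$|\\.ndjson$", path)) "jsonl" else "csv"
  }
  if (format == "csv") {
    df <- utils::read.csv(path, colClasses = "character", check.names = FALSE,
                          fileEncoding = "UTF-8")
    # empty text cells are absent values; as_cohort logs and maps them to ""
    for (f in intersect(ems_text_fields(), names(df))) {
      df[[f]][df[[f]] == ""] <- NA_character_
    }
  } else {
    lines <- readLines(path, encoding = "UTF-8")
    lines <- lines[nzchar(trimws(lines))]
    rows <- lapply(lines, function(l) jsonlite::fromJSON(l, simplifyVector = TRUE))
    keys <- unique(unlist(lapply(rows, names)))
    df <- as.data.frame(
      stats::setNames(lapply(keys, function(k) {
        vapply(rows, function(r) {
          v <- r[[k]]
          if (is.null(v) || length(v) == 0 || is.na(v[1])) NA_character_ else as.character(v[1])
        }, character(1))
      }), keys),
      stringsAsFactors = FALSE, check.names = FALSE)
  }
  as_cohort(df, provenance = path)
}

#' Write an EMS cohort to CSV or JSON-lines
#'
#' Output round-trips losslessly through [read_encounters()]: row order,
#' labels and empty text fields are preserved, and the byte stream is a
#' deterministic function of the cohort.
#'
#' @param cohort an `ems_cohort`.
#' @param path output path.
#' @param format `"csv"` or `"jsonl"`.
#' @export
write_encounters <- function(cohort, path, format = c("auto", "csv", "jsonl")) {
  format <- match.arg(format)
  if (format == "auto") {
    format <- if (grepl("\\.jsonl$|\\.ndjson$", path)) "jsonl" else "csv"
  }
  df <- as.data.frame(cohort)
  if (format == "csv") {
    utils::write.csv(df, path, row.names = FALSE, na = "", fileEncoding = "UTF-8",
                     quote = TRUE)
  } else {
    con <- file(path, open = "wt", encoding = "UTF-8")
    on.exit(close(con))
    for (i in seq_len(nrow(df))) {
      row <- as.list(df[i, , drop = FALSE])
      writeLines(jsonlite::toJSON(row, auto_unbox = TRUE, na = "null", digits = NA), con)
    }
  }
  invisible(path)
}

#' Summarize an EMS cohort
#'
#' Totals, per-county counts, positive count, and among labeled positives
#' the ethnicity and gender shares (unrounded, with a 1-decimal display
#' value) plus the positives' age range and mean. Unlabeled records are
#' excluded from positive shares. An empty cohort yields a summary of
#' zeros, not an error.
#'
#' @param cohort an `ems_cohort`.
#' @return A `cohort_summary` list.
#' @export
summarize_cohort <- function(cohort) {
  n_total <- nrow(cohort)
  county <- cohort$county
  n_by_county <- if (n_total) table(factor(ifelse(is.na(county), "unknown", county))) else table(character())
  n_by_county <- stats::setNames(as.integer(n_by_county), names(n_by_county))
  pos <- !is.na(cohort$label) & cohort$label == "positive"
  n_positive <- sum(pos)
  share_tab <- function(v) {
    if (!n_positive) {
      return(data.frame(category = character(), count = integer(),
                        percent = numeric(), percent_display = numeric(),
                        stringsAsFactors = FALSE))
    }
    v <- v[pos]
    v[is.na(v) | v == ""] <- "unknown or unassigned"
    tb <- sort(table(v), decreasing = TRUE)
    data.frame(category = names(tb),
               count = as.integer(tb),
               percent = 100 * as.integer(tb) / n_positive,
               percent_display = round(100 * as.integer(tb) / n_positive, 1),
               stringsAsFactors = FALSE)
  }
  ages <- cohort$age[pos]
  ages <- ages[!is.na(ages)]
  out <- list(
    n_total = n_total,
    n_by_county = n_by_county,
    n_positive = n_positive,
    positive_share_by_ethnicity = share_tab(cohort$ethnicity),
    positive_share_by_gender = share_tab(cohort$gender),
    age_range = if (length(ages)) range(ages) else c(NA_real_, NA_real_),
    mean_age = if (length(ages)) mean(ages) else NA_real_
  )
  class(out) <- "cohort_summary"
  out
}

#' @export
print.cohort_summary <- function(x, ...) {
  cat(sprintf("EMS cohort summary: %d records, %d labeled positive\n",
              x$n_total, x$n_positive))
  if (length(x$n_by_county)) {
    cat("  by county:",
        paste(sprintf("%s=%d", names(x$n_by_county), x$n_by_county), collapse = ", "),
        "\n")
  }
  if (nrow(x$positive_share_by_ethnicity)) {
    cat("  positive share by ethnicity:\n")
    e <- x$positive_share_by_ethnicity
    for (i in seq_len(nrow(e))) {
      cat(sprintf("    %-24s %4d (%.1f%%)\n", e$category[i], e$count[i], e$percent_display[i]))
    }
  }
  if (nrow(x$positive_share_by_gender)) {
    g <- x$positive_share_by_gender
    cat("  positive share by gender:",
        paste(sprintf("%s %d (%.1f%%)", g$category, g$count, g$percent_display), collapse = ", "),
        "\n")
  }
  if (!is.na(x$mean_age)) {
    cat(sprintf("  positives' age: %g-%g, mean %.2f\n",
                x$age_range[1], x$age_range[2], x$mean_age))
  }
  invisible(x)
}

#' Split a cohort into train and test partitions
#'
#' The partition is exact (disjoint, union equals the input) and
#' deterministic for a fixed seed. With `stratify_on_label = TRUE` the test
#' side takes `round(test_fraction * stratum size)` records from each label
#' stratum (half-up), with any remainder against the half-up overall target
#' resolved in the largest stratum — so the class balance of the held-out
#' set matches the cohort.
#'
#' @param cohort an `ems_cohort`.
#' @param test_fraction proportion in (0, 1) reserved for testing.
#' @param seed integer RNG seed.
#' @param stratify_on_label stratify the draw on the binary label.
#' @return `list(train = , test = )` of `ems_cohort`s, original row order
#'   preserved within each side.
#' @export
split_train_test <- function(cohort, test_fraction, seed, stratify_on_label = FALSE) {
  stopifnot(is.numeric(test_fraction), test_fraction > 0, test_fraction < 1)
  n <- nrow(cohort)
  if (stratify_on_label) {
    lab <- cohort$label
    if (all(is.na(lab))) stop("stratified split requested on a fully unlabeled cohort")
    strata <- split(seq_len(n), factor(ifelse(is.na(lab), "unlabeled", lab)))
  } else {
    strata <- list(all = seq_len(n))
  }
  sizes <- vapply(strata, length, integer(1))
  take <- round_half_up(test_fraction * sizes)
  target <- round_half_up(test_fraction * n)
  diff <- target - sum(take)
  if (diff != 0) {
    big <- which.max(sizes)
    take[big] <- min(max(take[big] + diff, 0L), sizes[big])
  }
  test_idx <- integer()
  with_rng(seed, {
    for (s in seq_along(strata)) {
      idx <- strata[[s]]
      test_idx <- c(test_idx, if (take[s] > 0) sample(idx, take[s]) else integer())
    }
  })
  test_idx <- sort(test_idx)
  train_idx <- setdiff(seq_len(n), test_idx)
  subset_cohort <- function(idx) {
    out <- cohort[idx, , drop = FALSE]
    rownames(out) <- NULL
    attr(out, "provenance") <- attr(cohort, "provenance")
    class(out) <- class(cohort)
    out
  }
  list(train = subset_cohort(train_idx), test = subset_cohort(test_idx))
}

#' Write an analysis report as JSON
#'
#' Stable key order (insertion order of the R object), `NaN`/`NA` written
#' as `null`, numbers at full precision so a report is a byte-deterministic
#' function of its inputs.
#'
#' @param report any list-like report object.
#' @param path output path.
#' @export
write_report <- function(report, path) {
  dir.create(dirname(path), recursive = TRUE, showWarnings = FALSE)
  json <- jsonlite::toJSON(report_sanitize(report), auto_unbox = TRUE,
                           na = "null", null = "null", digits = NA, pretty = TRUE)
  writeLines(json, path, useBytes = TRUE)
  invisible(path)
}

#' Read a JSON report written by [write_report()]
#' @param path file path.
#' @return The parsed report (lists and vectors; `null` becomes `NA`).
#' @export
read_report <- function(path) {
  jsonlite::fromJSON(path, simplifyVector = TRUE)
}

# strip classes/attributes that do not serialize; keep structure and names
report_sanitize <- function(x) {
  if (is.function(x)) return(NULL)
  if (is.data.frame(x)) return(as.data.frame(lapply(x, unclass), stringsAsFactors = FALSE))
  if (is.list(x)) {
    x <- unclass(x)
    return(lapply(x, report_sanitize))
  }
  if (is.table(x)) x <- stats::setNames(as.integer(x), names(x))
  if (is.atomic(x) && !is.null(names(x))) return(as.list(x))  # keep names in JSON
  x
}
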