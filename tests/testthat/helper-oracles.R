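# Independent oracles: deliberately different machinery from the package
# implementations (character-level scanning instead of PCRE, all-pairs
# loops instead of midranks, aov() instead of closed-form mean squares).

# character-level keyword scanner: longest-match-first, non-overlapping,
# boundary-aware, case-insensitive; spaces in terms match whitespace runs
oracle_count_terms <- function(text, ts) {
  chars <- strsplit(tolower(text), "")[[1]]
  n <- length(chars)
  if (!n) return(0L)
  is_word <- grepl("[a-z0-9_]", chars)
  terms <- ts$terms[order(-nchar(ts$terms))]
  # try to match term at position i; return chars consumed, or 0
  try_at <- function(i, term) {
    tch <- strsplit(term, "")[[1]]
    pos <- i
    for (tc in tch) {
      if (tc == " ") {
        if (pos > n || !grepl("\\s", chars[pos])) return(0L)
        while (pos <= n && grepl("\\s", chars[pos])) pos <- pos + 1L
      } else {
        if (pos > n || chars[pos] != tc) return(0L)
        pos <- pos + 1L
      }
    }
    pos - i
  }
  count <- 0L
  i <- 1L
  while (i <= n) {
    left_ok <- is_word[i] && (i == 1L || !is_word[i - 1L])
    if (left_ok) {
      adv <- 0L
      for (term in terms) {
        len <- try_at(i, term)
        if (len > 0L) {
          end <- i + len - 1L
          right_ok <- term %in% ts$prefix_terms || end == n || !is_word[end + 1L]
          if (right_ok) { adv <- len; break }
        }
      }
      if (adv > 0L) { count <- count + 1L; i <- i + adv; next }
    }
    i <- i + 1L
  }
  count
}

# all-pairs Mann-Whitney AUROC
oracle_auroc <- function(scores, labels) {
  pos <- scores[labels == 1]
  neg <- scores[labels == 0]
  cmp <- outer(pos, neg, function(a, b) (a > b) + 0.5 * (a == b))
  mean(cmp)
}

# naive structural-components DeLong variance (explicit placement loops)
oracle_delong_variance <- function(scores, labels) {
  pos <- scores[labels == 1]
  neg <- scores[labels == 0]
  v10 <- vapply(pos, function(a) mean((a > neg) + 0.5 * (a == neg)), numeric(1))
  v01 <- vapply(neg, function(b) mean((pos > b) + 0.5 * (pos == b)), numeric(1))
  stats::var(v10) / length(pos) + stats::var(v01) / length(neg)
}

# ICC(2,1) through R's own two-way ANOVA fit
oracle_icc21 <- function(m) {
  df <- data.frame(y = as.vector(m),
                   subj = factor(as.vector(row(m))),
                   rater = factor(as.vector(col(m))))
  tab <- stats::anova(stats::aov(y ~ subj + rater, data = df))
  msr <- tab["subj", "Mean Sq"]
  msc <- tab["rater", "Mean Sq"]
  mse <- tab["Residuals", "Mean Sq"]
  n <- nrow(m); k <- ncol(m)
  (msr - mse) / (msr + (k - 1) * mse + k * (msc - mse) / n)
}

# random keyword-and-filler texts exercising boundary traps
random_flag_text <- function(rng_tokens = 40L) {
  ts <- default_term_sets()
  tricky <- c("body", "mood", "odd", "oxygen", "methodical", "cracker",
              "substances", "abusement", "intoxicated", "intoxication",
              "poisonings", "ingestions", "heroine", "overdosed")
  pool <- c(ts$opioid$terms, ts$overdose$terms, default_filler_vocab(), tricky)
  n_tok <- sample.int(rng_tokens, 1L)
  toks <- sample(pool, n_tok, replace = TRUE)
  # random case mangling
  toks <- vapply(toks, function(t) {
    switch(sample.int(3L, 1L), t, toupper(t), {
      ch <- strsplit(t, "")[[1]]
      flip <- stats::runif(length(ch)) < 0.3
      ch[flip] <- toupper(ch[flip]); paste(ch, collapse = "")
    })
  }, character(1), USE.NAMES = FALSE)
  seps <- sample(c(" ", "  ", ", ", ". ", "; "), n_tok, replace = TRUE)
  paste0(paste0(toks, seps[seq_along(toks)]), collapse = "")
}

# tiny hand-built labeled cohort
tiny_cohort <- function() {
  suppressWarnings(as_cohort(data.frame(
    record_id = c("A", "B", "C", "D", "E", "F"),
    county = c("Travis", "Travis", "ElPaso", "ElPaso", "Williamson", "Travis"),
    chief_narrative = c("pt found unresponsive narcan given heroin od",
                        "fall at residence minor injury",
                        "suspected fentanyl overdose naloxone administered",
                        "chest pain radiating to arm",
                        "patient intoxicated denies substance abuse",
                        "routine transport to facility"),
    ethnicity = c("White", "White", "Hispanic or Latino", "unknown or unassigned",
                  "White", "Black or African American"),
    gender = c("male", "female", "male", "male", "female", "male"),
    age = c(34, 71, 28, 55, 41, 63),
    label = c("positive", "negative", "positive", "negative", "negative", "negative"),
    stringsAsFactors = FALSE)))
}

expect_same_records <- function(a, b) {
  expect_equal(as.data.frame(a), as.data.frame(b), ignore_attr = TRUE)
}
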