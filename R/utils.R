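#' @keywords internal
"_PACKAGE"

# Evaluate `code` under a temporary RNG state seeded with `seed`, restoring the
# caller's .Random.seed afterwards so library code never perturbs user RNG.
with_rng <- function(seed, code) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(rm(".Random.seed", envir = globalenv()), add = TRUE)
  }
  set.seed(as.integer(seed))
  force(code)
}

# Deterministically derive a child seed from a parent seed and a tag.
# Stays within 32-bit integer range.
derive_seed <- function(seed, tag) {
  h <- 0
  for (ch in utf8ToInt(paste0(tag))) h <- (h * 31 + ch) %% 1000003L
  as.integer((as.numeric(seed) %% 1000000007 + h * 2654435.0) %% 2147483647)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# round-half-up (base round() is banker's)
round_half_up <- function(x) floor(x + 0.5)

is_prob <- function(x) is.numeric(x) && all(!is.na(x)) && all(x >= 0) && all(x <= 1)

check_binary_labels <- function(labels, require_both = TRUE) {
  if (is.logical(labels)) labels <- as.integer(labels)
  if (is.character(labels) || is.factor(labels)) {
    labels <- as.character(labels)
    labels <- ifelse(labels == "positive", 1L, ifelse(labels == "negative", 0L, NA_integer_))
  }
  labels <- as.integer(labels)
  if (anyNA(labels) || !all(labels %in% c(0L, 1L))) {
    stop("labels must be binary (0/1 or negative/positive) with no missing values")
  }
  if (require_both && length(unique(labels)) < 2L) {
    stop("both classes must be present")
  }
  labels
}
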