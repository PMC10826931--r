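#' Area under the ROC curve
#'
#' Mann-Whitney formulation with ties counted one half, computed from
#' midranks (the layout the fast DeLong variance shares): the probability
#' that a random positive is scored above a random negative.
#'
#' @param scores numeric score (probability) vector.
#' @param labels binary labels (0/1 or negative/positive); both classes
#'   required.
#' @return AUROC in `[0, 1]`.
#' @export
auroc <- function(scores, labels) {
  labels <- check_binary_labels(labels)
  stopifnot(length(scores) == length(labels), all(is.finite(scores)))
  n_pos <- sum(labels == 1L)
  n_neg <- sum(labels == 0L)
  r <- rank(scores, ties.method = "average")
  (sum(r[labels == 1L]) - n_pos * (n_pos + 1) / 2) / (n_pos * n_neg)
}

#' AUROC with DeLong variance and confidence interval
#'
#' Variance from placement values (structural components): for positive i,
#' `V10_i` is the fraction of negatives it outranks (ties half), and
#' symmetrically `V01_j` for negatives; `var = var(V10)/n_pos +
#' var(V01)/n_neg`. The midrank computation is algebraically identical to
#' the naive all-pairs double loop. The Wald CI `auc +/- z * sqrt(var)` is
#' truncated to `[0, 1]`; perfectly separated scores give a zero-width CI
#' at the point estimate.
#'
#' @param scores numeric score vector.
#' @param labels binary labels; at least two of each class.
#' @param level confidence level (default 0.95).
#' @return A `roc_analysis` list: `auc`, `variance`, `ci`, `ci_level`,
#'   `n_pos`, `n_neg`.
#' @export
delong_ci <- function(scores, labels, level = 0.95) {
  labels <- check_binary_labels(labels)
  stopifnot(length(scores) == length(labels), all(is.finite(scores)),
            level > 0, level < 1)
  n_pos <- sum(labels == 1L)
  n_neg <- sum(labels == 0L)
  if (n_pos < 2L || n_neg < 2L) stop("DeLong CI needs at least 2 of each class")
  pos <- scores[labels == 1L]
  neg <- scores[labels == 0L]
  r_all <- rank(c(pos, neg), ties.method = "average")
  r_pos <- rank(pos, ties.method = "average")
  r_neg <- rank(neg, ties.method = "average")
  v10 <- (r_all[seq_len(n_pos)] - r_pos) / n_neg
  v01 <- 1 - (r_all[n_pos + seq_len(n_neg)] - r_neg) / n_pos
  auc <- mean(v10)
  variance <- stats::var(v10) / n_pos + stats::var(v01) / n_neg
  z <- stats::qnorm(1 - (1 - level) / 2)
  half <- z * sqrt(max(variance, 0))
  ci <- c(max(0, auc - half), min(1, auc + half))
  structure(list(auc = auc, variance = variance, ci_level = level,
                 ci = ci, n_pos = n_pos, n_neg = n_neg),
            class = "roc_analysis")
}

#' @export
print.roc_analysis <- function(x, ...) {
  cat(sprintf("AUROC = %.3f (%d%% CI: %.3f-%.3f; DeLong), n = %d pos / %d neg\n",
              x$auc, round(100 * x$ci_level), x$ci[1], x$ci[2], x$n_pos, x$n_neg))
  invisible(x)
}

#' ROC curve points
#'
#' One row per distinct threshold (descending, starting above the maximum
#' score): false-positive rate, true-positive rate, threshold.
#'
#' @inheritParams auroc
#' @return Data frame with `fpr`, `tpr`, `threshold`.
#' @export
roc_points <- function(scores, labels) {
  labels <- check_binary_labels(labels)
  thr <- c(Inf, sort(unique(scores), decreasing = TRUE))
  n_pos <- sum(labels == 1L)
  n_neg <- sum(labels == 0L)
  data.frame(
    fpr = vapply(thr, function(t) sum(scores >= t & labels == 0L) / n_neg, numeric(1)),
    tpr = vapply(thr, function(t) sum(scores >= t & labels == 1L) / n_pos, numeric(1)),
    threshold = thr)
}

#' Confusion table at a probability threshold
#'
#' Predicts positive where `score >= threshold` and tabulates counts plus
#' the derived metrics. Ratios with zero denominators are reported as
#' `NA` (unknown), never as 0.
#'
#' @inheritParams auroc
#' @param threshold probability cutoff (default 0.5).
#' @return A `confusion_table` list.
#' @export
confusion_at_threshold <- function(scores, labels, threshold = 0.5) {
  labels <- check_binary_labels(labels, require_both = FALSE)
  pred <- as.integer(scores >= threshold)
  tp <- sum(pred == 1L & labels == 1L)
  fp <- sum(pred == 1L & labels == 0L)
  fn <- sum(pred == 0L & labels == 1L)
  tn <- sum(pred == 0L & labels == 0L)
  safe_div <- function(a, b) if (b > 0) a / b else NA_real_
  out <- list(tn = tn, fp = fp, fn = fn, tp = tp, threshold = threshold,
              sensitivity = safe_div(tp, tp + fn),
              specificity = safe_div(tn, tn + fp),
              ppv = safe_div(tp, tp + fp),
              npv = safe_div(tn, tn + fn),
              accuracy = safe_div(tp + tn, tp + tn + fp + fn))
  class(out) <- "confusion_table"
  out
}

#' @export
print.confusion_table <- function(x, ...) {
  cat(sprintf("confusion @ %.2f: tn=%d fp=%d fn=%d tp=%d\n",
              x$threshold, x$tn, x$fp, x$fn, x$tp))
  cat(sprintf("  sens=%.3f spec=%.3f ppv=%.3f npv=%.3f acc=%.3f\n",
              x$sensitivity, x$specificity, x$ppv, x$npv, x$accuracy))
  invisible(x)
}

#' Model-independent per-predictor importance
#'
#' Scores each feature column as a classifier on its own: the AUROC of the
#' raw column against the labels, reported alongside the
#' direction-agnostic score `max(auc, 1 - auc)` (a feature predictive in
#' reverse is still informative). Constant columns score 0.5. Ranks are by
#' score, ties broken by column name.
#'
#' @param features numeric feature matrix with column names.
#' @param labels binary labels.
#' @return An `importance_report` data frame: `column`, `auc`, `score`,
#'   `rank`.
#' @export
variable_importance <- function(features, labels) {
  labels <- check_binary_labels(labels)
  stopifnot(nrow(features) == length(labels))
  aucs <- vapply(seq_len(ncol(features)), function(j) {
    auroc(features[, j], labels)
  }, numeric(1))
  score <- pmax(aucs, 1 - aucs)
  ord <- order(-score, colnames(features))
  out <- data.frame(column = colnames(features), auc = aucs, score = score,
                    stringsAsFactors = FALSE)
  out$rank <- match(seq_len(ncol(features)), ord)
  out <- out[order(out$rank), ]
  rownames(out) <- NULL
  class(out) <- c("importance_report", "data.frame")
  out
}

#' Pairwise demographic parity tests on error rates
#'
#' For a fixed error type (false negatives over condition positives, or
#' false positives over condition negatives), runs a two-proportion
#' chi-square test with Yates continuity correction for each unordered
#' pair of groups. Groups with zero denominator are excluded with a
#' warning. Holm adjustment is available but off by default.
#'
#' @param errors named integer vector of error counts per group.
#' @param denominators named integer vector of group denominators (true
#'   condition positives for false negatives; true condition negatives for
#'   false positives).
#' @param adjust `"none"` (default) or `"holm"`.
#' @return A `parity_report` list with per-group `rates` and a pairwise
#'   `tests` data frame (`group1`, `group2`, `statistic`, `df`, `p_value`).
#' @export
parity_tests <- function(errors, denominators, adjust = c("none", "holm")) {
  adjust <- match.arg(adjust)
  stopifnot(!is.null(names(errors)), identical(names(errors), names(denominators)),
            all(errors >= 0), all(errors <= denominators))
  zero <- denominators == 0
  if (any(zero)) {
    warning(sprintf("excluding group(s) with zero denominator: %s",
                    paste(names(errors)[zero], collapse = ", ")))
    errors <- errors[!zero]
    denominators <- denominators[!zero]
  }
  if (length(errors) < 2L) stop("parity tests need at least 2 groups with positive denominators")
  groups <- names(errors)
  pairs <- utils::combn(groups, 2)
  tests <- data.frame(group1 = pairs[1, ], group2 = pairs[2, ],
                      statistic = NA_real_, df = 1, p_value = NA_real_,
                      stringsAsFactors = FALSE)
  for (i in seq_len(ncol(pairs))) {
    g <- pairs[, i]
    ht <- suppressWarnings(stats::prop.test(errors[g], denominators[g],
                                            correct = TRUE))
    tests$statistic[i] <- unname(ht$statistic)
    tests$p_value[i] <- ht$p.value
  }
  if (adjust == "holm") tests$p_adjusted <- stats::p.adjust(tests$p_value, "holm")
  out <- list(rates = data.frame(group = groups,
                                 errors = unname(errors),
                                 denominator = unname(denominators),
                                 rate = unname(errors / denominators),
                                 stringsAsFactors = FALSE),
              tests = tests, adjust = adjust)
  class(out) <- "parity_report"
  out
}

#' @export
print.parity_report <- function(x, ...) {
  cat("group error rates:\n")
  r <- x$rates
  for (i in seq_len(nrow(r))) {
    cat(sprintf("  %-24s %d/%d (%.2f%%)\n", r$group[i], r$errors[i],
                r$denominator[i], 100 * r$rate[i]))
  }
  cat("pairwise equality-of-proportions tests (Yates-corrected):\n")
  t <- x$tests
  for (i in seq_len(nrow(t))) {
    cat(sprintf("  %s vs %s: chi2 = %.2f, df = 1, p = %.4f\n",
                t$group1[i], t$group2[i], t$statistic[i], t$p_value[i]))
  }
  invisible(x)
}

#' Intraclass correlation, ICC(2,1)
#'
#' Two-way random effects, absolute agreement, single rater — the form
#' used for inter-annotator reliability. Computed from the two-way ANOVA
#' decomposition: with n subjects, k raters, between-subject mean square
#' MSR, between-rater mean square MSC and residual MSE,
#' `ICC = (MSR - MSE) / (MSR + (k-1) MSE + k (MSC - MSE) / n)`.
#' A matrix with no variance anywhere has an undefined ICC, reported as
#' `NA` with an explanatory note.
#'
#' @param ratings numeric subjects x raters matrix, no missing cells, at
#'   least 5 subjects and 2 raters.
#' @return An `icc_result` list: `icc_value`, `form`, `n_subjects`,
#'   `n_raters`, mean squares, optional `note`.
#' @export
icc <- function(ratings) {
  ratings <- as.matrix(ratings)
  if (anyNA(ratings)) stop("ratings must have no missing cells")
  n <- nrow(ratings)
  k <- ncol(ratings)
  if (k < 2L) stop("need at least 2 raters")
  if (n < 5L) stop("need at least 5 subjects")
  grand <- mean(ratings)
  row_means <- rowMeans(ratings)
  col_means <- colMeans(ratings)
  ss_rows <- k * sum((row_means - grand)^2)
  ss_cols <- n * sum((col_means - grand)^2)
  ss_total <- sum((ratings - grand)^2)
  ss_err <- ss_total - ss_rows - ss_cols
  msr <- ss_rows / (n - 1)
  msc <- ss_cols / (k - 1)
  mse <- ss_err / ((n - 1) * (k - 1))
  denom <- msr + (k - 1) * mse + k * (msc - mse) / n
  note <- NULL
  if (denom <= .Machine$double.eps * max(1, abs(msr))) {
    value <- NA_real_
    note <- "undefined: no variance in ratings (zero denominator)"
  } else {
    value <- (msr - mse) / denom
  }
  structure(list(icc_value = value,
                 form = "two-way random effects, absolute agreement, single rater (ICC(2,1))",
                 n_subjects = n, n_raters = k,
                 ms = c(rows = msr, cols = msc, error = mse),
                 note = note),
            class = "icc_result")
}

#' @export
print.icc_result <- function(x, ...) {
  if (is.na(x$icc_value)) {
    cat(sprintf("ICC(2,1): %s [%d subjects x %d raters]\n",
                x$note, x$n_subjects, x$n_raters))
  } else {
    cat(sprintf("ICC(2,1) = %.3f [%d subjects x %d raters]\n",
                x$icc_value, x$n_subjects, x$n_raters))
  }
  invisible(x)
}
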