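#' Configure a benchmark run
#'
#' Describes the full featurizer-by-architecture grid: which feature
#' methods and learners to run, whether to stack an ensemble per method,
#' the CV protocol, and the single 80/20 stratified split shared by every
#' cell so feature methods are compared on identical held-out records.
#'
#' @param cohort a labeled `ems_cohort`, or `NULL` to generate one.
#' @param generator a [cohort_config()] used when `cohort` is `NULL`.
#' @param methods subset of `c("flags", "tfidf", "concept")`.
#' @param architectures subset of
#'   `c("glm", "nnet", "naive_bayes", "xgb_tree")`.
#' @param include_ensemble stack a linear ensemble per method.
#' @param cv a [cv_config()]; its seed is re-derived per benchmark seed.
#' @param test_fraction held-out fraction (default 0.2).
#' @param seed master seed for split, training and ensembling.
#' @param threshold probability cutoff for the reported confusion table.
#' @param concept_resources `list(lexicon=, embeddings=)` for the concept
#'   method; defaults to [synthetic_concept_resources()].
#' @param term_sets term sets for the flags method.
#' @param out_dir optional directory for the JSON report and ROC CSVs.
#' @return A `benchmark_config`.
#' @export
benchmark_config <- function(cohort = NULL, generator = cohort_config(),
                             methods = c("flags", "tfidf", "concept"),
                             architectures = c("glm", "nnet", "naive_bayes", "xgb_tree"),
                             include_ensemble = TRUE,
                             cv = cv_config(),
                             test_fraction = 0.2,
                             seed = 20240130L,
                             threshold = 0.5,
                             concept_resources = NULL,
                             term_sets = default_term_sets(),
                             out_dir = NULL) {
  if (!length(methods) || !length(architectures)) {
    stop("need at least one method and one architecture")
  }
  methods <- match.arg(methods, c("flags", "tfidf", "concept"), several.ok = TRUE)
  architectures <- match.arg(architectures,
                             c("glm", "nnet", "naive_bayes", "xgb_tree"),
                             several.ok = TRUE)
  structure(list(cohort = cohort, generator = generator, methods = methods,
                 architectures = architectures,
                 include_ensemble = isTRUE(include_ensemble), cv = cv,
                 test_fraction = test_fraction, seed = as.integer(seed),
                 threshold = threshold, concept_resources = concept_resources,
                 term_sets = term_sets, out_dir = out_dir),
            class = "benchmark_config")
}

build_features <- function(method, train, test, config, state = new.env()) {
  switch(method,
    flags = list(
      train = featurize_flags(train, config$term_sets),
      test = featurize_flags(test, config$term_sets)),
    tfidf = {
      mdl <- fit_tfidf(train)
      list(train = transform_tfidf(mdl, train), test = transform_tfidf(mdl, test),
           model = mdl)
    },
    concept = {
      res <- config$concept_resources %||% synthetic_concept_resources()
      list(train = suppressMessages(vectorize_narrative(train, res$lexicon, res$embeddings)),
           test = suppressMessages(vectorize_narrative(test, res$lexicon, res$embeddings)))
    })
}

#' Run the featurizer-by-model benchmark grid
#'
#' Generates (or takes) a labeled cohort, makes one stratified train/test
#' split, and for every requested feature method trains every requested
#' architecture on the training side, optionally stacks the linear
#' ensemble, and evaluates every cell on the shared held-out side with
#' DeLong confidence intervals. The report includes the best ensemble's
#' confusion table at the configured threshold and, when the flags method
#' is run, the per-predictor importance of the flags features. The report
#' is a byte-deterministic function of the config; if `out_dir` is set it
#' is written as JSON alongside per-cell ROC-point CSVs.
#'
#' @param config a [benchmark_config()].
#' @param quiet suppress per-cell progress messages.
#' @return A `benchmark_report` list.
#' @export
run_benchmark <- function(config, quiet = FALSE) {
  stopifnot(inherits(config, "benchmark_config"))
  cohort <- config$cohort
  if (is.null(cohort)) cohort <- generate_cohort(config$generator)$cohort
  if (all(is.na(cohort$label))) stop("benchmark requires a labeled cohort")
  parts <- split_train_test(cohort, config$test_fraction,
                            seed = derive_seed(config$seed, "split"),
                            stratify_on_label = TRUE)
  y_train <- check_binary_labels(parts$train$label)
  y_test <- check_binary_labels(parts$test$label)
  cells <- list()
  roc_curves <- list()
  ensembles <- list()
  for (method in config$methods) {
    feats <- build_features(method, parts$train, parts$test, config)
    cv <- config$cv
    cv$seed <- derive_seed(config$seed, paste("cv", method))
    models <- list()
    for (arch in config$architectures) {
      t0 <- Sys.time()
      mdl <- tryCatch(
        train_model(feats$train, y_train, model_spec(arch), cv),
        error = function(e) stop(sprintf("benchmark cell %s.%s failed: %s",
                                         method, arch, conditionMessage(e)),
                                 call. = FALSE))
      models[[arch]] <- mdl
      scores <- stats::predict(mdl, feats$test)
      roc <- delong_ci(scores, y_test)
      key <- paste0(method, ".", arch)
      cells[[key]] <- c(list(method = method, model = arch), unclass(roc))
      roc_curves[[key]] <- roc_points(scores, y_test)
      if (!quiet) {
        message(sprintf("[cell %s] AUROC %.3f (%.3f-%.3f) seed=%d %.1fs",
                        key, roc$auc, roc$ci[1], roc$ci[2], cv$seed,
                        as.numeric(difftime(Sys.time(), t0, units = "secs"))))
      }
    }
    if (config$include_ensemble) {
      ens <- fit_ensemble(models, y_train,
                          seed = derive_seed(config$seed, paste("ens", method)))
      scores <- stats::predict(ens, feats$test)
      roc <- delong_ci(scores, y_test)
      key <- paste0(method, ".ensemble")
      cells[[key]] <- c(list(method = method, model = "ensemble"), unclass(roc))
      roc_curves[[key]] <- roc_points(scores, y_test)
      ensembles[[method]] <- list(model = ens, scores = scores, auc = roc$auc)
      if (!quiet) {
        message(sprintf("[cell %s] AUROC %.3f (%.3f-%.3f)",
                        key, roc$auc, roc$ci[1], roc$ci[2]))
      }
    }
  }
  confusion <- NULL
  best_ensemble <- NULL
  if (length(ensembles)) {
    best_ensemble <- names(ensembles)[which.max(vapply(ensembles, `[[`, numeric(1), "auc"))]
    confusion <- unclass(confusion_at_threshold(ensembles[[best_ensemble]]$scores,
                                                y_test, config$threshold))
  }
  importance <- NULL
  if ("flags" %in% config$methods) {
    flags_test <- featurize_flags(parts$test, config$term_sets)
    importance <- variable_importance(flags_test, y_test)
  }
  report <- list(
    provenance = list(
      package = "emsflags",
      version = as.character(utils::packageVersion("emsflags")),
      seed = config$seed,
      test_fraction = config$test_fraction,
      threshold = config$threshold,
      methods = config$methods,
      architectures = config$architectures,
      include_ensemble = config$include_ensemble,
      cv = unclass(config$cv),
      n_train = nrow(parts$train), n_test = nrow(parts$test),
      n_test_positive = sum(y_test == 1L),
      cohort_provenance = attr(cohort, "provenance") %||% "unspecified"),
    cells = cells,
    best_ensemble = best_ensemble,
    confusion = confusion,
    importance = importance)
  class(report) <- "benchmark_report"
  if (!is.null(config$out_dir)) {
    dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
    write_report(unclass(report), file.path(config$out_dir, "benchmark_report.json"))
    for (key in names(roc_curves)) {
      utils::write.csv(roc_curves[[key]],
                       file.path(config$out_dir, paste0("roc_", key, ".csv")),
                       row.names = FALSE)
    }
  }
  attr(report, "roc_curves") <- roc_curves
  report
}

#' @export
print.benchmark_report <- function(x, ...) {
  cat(sprintf("benchmark report: %d cell(s), %d train / %d test records\n",
              length(x$cells), x$provenance$n_train, x$provenance$n_test))
  for (key in names(x$cells)) {
    cl <- x$cells[[key]]
    cat(sprintf("  %-24s AUROC %.3f (%.3f-%.3f)\n", key, cl$auc, cl$ci[1], cl$ci[2]))
  }
  if (!is.null(x$best_ensemble)) {
    cat(sprintf("  best ensemble: %s; confusion @ %.2f: tn=%d fp=%d fn=%d tp=%d\n",
                x$best_ensemble, x$confusion$threshold, x$confusion$tn,
                x$confusion$fp, x$confusion$fn, x$confusion$tp))
  }
  invisible(x)
}

#' Select a blinded annotation batch by model-assisted oversampling
#'
#' Scores an unlabeled pool, then draws a uniform random sample of
#' `n_per_class` records from each predicted class at the given threshold.
#' The emitted batch is order-randomized and contains no prediction field
#' (its column set equals the pool's), so annotators are blinded; the
#' record-to-predicted-class map is returned separately (and optionally
#' written to a sealed side-file) for later unblinding.
#'
#' @param model an `ems_model` or `ems_ensemble`.
#' @param pool an `ems_cohort` to sample from.
#' @param n_per_class records to draw per predicted class.
#' @param seed integer seed.
#' @param featurizer function mapping a cohort to the model's feature
#'   matrix (default: flag features with the curated sets).
#' @param threshold predicted-class cutoff (default 0.5).
#' @param key_path optional path for the sealed JSON side-file.
#' @return `list(batch = ems_cohort, key = data.frame(record_id,
#'   predicted_class))`.
#' @export
select_annotation_batch <- function(model, pool, n_per_class, seed,
                                    featurizer = function(cohort) featurize_flags(cohort),
                                    threshold = 0.5, key_path = NULL) {
  scores <- stats::predict(model, featurizer(pool))
  pred_pos <- which(scores >= threshold)
  pred_neg <- which(scores < threshold)
  if (length(pred_pos) < n_per_class) {
    stop(sprintf("only %d predicted positive(s) in pool; need %d",
                 length(pred_pos), n_per_class))
  }
  if (length(pred_neg) < n_per_class) {
    stop(sprintf("only %d predicted negative(s) in pool; need %d",
                 length(pred_neg), n_per_class))
  }
  idx <- with_rng(seed, {
    chosen <- c(sample(pred_pos, n_per_class), sample(pred_neg, n_per_class))
    sample(chosen)  # randomize emitted order
  })
  batch <- pool[idx, , drop = FALSE]
  rownames(batch) <- NULL
  class(batch) <- class(pool)
  attr(batch, "provenance") <- sprintf("annotation batch (seed %d)", seed)
  key <- data.frame(record_id = pool$record_id[idx],
                    predicted_class = ifelse(scores[idx] >= threshold,
                                             "positive", "negative"),
                    stringsAsFactors = FALSE)
  if (!is.null(key_path)) write_report(key, key_path)
  list(batch = batch, key = key)
}

#' Annotation stopping rule on benchmark confidence intervals
#'
#' Annotation rounds stop once at least one benchmark cell's AUROC 95% CI
#' lower endpoint reaches the bound (default 0.90). Returns the decision
#' and the qualifying cell with the highest lower endpoint.
#'
#' @param reports list of `benchmark_report`s (>= 1, with >= 1 cell in
#'   total).
#' @param lower_bound CI lower-endpoint bound.
#' @return `list(stop = logical, best_cell = name or NULL, lower = value)`.
#' @export
stopping_rule <- function(reports, lower_bound = 0.90) {
  if (inherits(reports, "benchmark_report")) reports <- list(reports)
  if (!length(reports)) stop("need at least one report")
  lows <- numeric()
  for (ri in seq_along(reports)) {
    cells <- reports[[ri]]$cells
    for (key in names(cells)) {
      lows[paste0("report", ri, ":", key)] <- cells[[key]]$ci[1]
    }
  }
  if (!length(lows)) stop("no benchmark cells in any report")
  best <- which.max(lows)
  list(stop = unname(lows[best]) >= lower_bound,
       best_cell = if (lows[best] >= lower_bound) names(lows)[best] else NULL,
       lower = unname(lows[best]))
}
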