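# Neutral clinical filler vocabulary. Validated at config construction to
# contain no keyword match under the default term sets' boundary rules;
# words like "blood" and "body" (which contain "od" without boundaries) are
# deliberately kept to exercise the boundary logic.
default_filler_vocab <- function() {
  c("patient", "assessed", "vitals", "stable", "transported", "hospital",
    "scene", "arrival", "blood", "pressure", "pulse", "respiratory", "rate",
    "normal", "alert", "oriented", "denies", "pain", "chest", "prior",
    "administered", "oxygen", "glucose", "monitor", "ambulance", "responded",
    "dispatch", "residence", "adult", "complains", "dizziness", "weakness",
    "nausea", "fall", "injury", "minor", "refused", "transport", "signed",
    "release", "officer", "bystander", "reports", "found", "sitting",
    "upright", "conscious", "breathing", "body", "supine", "gcs", "airway",
    "patent", "skin", "warm", "dry", "secured", "stretcher", "uneventful",
    "ride", "facility", "staff", "report", "given")
}

behavioral_health_vocab <- function() {
  c("behavioral", "health", "crisis", "suicidal", "ideation", "reported",
    "tearful", "counseling", "requested", "distressed", "statements",
    "safety", "plan", "discussed")
}

no_response_phrase <- function() c("administered", "with", "no", "improvement", "noted")
unnamed_product_phrase <- function() c("unknown", "pain", "pills", "taken")

#' Configure the synthetic EMS cohort generator
#'
#' The generator stands in for protected EMS records: it emits labeled
#' encounters whose six text fields are neutral clinical filler, with
#' curated opioid/overdose keywords planted in positive records and the
#' documented confounders injected at configurable rates. Defaults emulate
#' the study conditions: ~15% positive prevalence, three county strata
#' weighted 1635/747/576, keyword signal concentrated in the chief
#' narrative and primary impression, positives' ages uniform on 16-90, and
#' confounder rates proportional to the documented 25:8:6:3:3 error tally.
#'
#' Confounder semantics (applied per record, after signal planting):
#' \describe{
#'   \item{narcan_no_response}{a negative record gains "Narcan" plus a
#'     no-improvement phrase in its chief narrative.}
#'   \item{detailed_denial}{a negative record gains three distinct opioid
#'     terms inside a denial phrase.}
#'   \item{history_only}{a negative record gains one opioid term in
#'     medical_history or medication_list only.}
#'   \item{behavioral_health_focus}{a positive record's chief-narrative
#'     keywords are removed and replaced with behavioral-health language.}
#'   \item{unnamed_product}{a positive record's opioid terms (all fields)
#'     are replaced; the narrative instead mentions "unknown pain pills".}
#' }
#'
#' @param n record count.
#' @param prevalence positive-class probability.
#' @param counties named weight vector (normalized internally).
#' @param field_signal named probability per text field that a positive
#'   record receives at least one opioid and one overdose term there.
#' @param signal_count_mean Poisson mean of extra planted keywords per
#'   signaled field.
#' @param confounder_rates named probabilities for the five confounders.
#' @param filler_vocab neutral token vocabulary; validated against
#'   `term_sets` so planted counts are exactly recoverable.
#' @param filler_length_mean mean filler tokens per field (Poisson, +1).
#' @param base_keyword_rate probability that a negative record picks up one
#'   innocuous overdose-set keyword (default 0: the clean-oracle regime).
#' @param demographics list with `ethnicity` and `gender` probability
#'   vectors and `age_range_positive` / `age_range_negative`.
#' @param term_sets the term sets the signal is drawn from.
#' @param seed integer seed; generation is byte-deterministic given the
#'   config.
#' @return A validated `generator_config` list.
#' @export
cohort_config <- function(n = 3000,
                          prevalence = 0.15,
                          counties = c(Travis = 1635, ElPaso = 747, Williamson = 576),
                          field_signal = c(chief_narrative = 0.60,
                                           primary_impression = 0.45,
                                           chief_complaint = 0.25,
                                           call_nature = 0.10,
                                           medication_list = 0.10,
                                           medical_history = 0.10),
                          signal_count_mean = 1,
                          confounder_rates = c(narcan_no_response = 0.0667,
                                               detailed_denial = 0.0213,
                                               history_only = 0.0160,
                                               behavioral_health_focus = 0.0080,
                                               unnamed_product = 0.0080),
                          filler_vocab = default_filler_vocab(),
                          filler_length_mean = 8,
                          base_keyword_rate = 0,
                          demographics = NULL,
                          term_sets = default_term_sets(),
                          seed = 20240130) {
  stopifnot(n >= 0, is_prob(prevalence), is_prob(field_signal),
            is_prob(confounder_rates), is_prob(base_keyword_rate),
            signal_count_mean >= 0, filler_length_mean >= 0,
            all(counties >= 0), sum(counties) > 0)
  need <- c("narcan_no_response", "detailed_denial", "history_only",
            "behavioral_health_focus", "unnamed_product")
  if (!all(need %in% names(confounder_rates))) {
    stop("confounder_rates must name: ", paste(need, collapse = ", "))
  }
  if (!all(names(field_signal) %in% ems_text_fields())) {
    stop("field_signal names must be text fields")
  }
  fs <- stats::setNames(rep(0, 6), ems_text_fields())
  fs[names(field_signal)] <- field_signal
  if (is.null(demographics)) {
    demographics <- list(
      ethnicity = c("White" = 0.55, "Hispanic or Latino" = 0.258,
                    "Black or African American" = 0.055, "Asian" = 0.014,
                    "unknown or unassigned" = 0.123),
      gender_positive = c(male = 0.719, female = 0.281),
      gender_negative = c(male = 0.5, female = 0.5),
      age_range_positive = c(16, 90),
      age_range_negative = c(1, 90)
    )
  }
  # clean-oracle guarantee: filler and confounder phrase tokens must not
  # collide with any term set under the matching rules
  aux <- c(filler_vocab, behavioral_health_vocab(), no_response_phrase(),
           unnamed_product_phrase(), "denies", "taking", "and", "history", "of", "use")
  joined <- paste(aux, collapse = " ")
  for (ts in term_sets) {
    if (count_term_matches(joined, ts) > 0 || any(count_term_matches(aux, ts) > 0)) {
      stop(sprintf("filler vocabulary collides with term set '%s'", ts$name))
    }
  }
  cfg <- list(n = as.integer(n), prevalence = prevalence,
              counties = counties / sum(counties),
              field_signal = fs, signal_count_mean = signal_count_mean,
              confounder_rates = confounder_rates[need],
              filler_vocab = filler_vocab,
              filler_length_mean = filler_length_mean,
              base_keyword_rate = base_keyword_rate,
              demographics = demographics,
              term_sets = term_sets,
              seed = as.integer(seed))
  class(cfg) <- "generator_config"
  cfg
}

# insert term tokens at random positions among filler tokens
insert_tokens <- function(filler, inserts) {
  if (!length(inserts)) return(filler)
  for (tok in inserts) {
    pos <- sample.int(length(filler) + 1L, 1L)
    filler <- append(filler, tok, after = pos - 1L)
  }
  filler
}

#' Generate a synthetic labeled EMS cohort
#'
#' Draws `n` records with i.i.d. Bernoulli(`prevalence`) labels, plants
#' keyword signal in positives per `field_signal`, applies confounders, and
#' returns both the cohort and a generation-truth object recording every
#' planted term (field, term, set) per record, which makes featurizer
#' outputs exactly predictable. Deterministic for a fixed config.
#'
#' @param config a [cohort_config()].
#' @return `list(cohort = ems_cohort, truth = generation_truth)`.
#' @export
generate_cohort <- function(config) {
  stopifnot(inherits(config, "generator_config"))
  n <- config$n
  tf <- ems_text_fields()
  ts <- config$term_sets
  opioid_terms <- ts$opioid$terms
  overdose_terms <- ts$overdose$terms
  dem <- config$demographics
  with_rng(config$seed, {
    labels <- stats::rbinom(n, 1L, config$prevalence)
    county <- if (n) sample(names(config$counties), n, replace = TRUE,
                            prob = config$counties) else character()
    ethnicity <- if (n) sample(names(dem$ethnicity), n, replace = TRUE,
                               prob = dem$ethnicity) else character()
    gender <- character(n)
    age <- numeric(n)
    fields <- matrix("", nrow = n, ncol = length(tf), dimnames = list(NULL, tf))
    planted <- vector("list", n)
    confounders <- vector("list", n)
    for (i in seq_len(n)) {
      pos <- labels[i] == 1L
      gp <- if (pos) dem$gender_positive else dem$gender_negative
      gender[i] <- sample(names(gp), 1L, prob = gp)
      ar <- if (pos) dem$age_range_positive else dem$age_range_negative
      age[i] <- round(stats::runif(1, ar[1], ar[2]))
      # per-field planted terms for positives
      plant <- list()
      for (f in tf) {
        if (pos && stats::runif(1) < config$field_signal[[f]]) {
          terms <- c(sample(opioid_terms, 1L), sample(overdose_terms, 1L))
          sets <- c("opioid", "overdose")
          extra <- stats::rpois(1L, config$signal_count_mean)
          if (extra > 0) {
            for (k in seq_len(extra)) {
              if (stats::runif(1) < 0.5) {
                terms <- c(terms, sample(opioid_terms, 1L)); sets <- c(sets, "opioid")
              } else {
                terms <- c(terms, sample(overdose_terms, 1L)); sets <- c(sets, "overdose")
              }
            }
          }
          plant[[f]] <- data.frame(field = f, term = terms, set = sets,
                                   stringsAsFactors = FALSE)
        }
      }
      # innocuous background keyword on negatives (off by default)
      if (!pos && config$base_keyword_rate > 0 &&
          stats::runif(1) < config$base_keyword_rate) {
        plant[["chief_narrative"]] <- rbind(
          plant[["chief_narrative"]],
          data.frame(field = "chief_narrative",
                     term = sample(overdose_terms, 1L), set = "overdose",
                     stringsAsFactors = FALSE))
      }
      # confounders; terms they inject are inserted via their phrase only,
      # and recorded separately so truth still counts them
      active <- character()
      cr <- config$confounder_rates
      extra_tokens <- stats::setNames(vector("list", length(tf)), tf)
      conf_plant <- list()
      if (!pos) {
        if (stats::runif(1) < cr[["narcan_no_response"]]) {
          active <- c(active, "narcan_no_response")
          conf_plant[[length(conf_plant) + 1L]] <-
            data.frame(field = "chief_narrative", term = "narcan",
                       set = "opioid", stringsAsFactors = FALSE)
          extra_tokens[["chief_narrative"]] <-
            c(extra_tokens[["chief_narrative"]],
              list(c("Narcan", no_response_phrase())))
        }
        if (stats::runif(1) < cr[["detailed_denial"]]) {
          active <- c(active, "detailed_denial")
          denied <- sample(opioid_terms, 3L)
          conf_plant[[length(conf_plant) + 1L]] <-
            data.frame(field = "chief_narrative", term = denied,
                       set = "opioid", stringsAsFactors = FALSE)
          extra_tokens[["chief_narrative"]] <-
            c(extra_tokens[["chief_narrative"]],
              list(c("patient", "denies", "taking", denied[1], denied[2],
                     "and", denied[3])))
        }
        if (stats::runif(1) < cr[["history_only"]]) {
          active <- c(active, "history_only")
          f <- sample(c("medical_history", "medication_list"), 1L)
          term <- sample(opioid_terms, 1L)
          conf_plant[[length(conf_plant) + 1L]] <-
            data.frame(field = f, term = term, set = "opioid",
                       stringsAsFactors = FALSE)
          extra_tokens[[f]] <- c(extra_tokens[[f]],
                                 list(c("history", "of", term, "use")))
        }
      } else {
        if (stats::runif(1) < cr[["behavioral_health_focus"]]) {
          active <- c(active, "behavioral_health_focus")
          plant[["chief_narrative"]] <- NULL
        }
        if (stats::runif(1) < cr[["unnamed_product"]]) {
          active <- c(active, "unnamed_product")
          plant <- lapply(plant, function(p) p[p$set != "opioid", , drop = FALSE])
          plant <- plant[vapply(plant, function(p) !is.null(p) && nrow(p) > 0, logical(1))]
          extra_tokens[["chief_narrative"]] <-
            c(extra_tokens[["chief_narrative"]], list(unnamed_product_phrase()))
        }
      }
      # assemble field text: filler + planted terms + confounder phrases
      bh <- "behavioral_health_focus" %in% active
      for (f in tf) {
        n_fill <- stats::rpois(1L, config$filler_length_mean) + 1L
        vocab <- config$filler_vocab
        if (bh && f == "chief_narrative") vocab <- c(vocab, behavioral_health_vocab())
        toks <- sample(vocab, n_fill, replace = TRUE)
        p <- plant[[f]]
        if (!is.null(p) && nrow(p)) toks <- insert_tokens(toks, p$term)
        for (phrase in extra_tokens[[f]]) {
          pos_at <- sample.int(length(toks) + 1L, 1L)
          toks <- append(toks, phrase, after = pos_at - 1L)
        }
        fields[i, f] <- paste(toks, collapse = " ")
      }
      pl <- do.call(rbind, c(plant, conf_plant))
      planted[[i]] <- if (is.null(pl)) {
        data.frame(field = character(), term = character(), set = character(),
                   stringsAsFactors = FALSE)
      } else {
        rownames(pl) <- NULL
        pl
      }
      confounders[[i]] <- active
    }
  })
  df <- data.frame(record_id = sprintf("R%05d", seq_len(n)),
                   county = county, stringsAsFactors = FALSE)
  for (f in tf) df[[f]] <- unname(fields[, f])
  df$ethnicity <- ethnicity
  df$gender <- gender
  df$age <- age
  df$label <- ifelse(labels == 1L, "positive", "negative")
  df$phase <- NA_character_
  cohort <- suppressWarnings(as_cohort(df, provenance = sprintf(
    "synthetic (seed %d, n %d, prevalence %g)", config$seed, n, config$prevalence)))
  truth <- structure(list(labels = labels, planted = planted,
                          confounders = confounders, config = config),
                     class = "generation_truth")
  list(cohort = cohort, truth = truth)
}

#' Planted keyword counts implied by a generation truth
#'
#' Returns the (record x set__field) matrix of planted term counts — the
#' oracle a flag featurization of the same cohort must reproduce exactly.
#'
#' @param truth a `generation_truth`.
#' @return Integer matrix shaped like [featurize_flags()] output.
#' @export
truth_flag_counts <- function(truth) {
  stopifnot(inherits(truth, "generation_truth"))
  tf <- ems_text_fields()
  sets <- names(truth$config$term_sets)
  cols <- unlist(lapply(sets, function(s) paste0(s, "__", tf)))
  mat <- matrix(0L, nrow = length(truth$planted), ncol = length(cols),
                dimnames = list(NULL, cols))
  for (i in seq_along(truth$planted)) {
    p <- truth$planted[[i]]
    if (nrow(p)) {
      key <- paste0(p$set, "__", p$field)
      tb <- table(key)
      mat[i, names(tb)] <- as.integer(tb)
    }
  }
  mat
}

#' Vary one generator parameter across a list of values
#'
#' Produces one config per value, identical to `base` except for the named
#' scalar parameter, with seeds offset deterministically so scenarios are
#' independent but reproducible.
#'
#' @param base a [cohort_config()].
#' @param axis name of a scalar config parameter (e.g. `"prevalence"`) or a
#'   confounder rate name (e.g. `"narcan_no_response"`).
#' @param values vector of values for the axis.
#' @return List of `generator_config`s (empty for empty `values`).
#' @export
grid_of_scenarios <- function(base, axis, values) {
  stopifnot(inherits(base, "generator_config"))
  scalar_axes <- c("n", "prevalence", "signal_count_mean", "filler_length_mean",
                   "base_keyword_rate")
  conf_axes <- names(base$confounder_rates)
  if (!(axis %in% c(scalar_axes, conf_axes))) {
    stop(sprintf("unknown scenario axis: %s", axis))
  }
  lapply(seq_along(values), function(i) {
    cfg <- unclass(base)
    if (axis %in% scalar_axes) cfg[[axis]] <- values[i]
    else cfg$confounder_rates[[axis]] <- values[i]
    cfg$seed <- as.integer((base$seed + i * 1009L) %% 2147483647L)
    class(cfg) <- "generator_config"
    # re-validate through the constructor
    do.call(cohort_config, cfg[setdiff(names(cfg), character())])
  })
}

#' Write a generator config as YAML
#' @param config a [cohort_config()].
#' @param path output path.
#' @export
write_generator_config <- function(config, path) {
  cfg <- unclass(config)
  cfg$term_sets <- lapply(unname(cfg$term_sets), function(ts) {
    list(name = ts$name, terms = as.list(ts$terms),
         prefix_terms = as.list(ts$prefix_terms))
  })
  cfg$counties <- as.list(cfg$counties)
  cfg$field_signal <- as.list(cfg$field_signal)
  cfg$confounder_rates <- as.list(cfg$confounder_rates)
  yaml::write_yaml(cfg, path)
  invisible(path)
}

#' Write generation truth as a JSON side-file
#' @param truth a `generation_truth`.
#' @param path output path.
#' @export
write_generation_truth <- function(truth, path) {
  out <- list(
    labels = truth$labels,
    planted = lapply(truth$planted, function(p) {
      lapply(seq_len(nrow(p)), function(i) as.list(p[i, ]))
    }),
    confounders = truth$confounders
  )
  write_report(out, path)
}
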