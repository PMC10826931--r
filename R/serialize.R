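#' Save a trained model or ensemble as JSON
#'
#' Model state is stored verbatim: GLM and naive-Bayes parameters as
#' numbers, the neural network's weight vector plus layout, and the
#' gradient-boosted booster's own JSON dump embedded as a string.
#' Ensembles embed their base models recursively. [load_model()] restores
#' an object whose predictions are identical to the original's.
#'
#' @param model an `ems_model` or `ems_ensemble`.
#' @param path output path.
#' @export
save_model <- function(model, path) {
  write_report(model_to_list(model), path)
}

model_to_list <- function(model) {
  if (inherits(model, "ems_ensemble")) {
    return(list(
      type = "ems_ensemble",
      combiner = model$combiner,
      combiner_names = names(model$combiner_named),
      seed = model$training_meta$seed,
      n_train = model$training_meta$n_train,
      fold_scheme_repeat1 = model$training_meta$fold_scheme_repeat1,
      base_models = lapply(model$base_models, model_to_list)))
  }
  stopifnot(inherits(model, "ems_model"))
  fit <- switch(model$architecture,
    glm = list(coef = model$fit_state$coef),
    nnet = list(wts = model$fit_state$wts, p = model$fit_state$p,
                size = model$fit_state$size),
    naive_bayes = {
      fs <- model$fit_state
      list(prior = fs$prior, usekernel = fs$usekernel,
           per_class = lapply(fs$per_class, function(pc) {
             list(mean = unname(pc$mean), sd = unname(pc$sd),
                  dens = lapply(pc$dens %||% list(), function(d) {
                    if (is.null(d)) NULL else list(x = d$x, y = d$y)
                  }))
           }))
    },
    xgb_tree = list(booster_json = rawToChar(model$fit_state)))
  list(type = "ems_model",
       architecture = model$architecture,
       fixed_params = model$spec$fixed_params,
       chosen_hyperparameters = model$chosen_hyperparameters,
       cv = unclass(model$cv),
       cv_trace = model$cv_trace,
       oof_predictions = as.list(model$oof_predictions),
       feature_names = model$feature_names,
       n_train = model$n_train,
       fold_scheme = model$fold_scheme,
       labels = model$labels,
       fit = fit)
}

#' Load a model saved by [save_model()]
#' @param path JSON file path.
#' @return An `ems_model` or `ems_ensemble`.
#' @export
load_model <- function(path) {
  model_from_list(jsonlite::fromJSON(path, simplifyVector = TRUE,
                                     simplifyDataFrame = FALSE,
                                     simplifyMatrix = FALSE))
}

model_from_list <- function(obj) {
  if (identical(obj$type, "ems_ensemble")) {
    base <- lapply(obj$base_models, model_from_list)
    cf <- as.numeric(obj$combiner)
    return(structure(list(
      base_models = base,
      combiner = cf,
      combiner_named = stats::setNames(cf, obj$combiner_names),
      training_meta = list(seed = obj$seed, n_train = obj$n_train,
                           fold_scheme_repeat1 = as.integer(obj$fold_scheme_repeat1))),
      class = "ems_ensemble"))
  }
  stopifnot(identical(obj$type, "ems_model"))
  arch <- obj$architecture
  fit <- switch(arch,
    glm = list(coef = as.numeric(obj$fit$coef)),
    nnet = list(wts = as.numeric(obj$fit$wts), p = as.integer(obj$fit$p),
                size = as.integer(obj$fit$size)),
    naive_bayes = {
      pcs <- obj$fit$per_class
      list(prior = as.numeric(obj$fit$prior),
           usekernel = isTRUE(obj$fit$usekernel),
           classes = c(0L, 1L),
           per_class = lapply(pcs, function(pc) {
             dens <- pc$dens
             if (!is.null(dens) && length(dens)) {
               dens <- lapply(dens, function(d) {
                 if (is.null(d) || !length(d)) NULL
                 else list(x = as.numeric(d$x), y = as.numeric(d$y))
               })
             } else dens <- NULL
             list(mean = as.numeric(pc$mean), sd = as.numeric(pc$sd), dens = dens)
           }))
    },
    xgb_tree = charToRaw(obj$fit$booster_json))
  structure(list(
    spec = model_spec(arch, fixed_params = as.list(obj$fixed_params)),
    architecture = arch,
    chosen_hyperparameters = obj$chosen_hyperparameters,
    cv_trace = as.data.frame(obj$cv_trace, stringsAsFactors = FALSE),
    oof_predictions = unlist(obj$oof_predictions),
    fit_state = fit,
    feature_names = obj$feature_names,
    n_train = obj$n_train,
    cv = do.call(cv_config, obj$cv[c("k", "repeats", "search_n", "seed")]),
    fold_scheme = lapply(obj$fold_scheme, as.integer),
    labels = as.integer(obj$labels)
  ), class = "ems_model")
}
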