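#' Fit a linear stacking ensemble on out-of-fold probabilities
#'
#' The combiner is an unpenalized logistic regression of the training
#' labels on the matrix of base-model out-of-fold probabilities (intercept
#' included, coefficients unconstrained) — the linear stacking approach.
#' Base models must have been trained on identical records and identical
#' fold assignments, so the combiner never sees an in-sample base
#' prediction. Perfectly collinear bases (e.g. two identical models) get
#' aliased coefficients that are treated as zero, leaving the ensemble's
#' predictions well defined and invariant to how weight is split between
#' them.
#'
#' @param base_models list of [train_model()] objects (>= 1).
#' @param labels binary training labels, aligned with the base models'
#'   training records.
#' @param seed integer seed recorded in the training metadata (the fit
#'   itself is deterministic).
#' @return An `ems_ensemble`.
#' @export
fit_ensemble <- function(base_models, labels, seed = 1L) {
  if (!length(base_models)) stop("need at least 1 base model")
  if (!all(vapply(base_models, inherits, logical(1), "ems_model"))) {
    stop("base_models must all be ems_model objects")
  }
  labels <- check_binary_labels(labels)
  ids <- names(base_models[[1]]$oof_predictions)
  for (m in base_models[-1]) {
    if (!identical(names(m$oof_predictions), ids)) {
      stop("base models were trained on mismatched record sets")
    }
    if (!identical(m$fold_scheme[[1]], base_models[[1]]$fold_scheme[[1]])) {
      stop("base models were trained on different fold assignments")
    }
  }
  if (length(labels) != length(ids)) stop("labels misaligned with base models")
  Z <- vapply(base_models, function(m) unname(m$oof_predictions),
              numeric(length(ids)))
  Z <- matrix(Z, nrow = length(ids))
  fit <- suppressWarnings(stats::glm.fit(cbind(1, Z), labels,
                                         family = stats::binomial()))
  cf <- fit$coefficients
  cf[is.na(cf)] <- 0
  names(cf) <- c("(Intercept)",
                 vapply(base_models, function(m) m$architecture, character(1)))
  structure(list(base_models = base_models,
                 combiner = unname(cf),
                 combiner_named = cf,
                 training_meta = list(seed = as.integer(seed),
                                      n_train = length(ids),
                                      fold_scheme_repeat1 = base_models[[1]]$fold_scheme[[1]])),
            class = "ems_ensemble")
}

#' Predict ensemble probabilities
#'
#' `logistic(intercept + sum(coef * base probability))`, with base
#' probabilities from each base model's own prediction on `newdata`.
#'
#' @param object an `ems_ensemble`.
#' @param newdata feature matrix valid for every base model.
#' @param ... unused.
#' @return Probability vector, deterministic.
#' @export
predict.ems_ensemble <- function(object, newdata, ...) {
  P <- vapply(object$base_models, function(m) stats::predict(m, newdata),
              numeric(nrow(as.matrix(newdata))))
  P <- matrix(P, nrow = nrow(as.matrix(newdata)))
  drop(stats::plogis(cbind(1, P) %*% object$combiner))
}

#' @export
print.ems_ensemble <- function(x, ...) {
  archs <- vapply(x$base_models, function(m) m$architecture, character(1))
  cat(sprintf("ems_ensemble: linear stack of %d base model(s) [%s]\n",
              length(archs), paste(archs, collapse = ", ")))
  cat("  combiner coefficients:\n")
  print(round(x$combiner_named, 4))
  invisible(x)
}

#' @export
coef.ems_ensemble <- function(object, ...) object$combiner_named

#' @export
summary.ems_ensemble <- function(object, ...) {
  print(object)
  oof_auc <- vapply(object$base_models, function(m) {
    auroc(m$oof_predictions, m$labels)
  }, numeric(1))
  cat("  base-model out-of-fold AUROC:\n")
  print(round(stats::setNames(oof_auc,
                              vapply(object$base_models, function(m) m$architecture,
                                     character(1))), 4))
  invisible(oof_auc)
}
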