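#' Specify a base learner
#'
#' Four architectures are supported: `"glm"` (maximum-likelihood logistic
#' regression; optional tiny ridge via `fixed_params$ridge` for separable
#' data), `"nnet"` (single-hidden-layer feed-forward network with logistic
#' output, tuned over hidden size 1..10 and weight decay 10^[-5, 0]),
#' `"naive_bayes"` (Gaussian class-conditionals with a variance floor and
#' a tuned kernel-density flag), and `"xgb_tree"` (gradient-boosted trees
#' tuned over rounds, depth, learning rate, and row/column subsampling).
#'
#' @param architecture one of `"glm"`, `"nnet"`, `"naive_bayes"`,
#'   `"xgb_tree"`.
#' @param hyperparameter_space optional override of the random-search
#'   space; a function `(n, seed) -> data.frame` of candidates.
#' @param fixed_params list of fixed engine parameters (e.g. `ridge`,
#'   `maxit`).
#' @return A `model_spec`.
#' @export
model_spec <- function(architecture = c("glm", "nnet", "naive_bayes", "xgb_tree"),
                       hyperparameter_space = NULL, fixed_params = list()) {
  architecture <- match.arg(architecture)
  structure(list(architecture = architecture,
                 hyperparameter_space = hyperparameter_space,
                 fixed_params = fixed_params),
            class = "model_spec")
}

#' Cross-validation and random-search configuration
#'
#' Repeated stratified k-fold cross-validation with random-search
#' hyperparameter optimization selected on AUROC. Defaults follow the
#' training protocol: k = 5 folds, 10 repeats, 30 random-search draws.
#'
#' @param k folds (>= 2).
#' @param repeats CV repeats (>= 1).
#' @param search_n random-search draws (>= 1; architectures with a finite
#'   grid smaller than this use the full grid).
#' @param seed integer seed controlling folds, search draws and fits.
#' @return A `cv_config`.
#' @export
cv_config <- function(k = 5L, repeats = 10L, search_n = 30L, seed = 1L) {
  stopifnot(k >= 2L, repeats >= 1L, search_n >= 1L)
  structure(list(k = as.integer(k), repeats = as.integer(repeats),
                 search_n = as.integer(search_n), metric = "AUROC",
                 seed = as.integer(seed)),
            class = "cv_config")
}

# stratified fold assignments, one integer vector per repeat; identical
# across candidate draws so candidates are compared on the same folds
make_folds <- function(labels, k, repeats, seed) {
  with_rng(seed, {
    lapply(seq_len(repeats), function(r) {
      fold <- integer(length(labels))
      for (cls in unique(labels)) {
        idx <- which(labels == cls)
        fold[idx] <- sample(rep_len(seq_len(k), length(idx)))
      }
      fold
    })
  })
}

draw_candidates <- function(spec, n, seed) {
  if (!is.null(spec$hyperparameter_space)) {
    return(spec$hyperparameter_space(n, seed))
  }
  switch(spec$architecture,
    glm = data.frame(intercept = TRUE),   # no tunable parameters: grid of 1
    naive_bayes = data.frame(usekernel = c(FALSE, TRUE)),
    nnet = with_rng(seed, data.frame(
      size = sample(1:10, n, replace = TRUE),
      decay = 10^stats::runif(n, -5, 0))),
    xgb_tree = with_rng(seed, data.frame(
      nrounds = sample(50:300, n, replace = TRUE),
      max_depth = sample(1:6, n, replace = TRUE),
      eta = 10^stats::runif(n, -2, -0.5),
      subsample = stats::runif(n, 0.5, 1),
      colsample_bytree = stats::runif(n, 0.5, 1)))
  )
}

# smaller-model-first tie-break key, two components, lexicographic
complexity_key <- function(arch, params) {
  switch(arch,
    glm = c(0, 0),
    naive_bayes = c(as.numeric(params$usekernel), 0),
    nnet = c(params$size, -params$decay),
    xgb_tree = c(params$nrounds * params$max_depth, params$eta))
}

# ---- fit engines ------------------------------------------------------------

# ridge-penalized IRLS for logistic regression (used only when ridge > 0)
ridge_logistic <- function(x, y, lambda, maxit = 50) {
  X <- cbind(1, x)
  beta <- numeric(ncol(X))
  pen <- diag(c(0, rep(lambda, ncol(x))), ncol(X))
  for (it in seq_len(maxit)) {
    eta <- drop(X %*% beta)
    mu <- stats::plogis(eta)
    w <- pmax(mu * (1 - mu), 1e-10)
    z <- eta + (y - mu) / w
    beta_new <- solve(crossprod(X * sqrt(w)) + pen, crossprod(X, w * z))
    if (max(abs(beta_new - beta)) < 1e-10) { beta <- drop(beta_new); break }
    beta <- drop(beta_new)
  }
  beta
}

nb_fit <- function(x, y, usekernel = FALSE) {
  classes <- c(0L, 1L)
  overall_sd <- apply(x, 2, stats::sd)
  floor_sd <- pmax(1e-6, 0.001 * overall_sd)
  per_class <- lapply(classes, function(cls) {
    xc <- x[y == cls, , drop = FALSE]
    mean <- colMeans(xc)
    sd <- pmax(apply(xc, 2, stats::sd), floor_sd)
    sd[is.na(sd)] <- floor_sd[is.na(sd)]
    dens <- NULL
    if (usekernel) {
      dens <- lapply(seq_len(ncol(xc)), function(j) {
        v <- xc[, j]
        if (length(unique(v)) < 2L) return(NULL)  # degenerate: Gaussian fallback
        stats::density(v)
      })
    }
    list(mean = mean, sd = sd, dens = dens)
  })
  list(prior = c(mean(y == 0L), mean(y == 1L)), classes = classes,
       per_class = per_class, usekernel = usekernel)
}

nb_predict <- function(fit, x) {
  loglik <- sapply(seq_along(fit$classes), function(ci) {
    pc <- fit$per_class[[ci]]
    ll <- log(fit$prior[ci])
    for (j in seq_len(ncol(x))) {
      d <- if (fit$usekernel && !is.null(pc$dens[[j]])) {
        dj <- pc$dens[[j]]
        pmax(stats::approx(dj$x, dj$y, xout = x[, j], rule = 2)$y, 1e-10)
      } else {
        pmax(stats::dnorm(x[, j], pc$mean[j], pc$sd[j]), 1e-300)
      }
      ll <- ll + log(d)
    }
    ll
  })
  if (is.null(dim(loglik))) loglik <- matrix(loglik, nrow = 1)
  # stable posterior for the positive class
  m <- pmax(loglik[, 1], loglik[, 2])
  e0 <- exp(loglik[, 1] - m)
  e1 <- exp(loglik[, 2] - m)
  e1 / (e0 + e1)
}

# single-hidden-layer logistic forward pass from an nnet weight vector,
# layout: per hidden unit (bias, inputs...), then output (bias, hiddens...)
nnet_forward <- function(wts, p, size, x) {
  n_h <- size * (p + 1)
  W <- matrix(wts[seq_len(n_h)], nrow = p + 1, ncol = size)
  v <- wts[n_h + seq_len(size + 1)]
  H <- stats::plogis(cbind(1, x) %*% W)
  drop(stats::plogis(cbind(1, H) %*% v))
}

fit_engine <- function(arch, x, y, params, fixed, seed) {
  switch(arch,
    glm = {
      ridge <- fixed$ridge %||% 0
      if (ridge > 0) {
        list(coef = ridge_logistic(x, y, ridge))
      } else {
        fit <- suppressWarnings(stats::glm.fit(cbind(`(Intercept)` = 1, x), y,
                                               family = stats::binomial()))
        cf <- fit$coefficients
        cf[is.na(cf)] <- 0   # aliased columns contribute nothing
        list(coef = unname(cf))
      }
    },
    naive_bayes = nb_fit(x, y, usekernel = isTRUE(params$usekernel)),
    nnet = {
      maxit <- fixed$maxit %||% 200L
      fit <- with_rng(seed, nnet::nnet(x = x, y = y, size = params$size,
                                       decay = params$decay, maxit = maxit,
                                       entropy = TRUE, trace = FALSE,
                                       MaxNWts = 100000L))
      list(wts = fit$wts, p = ncol(x), size = params$size)
    },
    xgb_tree = {
      dtrain <- xgboost::xgb.DMatrix(x, label = y, nthread = 1)
      xgboost::xgb.train(
        params = list(objective = "binary:logistic",
                      max_depth = params$max_depth, eta = params$eta,
                      subsample = params$subsample,
                      colsample_bytree = params$colsample_bytree,
                      nthread = 1, seed = seed),
        data = dtrain, nrounds = params$nrounds, verbose = 0)
    })
}

predict_engine <- function(arch, fit, x) {
  switch(arch,
    glm = drop(stats::plogis(cbind(1, x) %*% fit$coef)),
    naive_bayes = nb_predict(fit, x),
    nnet = nnet_forward(fit$wts, fit$p, fit$size, x),
    xgb_tree = {
      if (is.raw(fit)) fit <- xgboost::xgb.load.raw(fit)
      stats::predict(fit, xgboost::xgb.DMatrix(x, nthread = 1))
    })
}

#' Train a base learner with repeated CV and random search
#'
#' Every candidate hyperparameter draw is evaluated on the same stratified
#' fold assignments; the candidate with the highest mean cross-validated
#' AUROC wins (ties go to the smaller model by a per-architecture
#' complexity key, then to the earlier draw). The final model is refit on
#' all training rows with the winning hyperparameters. Out-of-fold
#' probabilities from the first CV repeat of the winning candidate are
#' retained — they are the stacking inputs for [fit_ensemble()].
#' Fully deterministic for a fixed `cv$seed`.
#'
#' @param features numeric matrix with unique column names, rows aligned
#'   with `labels`, no missing cells.
#' @param labels binary labels (both classes required).
#' @param spec a [model_spec()].
#' @param cv a [cv_config()].
#' @return An `ems_model` with `chosen_hyperparameters`, `cv_trace`,
#'   `oof_predictions`, and the refit state.
#' @export
train_model <- function(features, labels, spec, cv = cv_config()) {
  stopifnot(inherits(spec, "model_spec"), inherits(cv, "cv_config"))
  labels <- check_binary_labels(labels)
  features <- as.matrix(features)
  if (is.null(colnames(features)) || anyDuplicated(colnames(features))) {
    stop("features must have unique column names")
  }
  if (nrow(features) != length(labels)) stop("features and labels are misaligned")
  if (anyNA(features)) stop("features must have no missing cells")
  arch <- spec$architecture
  folds <- make_folds(labels, cv$k, cv$repeats, derive_seed(cv$seed, "folds"))
  cand <- draw_candidates(spec, cv$search_n, derive_seed(cv$seed, "search"))
  n_cand <- nrow(cand)
  n <- nrow(features)
  mean_auc <- sd_auc <- numeric(n_cand)
  oof_by_cand <- matrix(NA_real_, nrow = n, ncol = n_cand)
  for (ci in seq_len(n_cand)) {
    params <- as.list(cand[ci, , drop = FALSE])
    fold_aucs <- numeric(0)
    for (r in seq_len(cv$repeats)) {
      fold <- folds[[r]]
      for (f in seq_len(cv$k)) {
        hold <- fold == f
        fit <- fit_engine(arch, features[!hold, , drop = FALSE], labels[!hold],
                          params, spec$fixed_params,
                          derive_seed(cv$seed, paste("fit", ci, r, f)))
        pred <- predict_engine(arch, fit, features[hold, , drop = FALSE])
        fold_aucs <- c(fold_aucs, auroc(pred, labels[hold]))
        if (r == 1L) oof_by_cand[hold, ci] <- pred
      }
    }
    mean_auc[ci] <- mean(fold_aucs)
    sd_auc[ci] <- stats::sd(fold_aucs)
  }
  comp <- t(vapply(seq_len(n_cand), function(ci) {
    complexity_key(arch, as.list(cand[ci, , drop = FALSE]))
  }, numeric(2)))
  winner <- order(-mean_auc, comp[, 1], comp[, 2], seq_len(n_cand))[1]
  chosen <- as.list(cand[winner, , drop = FALSE])
  final <- fit_engine(arch, features, labels, chosen, spec$fixed_params,
                      derive_seed(cv$seed, "final"))
  if (arch == "xgb_tree") final <- xgboost::xgb.save.raw(final, raw_format = "json")
  trace <- cand
  trace$mean_auc <- mean_auc
  trace$sd_auc <- sd_auc
  structure(list(
    spec = spec,
    architecture = arch,
    chosen_hyperparameters = chosen,
    cv_trace = trace,
    oof_predictions = stats::setNames(oof_by_cand[, winner], rownames(features)),
    fit_state = final,
    feature_names = colnames(features),
    n_train = n,
    cv = cv,
    fold_scheme = folds,
    labels = labels
  ), class = "ems_model")
}

check_feature_columns <- function(feature_names, features) {
  features <- as.matrix(features)
  have <- colnames(features)
  missing <- setdiff(feature_names, have)
  extra <- setdiff(have, feature_names)
  if (length(missing) || length(extra)) {
    stop(sprintf("feature column mismatch%s%s",
                 if (length(missing)) paste0("; missing: ", paste(missing, collapse = ", ")) else "",
                 if (length(extra)) paste0("; unexpected: ", paste(extra, collapse = ", ")) else ""))
  }
  features[, feature_names, drop = FALSE]
}

#' Predict class probabilities from a trained model
#'
#' @param object an `ems_model`.
#' @param newdata numeric feature matrix whose columns match the training
#'   columns by name (order-insensitive); mismatches are an error naming
#'   the offending columns.
#' @param ... unused.
#' @return Probability vector in `[0, 1]`, deterministic.
#' @export
predict.ems_model <- function(object, newdata, ...) {
  x <- check_feature_columns(object$feature_names, newdata)
  p <- predict_engine(object$architecture, object$fit_state, x)
  pmin(pmax(as.numeric(p), 0), 1)
}

#' @rdname predict.ems_model
#' @param model an `ems_model` or `ems_ensemble`.
#' @param features feature matrix.
#' @export
predict_proba <- function(model, features) {
  stats::predict(model, features)
}

#' @export
print.ems_model <- function(x, ...) {
  hp <- x$chosen_hyperparameters
  hp_str <- if (length(hp)) paste(sprintf("%s=%s", names(hp),
                                          vapply(hp, function(v) format(v, digits = 4), character(1))),
                                  collapse = ", ") else "none"
  cat(sprintf("ems_model [%s]: trained on %d records x %d features\n",
              x$architecture, x$n_train, length(x$feature_names)))
  cat(sprintf("  chosen hyperparameters: %s\n", hp_str))
  cat(sprintf("  CV (k=%d, repeats=%d): best mean AUROC %.4f over %d candidate(s)\n",
              x$cv$k, x$cv$repeats, max(x$cv_trace$mean_auc), nrow(x$cv_trace)))
  invisible(x)
}

#' @export
summary.ems_model <- function(object, ...) {
  print(object)
  cat("candidate trace (mean/sd CV AUROC):\n")
  print(object$cv_trace, digits = 4)
  invisible(object$cv_trace)
}

#' @export
coef.ems_model <- function(object, ...) {
  if (object$architecture != "glm") {
    stop("coefficients are only defined for the glm architecture")
  }
  stats::setNames(object$fit_state$coef, c("(Intercept)", object$feature_names))
}
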