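# Thin adapters around off-the-shelf classifier backends.  The pipeline
# only needs one contract: fit on (X, y), then produce a continuous
# PD-score per subject (higher = more PD-like), deterministically for a
# given seed.

.classifier_kinds <- c("logreg", "svm", "random_forest", "gradient_boosting")

#' Train a scoring classifier
#'
#' @param kind one of `"logreg"` (penalised logistic regression, glmnet),
#'   `"svm"` (e1071), `"random_forest"` (ranger, probability forest) or
#'   `"gradient_boosting"` (xgboost).
#' @param hyperparams named list of backend hyperparameters; missing
#'   entries fall back to defaults.  See [sample_search_config()] for the
#'   searched ranges.
#' @param X numeric feature matrix, subjects x features.
#' @param y labels (`"PD"`/`"HV"`); both classes required.
#' @param seed integer seed controlling every stochastic element of the
#'   fit.
#' @return a `scoring_model`; `predict()` returns continuous PD-scores.
#' @export
train_classifier <- function(kind, hyperparams = list(), X, y, seed = 1L) {
  kind <- match.arg(tolower(kind), .classifier_kinds)
  X <- as.matrix(X)
  y <- factor(.as_pd(y), levels = c(FALSE, TRUE), labels = c("HV", "PD"))
  if (nlevels(droplevels(y)) < 2) {
    stop("training labels contain a single class")
  }
  hp <- hyperparams
  fit <- .with_seed(seed, switch(kind,
    logreg = {
      lambda <- hp$lambda %||% 0.01
      glmnet::glmnet(X, y, family = "binomial", alpha = hp$alpha %||% 0,
                     lambda = sort(unique(lambda * c(10, 5, 2, 1)),
                                   decreasing = TRUE),
                     standardize = TRUE)
    },
    svm = e1071::svm(X, y, kernel = hp$kernel %||% "radial",
                     cost = hp$cost %||% 1,
                     gamma = hp$gamma %||% (1 / ncol(X)),
                     scale = apply(X, 2, stats::sd) > 0),
    random_forest = ranger::ranger(
      y = y, x = as.data.frame(X), probability = TRUE,
      num.trees = hp$num_trees %||% 200,
      mtry = max(1, floor((hp$mtry_frac %||% 0.3) * ncol(X))),
      min.node.size = hp$min_node_size %||% 5,
      seed = seed, num.threads = 1),
    gradient_boosting = xgboost::xgb.train(
      params = list(max_depth = hp$max_depth %||% 3,
                    eta = hp$eta %||% 0.1,
                    subsample = hp$subsample %||% 1,
                    objective = "binary:logistic",
                    nthread = 1, seed = seed),
      data = xgboost::xgb.DMatrix(X, label = as.numeric(y == "PD"),
                                  nthread = 1),
      nrounds = hp$nrounds %||% 100, verbose = 0)))
  structure(list(kind = kind, fit = fit, hyperparams = hp,
                 feature_names = colnames(X), seed = seed),
            class = "scoring_model")
}

#' @export
print.scoring_model <- function(x, ...) {
  cat("scoring_model:", x$kind, "on", length(x$feature_names), "features\n")
  invisible(x)
}

#' Continuous PD-scores from a trained classifier
#'
#' @param object a `scoring_model`.
#' @param newdata feature matrix or [feature_table] with the training
#'   feature columns.
#' @param ... unused.
#' @return numeric vector of scores, higher = more PD-like.
#' @export
predict.scoring_model <- function(object, newdata, ...) {
  X <- if (is_feature_table(newdata)) {
    as.matrix(newdata[, object$feature_names, drop = FALSE])
  } else {
    as.matrix(newdata)[, object$feature_names, drop = FALSE]
  }
  switch(object$kind,
    logreg = as.vector(stats::predict(
      object$fit, X, s = min(object$fit$lambda), type = "link")),
    svm = {
      dv <- attr(stats::predict(object$fit, X, decision.values = TRUE),
                 "decision.values")
      # e1071 orients decision values toward the first class of the
      # column label; flip so positive always means PD
      if (startsWith(colnames(dv)[1], "PD")) as.vector(dv) else -as.vector(dv)
    },
    random_forest = stats::predict(
      object$fit, as.data.frame(X), num.threads = 1)$predictions[, "PD"],
    gradient_boosting = stats::predict(
      object$fit, xgboost::xgb.DMatrix(X, nthread = 1)))
}
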