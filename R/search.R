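# Random hyperparameter search over classifier x balancing x
# harmonization configurations, evaluated by cross-validated AUC, with a
# single test-set evaluation of the selected best trial.
#
# The hyperparameter ranges sampled here are package defaults chosen to
# span the usual operating range of each backend; they are not tied to
# any particular published grid.

#' Define a hyperparameter search space
#'
#' @param classifiers classifier kinds to sample from (see
#'   [train_classifier()]).
#' @param strategies harmonization strategies to sample from (see
#'   [harmonization_strategies()]).
#' @param feature_sets feature families to sample from
#'   (see [prepare_features()]).
#' @param etiv_correct apply eTIV correction in feature preparation.
#' @param balance_methods,balance_by,flip_options balancing options to
#'   sample from.
#' @param n_iter number of sampled configurations (>= 1).
#' @param seed integer seed; drives configuration sampling and every
#'   fit's seed.
#' @return a `search_space`.
#' @export
search_space <- function(classifiers = .classifier_kinds,
                         strategies = "fit_train_only",
                         feature_sets = "DOJ_PLUS_FS",
                         etiv_correct = FALSE,
                         balance_methods = c("none", "smote", "rus"),
                         balance_by = c("group", "group_x_scanner"),
                         flip_options = c(FALSE, TRUE),
                         n_iter = 200L, seed = 1L) {
  stopifnot(n_iter >= 1,
            all(classifiers %in% .classifier_kinds),
            all(strategies %in% .strategies))
  structure(list(classifiers = classifiers, strategies = strategies,
                 feature_sets = feature_sets, etiv_correct = etiv_correct,
                 balance_methods = balance_methods, balance_by = balance_by,
                 flip_options = flip_options, n_iter = as.integer(n_iter),
                 seed = as.integer(seed)),
            class = "search_space")
}

.sample1 <- function(x) if (length(x) == 1) x else x[sample.int(length(x), 1)]

#' Draw one fully specified configuration from a search space
#'
#' Uses the current RNG state; [random_search()] wraps it under the
#' space's seed.
#'
#' @param space a [search_space].
#' @return a named list: classifier kind, hyperparameters, strategy,
#'   feature set and balancing recipe.
#' @export
sample_search_config <- function(space) {
  kind <- .sample1(space$classifiers)
  hp <- switch(kind,
    logreg = list(alpha = stats::runif(1),
                  lambda = 10^stats::runif(1, -4, 1)),
    svm = list(kernel = .sample1(c("linear", "radial")),
               cost = 10^stats::runif(1, -2, 2),
               gamma = 10^stats::runif(1, -4, 0)),
    random_forest = list(num_trees = sample(50:500, 1),
                         mtry_frac = stats::runif(1, 0.1, 0.9),
                         min_node_size = sample(1:10, 1)),
    gradient_boosting = list(nrounds = sample(50:300, 1),
                             max_depth = sample(2:8, 1),
                             eta = 10^stats::runif(1, -2, -0.3),
                             subsample = stats::runif(1, 0.5, 1)))
  list(classifier = kind, hyperparams = hp,
       strategy = .sample1(space$strategies),
       feature_set = .sample1(space$feature_sets),
       balance_method = .sample1(space$balance_methods),
       balance_by = .sample1(space$balance_by),
       flip = .sample1(space$flip_options),
       smote_k = 5L)
}

.derived_seed <- function(seed, trial, fold = 0L) {
  as.integer((as.double(seed) + 1009 * trial + 101 * fold) %% 2147483629)
}

# evaluate one configuration across the plan's folds
.eval_config <- function(config, table, plan, space, trial_idx,
                         use_age = TRUE, use_sex = TRUE, min_batch = 4) {
  tbl <- prepare_features(table, config$feature_set,
                          etiv_correct = space$etiv_correct)
  n_folds <- length(plan$folds)
  fold_aucs <- rep(NA_real_, n_folds)
  valid_scores <- numeric(0)
  for (f in seq_len(n_folds)) {
    h <- suppressMessages(
      harmonize_splits(config$strategy, tbl, plan, fold = f,
                       use_age = use_age, use_sex = use_sex,
                       min_batch = min_batch))
    fold <- plan$folds[[f]]
    train <- .ft_rows(h, h$subject_id %in% fold$train_ids)
    valid <- .ft_rows(h, h$subject_id %in% fold$valid_ids)
    fseed <- .derived_seed(space$seed, trial_idx, f)
    bal <- balance_training_set(train, balance_config(
      config$balance_method, config$balance_by, config$flip,
      config$smote_k, seed = fseed))
    model <- train_classifier(config$classifier, config$hyperparams,
                              feature_matrix(bal), bal$group, seed = fseed)
    sc <- predict(model, valid)
    fold_aucs[f] <- roc_auc(sc, valid$group)
    valid_scores <- c(valid_scores, stats::setNames(sc, valid$subject_id))
  }
  list(config = config, fold_aucs = fold_aucs,
       mean_auc = mean(fold_aucs), sd_auc = stats::sd(fold_aucs),
       valid_scores = valid_scores, failed = FALSE, error = NULL)
}

#' Random hyperparameter search with leakage-safe per-fold harmonization
#'
#' Samples `space$n_iter` configurations.  Each is evaluated fold by
#' fold: the harmonization model is fitted on the fold's designated fit
#' set (for `fit_train_only*` strategies, that fold's training rows),
#' the training fold alone is balanced/augmented, a classifier is fitted
#' and scored on the fold's validation set.  Only the best configuration
#' (highest mean validation AUC; ties broken by earliest trial) is then
#' refitted on all non-test rows and scored once on the held-out test
#' set.  A failing trial is recorded and the search continues.
#'
#' @param space a [search_space].
#' @param table the full (unprepared) [feature_table].
#' @param plan a [split_plan] with folds (and usually a test holdout).
#' @param use_age,use_sex harmonization covariates.
#' @param min_batch minimum scanner size for fold-level harmonization
#'   fits.
#' @return a `search_result`: list of `trials`, `best_index`, and `best`
#'   (the winning trial with `test_auc` and pooled validation scores).
#' @export
random_search <- function(space, table, plan, use_age = TRUE,
                          use_sex = TRUE, min_batch = 4) {
  stopifnot(inherits(space, "search_space"))
  validate_split_plan(plan, table)
  configs <- .with_seed(space$seed, {
    lapply(seq_len(space$n_iter), function(i) sample_search_config(space))
  })
  trials <- vector("list", space$n_iter)
  for (t in seq_len(space$n_iter)) {
    trials[[t]] <- tryCatch(
      .eval_config(configs[[t]], table, plan, space, t,
                   use_age = use_age, use_sex = use_sex,
                   min_batch = min_batch),
      error = function(e) {
        list(config = configs[[t]], fold_aucs = NA_real_,
             mean_auc = NA_real_, sd_auc = NA_real_,
             valid_scores = numeric(0), failed = TRUE,
             error = conditionMessage(e))
      })
  }
  mean_aucs <- vapply(trials, `[[`, numeric(1), "mean_auc")
  if (all(is.na(mean_aucs))) {
    stop("all ", space$n_iter, " trials failed; first error: ",
         trials[[1]]$error)
  }
  best_idx <- which.max(mean_aucs)  # earliest index wins ties
  best <- trials[[best_idx]]
  if (length(plan$test_ids) > 0) {
    best <- c(best, .test_evaluation(best$config, table, plan, space,
                                     best_idx, use_age, use_sex, min_batch))
  }
  structure(list(trials = trials, best_index = best_idx, best = best),
            class = "search_result")
}

# refit the winning configuration on all non-test rows, score the test set
.test_evaluation <- function(config, table, plan, space, trial_idx,
                             use_age, use_sex, min_batch) {
  tbl <- prepare_features(table, config$feature_set,
                          etiv_correct = space$etiv_correct)
  h <- suppressMessages(
    harmonize_splits(config$strategy, tbl, plan, fold = NULL,
                     use_age = use_age, use_sex = use_sex,
                     min_batch = min_batch))
  non_test <- !(h$subject_id %in% plan$test_ids)
  train <- .ft_rows(h, non_test)
  test <- .ft_rows(h, !non_test)
  fseed <- .derived_seed(space$seed, trial_idx, 0L)
  bal <- balance_training_set(train, balance_config(
    config$balance_method, config$balance_by, config$flip,
    config$smote_k, seed = fseed))
  model <- train_classifier(config$classifier, config$hyperparams,
                            feature_matrix(bal), bal$group, seed = fseed)
  sc <- stats::setNames(predict(model, test), test$subject_id)
  list(test_auc = roc_auc(sc, test$group), test_scores = sc,
       test_report = scanner_specific_report(sc, test$group, test$scanner))
}

#' @export
print.search_result <- function(x, ...) {
  ok <- !vapply(x$trials, `[[`, logical(1), "failed")
  cat("Random search:", length(x$trials), "trials (", sum(!ok), "failed )\n")
  b <- x$best
  cat(sprintf("best: trial %d, %s + %s, mean validation AUC %.3f +/- %s\n",
              x$best_index, b$config$classifier, b$config$strategy,
              b$mean_auc,
              if (is.na(b$sd_auc)) "NA" else sprintf("%.3f", b$sd_auc)))
  if (!is.null(b$test_auc)) cat(sprintf("test AUC: %.3f\n", b$test_auc))
  invisible(x)
}

#' Single-scanner classification experiment
#'
#' Restricts the cohort to one scanner and runs the search with
#' leave-one-out cross-validation, reporting the AUC over the pooled
#' leave-one-out scores.  Harmonization is forced off: with a single
#' site there is no batch structure for ComBat to estimate, so a space
#' requesting any strategy other than `"none"` is an error.
#'
#' @param table a [feature_table].
#' @param scanner_id which scanner to keep.
#' @param space a [search_space] with `strategies = "none"`.
#' @param min_per_class minimum subjects per class (default 4).
#' @return a `single_scanner_result`: the best trial with `auc` over
#'   pooled LOOCV scores.
#' @export
run_single_scanner <- function(table, scanner_id, space,
                               min_per_class = 4) {
  stopifnot(inherits(space, "search_space"))
  if (!all(space$strategies == "none")) {
    stop("single-scanner classification cannot use ComBat harmonization:",
         " there is only a single site; set strategies = \"none\"")
  }
  sub <- .ft_rows(table, table$scanner == scanner_id)
  if (nrow(sub) == 0) stop("unknown scanner: ", scanner_id)
  counts <- table(factor(sub$group, levels = c("HV", "PD")))
  if (any(counts == 0)) {
    stop("scanner ", scanner_id, " has a single class; AUC undefined")
  }
  if (any(counts < min_per_class)) {
    stop("scanner ", scanner_id, " has fewer than ", min_per_class,
         " subjects in a class")
  }
  plan <- make_cv_folds(sub, k = "loocv", seed = space$seed)
  configs <- .with_seed(space$seed, {
    lapply(seq_len(space$n_iter), function(i) sample_search_config(space))
  })
  trials <- vector("list", space$n_iter)
  for (t in seq_len(space$n_iter)) {
    trials[[t]] <- tryCatch({
      cfg <- configs[[t]]
      tbl <- prepare_features(sub, cfg$feature_set,
                              etiv_correct = space$etiv_correct)
      scores <- vapply(seq_along(plan$folds), function(f) {
        fold <- plan$folds[[f]]
        train <- .ft_rows(tbl, tbl$subject_id %in% fold$train_ids)
        valid <- .ft_rows(tbl, tbl$subject_id %in% fold$valid_ids)
        fseed <- .derived_seed(space$seed, t, f)
        bal <- balance_training_set(train, balance_config(
          cfg$balance_method, cfg$balance_by, cfg$flip, cfg$smote_k,
          seed = fseed))
        model <- train_classifier(cfg$classifier, cfg$hyperparams,
                                  feature_matrix(bal), bal$group,
                                  seed = fseed)
        predict(model, valid)
      }, numeric(1))
      ids <- vapply(plan$folds, function(f) f$valid_ids, character(1))
      labels <- sub$group[match(ids, sub$subject_id)]
      list(config = cfg, auc = roc_auc(scores, labels),
           scores = stats::setNames(scores, ids), failed = FALSE)
    }, error = function(e) {
      list(config = configs[[t]], auc = NA_real_, failed = TRUE,
           error = conditionMessage(e))
    })
  }
  aucs <- vapply(trials, `[[`, numeric(1), "auc")
  if (all(is.na(aucs))) stop("all single-scanner trials failed")
  best_idx <- which.max(aucs)
  structure(list(scanner_id = scanner_id, trials = trials,
                 best_index = best_idx, best = trials[[best_idx]],
                 auc = aucs[best_idx], n = nrow(sub)),
            class = "single_scanner_result")
}

#' @export
print.single_scanner_result <- function(x, ...) {
  cat(sprintf("single-scanner classifier [%s]: pooled LOOCV AUC %.3f (n = %d)\n",
              x$scanner_id, x$auc, x$n))
  invisible(x)
}

#' Multi-scanner classification experiment
#'
#' The full pipeline: eligibility filter, stratified test holdout,
#' group-stratified CV folds, random hyperparameter search under the
#' given harmonization strategy, one test evaluation of the winning
#' trial, and scanner-specific reports for both the pooled validation
#' scores and the test scores.
#'
#' @param table a [feature_table] covering at least two eligible
#'   scanners.
#' @param strategy harmonization strategy for the whole search (one of
#'   [harmonization_strategies()]).
#' @param space a [search_space]; its `strategies` entry is overridden
#'   by `strategy`.
#' @param test_fraction held-out test fraction.
#' @param k number of CV folds.
#' @param min_hv,min_pd scanner eligibility thresholds.
#' @param use_age,use_sex harmonization covariates.
#' @param min_batch minimum scanner size for fold-level harmonization
#'   fits.
#' @return a `multi_scanner_result`: the `search_result` plus
#'   `valid_report` and `test_report` ([scanner_specific_report()]s) and
#'   the [split_plan] used.
#' @export
run_multi_scanner <- function(table, strategy, space, test_fraction = 0.2,
                              k = 5, min_hv = 10, min_pd = 10,
                              use_age = TRUE, use_sex = TRUE,
                              min_batch = 4) {
  stopifnot(inherits(space, "search_space"))
  strategy <- match.arg(tolower(strategy), .strategies)
  elig <- filter_eligible_scanners(table, min_hv = min_hv, min_pd = min_pd)
  n_scanners <- length(unique(elig$scanner))
  if (n_scanners < 2) {
    stop("multi-scanner classification needs >= 2 eligible scanners, got ",
         n_scanners)
  }
  space$strategies <- strategy
  plan <- stratified_holdout(elig, test_fraction, seed = space$seed)
  plan <- make_cv_folds(elig, k = k, seed = space$seed, plan = plan)
  search <- random_search(space, elig, plan, use_age = use_age,
                          use_sex = use_sex, min_batch = min_batch)
  vs <- search$best$valid_scores
  vlab <- elig$group[match(names(vs), elig$subject_id)]
  vscan <- elig$scanner[match(names(vs), elig$subject_id)]
  structure(list(strategy = strategy, search = search, best = search$best,
                 valid_report = scanner_specific_report(vs, vlab, vscan),
                 test_report = search$best$test_report,
                 plan = plan, n_scanners = n_scanners),
            class = "multi_scanner_result")
}

#' @export
print.multi_scanner_result <- function(x, ...) {
  cat("Multi-scanner experiment, strategy:", x$strategy, "\n")
  print(x$search)
  cat("\nvalidation scores by scanner:\n")
  print(x$valid_report)
  invisible(x)
}
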