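# Pipeline drivers on small synthetic cohorts with a true group effect.

search_cohort <- function(seed = 101, effect = 0.8, n_per_group = 15) {
  specs <- list(scanner_spec("sc1", n_per_group, n_per_group, gamma_loc = 0.6),
                scanner_spec("sc2", n_per_group, n_per_group, gamma_loc = -0.6,
                             delta_scale = 1.2),
                scanner_spec("sc3", n_per_group, n_per_group, gamma_loc = 0.2,
                             delta_scale = 0.9))
  generate_cohort(cohort_config(specs, n_features_fs = 12, n_features_doj = 8,
                                group_effect_size = effect, seed = seed))
}

quick_space <- function(n_iter = 2, seed = 31, ...) {
  search_space(classifiers = "logreg", balance_methods = "none",
               flip_options = FALSE, n_iter = n_iter, seed = seed, ...)
}

test_that("a one-trial search selects its sole trial and reports its fold mean", {
  tbl <- search_cohort()
  plan <- make_cv_folds(tbl, k = 3, seed = 1,
                        plan = stratified_holdout(tbl, 0.2, seed = 1))
  res <- random_search(quick_space(n_iter = 1), tbl, plan)
  expect_equal(res$best_index, 1)
  expect_equal(res$best$mean_auc, mean(res$best$fold_aucs))
  expect_equal(res$best$sd_auc, sd(res$best$fold_aucs))
  expect_false(is.null(res$best$test_auc))
})

test_that("the reported best is the argmax over trials and the search is deterministic", {
  tbl <- search_cohort()
  plan <- make_cv_folds(tbl, k = 3, seed = 1,
                        plan = stratified_holdout(tbl, 0.2, seed = 1))
  space <- search_space(classifiers = c("logreg", "random_forest"),
                        balance_methods = c("none", "rus"),
                        flip_options = c(FALSE, TRUE), n_iter = 4, seed = 13)
  r1 <- random_search(space, tbl, plan)
  means <- vapply(r1$trials, `[[`, numeric(1), "mean_auc")
  expect_equal(r1$best_index, which.max(means))
  expect_equal(r1$best$mean_auc, max(means, na.rm = TRUE))
  r2 <- random_search(space, tbl, plan)
  expect_identical(lapply(r1$trials, `[[`, "config"),
                   lapply(r2$trials, `[[`, "config"))
  expect_identical(means, vapply(r2$trials, `[[`, numeric(1), "mean_auc"))
  expect_equal(r1$best$test_auc, r2$best$test_auc)
})

test_that("single-scanner runs force strategy none and use pooled LOOCV", {
  tbl <- search_cohort(effect = 2, n_per_group = 10)
  res <- run_single_scanner(tbl, "sc1",
                            quick_space(n_iter = 4, strategies = "none"))
  expect_s3_class(res, "single_scanner_result")
  expect_equal(res$n, 20)
  expect_equal(res$auc, 1.0)  # strong, separable effect
  expect_error(run_single_scanner(tbl, "sc1",
                                  quick_space(strategies = "fit_train_only")),
               "single site")
  expect_error(run_single_scanner(tbl, "nope",
                                  quick_space(strategies = "none")),
               "unknown")
  # a single-class scanner cannot be scored
  solo <- tbl[tbl$group == "PD", ]; class(solo) <- class(tbl)
  expect_error(run_single_scanner(solo, "sc1",
                                  quick_space(strategies = "none")),
               "single class")
})

test_that("a null single scanner stays in the wide LOOCV chance band", {
  specs <- list(scanner_spec("null1", 18, 18))
  tbl <- generate_cohort(cohort_config(specs, n_features_fs = 10,
                                       n_features_doj = 10,
                                       group_effect_size = 0, seed = 71))
  res <- run_single_scanner(tbl, "null1",
                            quick_space(n_iter = 1, seed = 5,
                                        strategies = "none"))
  expect_gt(res$auc, 0.25)
  expect_lt(res$auc, 0.75)
})

test_that("multi-scanner runs produce per-scanner entries for every eligible scanner", {
  tbl <- search_cohort()
  res <- run_multi_scanner(tbl, "fit_train_only", quick_space(),
                           k = 3, min_hv = 5, min_pd = 5)
  expect_s3_class(res, "multi_scanner_result")
  expect_setequal(res$valid_report$per_scanner$scanner, unique(tbl$scanner))
  expect_false(is.null(res$best$test_auc))
  # a cohort reduced to a single eligible scanner is refused
  one <- tbl[tbl$scanner == "sc1", ]; class(one) <- class(tbl)
  expect_error(run_multi_scanner(one, "none", quick_space(),
                                 min_hv = 5, min_pd = 5),
               ">= 2 eligible")
})

test_that("label-free strategies are untouched by test-label content", {
  # constant-filling the test labels must leave harmonized features and
  # classifier scores bit-identical for none / fit_train_only
  tbl <- search_cohort(seed = 301)
  plan <- make_cv_folds(tbl, k = 3, seed = 3,
                        plan = stratified_holdout(tbl, 0.2, seed = 3))
  is_test <- tbl$subject_id %in% plan$test_ids
  tbl_const <- tbl
  tbl_const$group[is_test] <- "HV"
  for (strategy in c("none", "fit_train_only")) {
    h1 <- harmonize_splits(strategy, tbl, plan, fold = 1)
    h2 <- harmonize_splits(strategy, tbl_const, plan, fold = 1)
    expect_identical(feature_matrix(h1), feature_matrix(h2))
    tr <- h1$subject_id %in% plan$folds[[1]]$train_ids
    m1 <- train_classifier("logreg", list(lambda = 0.05),
                           feature_matrix(h1)[tr, ], h1$group[tr], seed = 9)
    m2 <- train_classifier("logreg", list(lambda = 0.05),
                           feature_matrix(h2)[tr, ], h2$group[tr], seed = 9)
    expect_identical(predict(m1, feature_matrix(h1)[is_test, ]),
                     predict(m2, feature_matrix(h2)[is_test, ]))
  }
})

test_that("failed trials are recorded and the search continues", {
  tbl <- search_cohort()
  plan <- make_cv_folds(tbl, k = 3, seed = 1,
                        plan = stratified_holdout(tbl, 0.2, seed = 1))
  # smote with group_x_scanner on tiny folds produces singleton strata
  # for some trials; those must fail gracefully, not abort the search
  space <- search_space(classifiers = "logreg",
                        balance_methods = c("none", "smote"),
                        balance_by = "group_x_scanner",
                        flip_options = FALSE, n_iter = 6, seed = 17)
  res <- suppressWarnings(random_search(space, tbl, plan))
  expect_length(res$trials, 6)
  expect_false(res$trials[[res$best_index]]$failed)
})
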