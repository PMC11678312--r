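# Harmonization fit-split strategies.
#
# A ComBat model is always *applied* to every row of the table; what
# varies is which rows it is *fitted* on:
#
#   none                 -- no harmonization at all
#   fit_train_only       -- fit on the current fold's training rows
#                           (or, with no fold, on all non-test rows)
#   fit_train_valid      -- fit on all non-test rows
#   fit_all              -- fit on everything, test included (the
#                           transductive setting: test features, though
#                           not labels, inform the transform)
#   fit_train_only_group -- like fit_train_only but with the diagnostic
#                           group as covariate: the transform then needs
#                           the labels of every row it harmonizes,
#                           including validation/test rows.  This is the
#                           deliberate leakage strategy kept to
#                           demonstrate how it inflates AUC.

.strategies <- c("none", "fit_train_only", "fit_train_valid", "fit_all",
                 "fit_train_only_group")

#' Available harmonization strategies
#' @return character vector of strategy names.
#' @export
harmonization_strategies <- function() .strategies

#' Harmonize a table under an explicit fit-split strategy
#'
#' Fits a ComBat model on the subset of rows the strategy designates and
#' transforms the whole table with it.  See the strategy descriptions in
#' the package vignette; `"fit_train_only_group"` requires group labels
#' on every row (the leakage pathway) and errors when validation/test
#' labels have been stripped.
#'
#' @param strategy one of [harmonization_strategies()].
#' @param table the full [feature_table].
#' @param plan a [split_plan] partitioning `table`.
#' @param fold fold index whose training rows are the fit set for the
#'   `fit_train_only*` strategies; `NULL` (default) uses all non-test
#'   rows (the final refit-for-test stage).
#' @param use_age,use_sex covariates of the harmonization design.
#' @param eb_mode,min_batch,tol,max_iter passed to [combat_fit()];
#'   `min_batch` defaults to 4 here because fold-level fit sets are
#'   subsets of the full cohort (the ~20-scans-per-scanner guidance is
#'   enforced where the full model is fitted).
#' @param return_model also return the fitted model.
#' @return the harmonized [feature_table]; if `return_model = TRUE`, a
#'   list `(table, model)`.
#' @export
harmonize_splits <- function(strategy, table, plan, fold = NULL,
                             use_age = TRUE, use_sex = TRUE,
                             eb_mode = "parametric_eb", min_batch = 4,
                             tol = 1e-4, max_iter = 500L,
                             return_model = FALSE) {
  strategy <- match.arg(tolower(strategy), .strategies)
  stopifnot(inherits(plan, "split_plan"))
  if (strategy == "none") {
    return(if (return_model) list(table = table, model = NULL) else table)
  }
  all_ids <- table$subject_id
  non_test <- setdiff(all_ids, plan$test_ids)
  fit_ids <- switch(strategy,
    fit_train_only = ,
    fit_train_only_group = {
      if (is.null(fold)) non_test else {
        stopifnot(fold >= 1, fold <= length(plan$folds))
        plan$folds[[fold]]$train_ids
      }
    },
    fit_train_valid = non_test,
    fit_all = all_ids)
  use_group <- strategy == "fit_train_only_group"
  if (use_group && anyNA(table$group)) {
    stop("strategy fit_train_only_group must know the group label of",
         " every row it harmonizes, including validation/test rows;",
         " labels are missing.  This requirement is exactly why the",
         " strategy leaks.")
  }
  fit_tbl <- .ft_rows(table, all_ids %in% fit_ids)
  model <- combat_fit(fit_tbl, use_age = use_age, use_sex = use_sex,
                      use_group = use_group, eb_mode = eb_mode,
                      min_batch = min_batch, tol = tol, max_iter = max_iter)
  out <- suppressMessages(predict(model, table))
  if (use_group) {
    message("harmonize_splits: label-dependent strategy ", strategy,
            " used group labels of all ", nrow(table), " rows (leakage)")
  }
  if (return_model) list(table = out, model = model) else out
}
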