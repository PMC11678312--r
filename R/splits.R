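# Holdout and cross-validation split plans.
#
# A split_plan is the single source of truth for which subject is test,
# and, per CV fold, which subjects train and which validate.  Every
# harmonization fit-split strategy is expressed against a plan, which is
# what makes leakage auditable: the fit set of each stage is explicit.

#' Construct a split plan
#'
#' @param test_ids character vector of held-out test subject ids.
#' @param folds list of `list(train_ids, valid_ids)` pairs.
#' @param strata_spec variables the holdout was stratified on.
#' @param seed seed the plan was drawn with.
#' @return a `split_plan`.
#' @export
split_plan <- function(test_ids = character(0), folds = list(),
                       strata_spec = character(0), seed = NA_integer_) {
  structure(list(test_ids = as.character(test_ids), folds = folds,
                 strata_spec = strata_spec, seed = seed),
            class = "split_plan")
}

#' @export
print.split_plan <- function(x, ...) {
  cat("Split plan:", length(x$test_ids), "test subjects,",
      length(x$folds), "CV folds",
      if (length(x$strata_spec))
        paste0("(stratified by ", paste(x$strata_spec, collapse = ", "), ")"),
      "\n")
  invisible(x)
}

#' Check that a plan partitions a table
#'
#' Verifies the split invariants: the test set is disjoint from every
#' fold, train and valid are disjoint within each fold, and the folds'
#' validation sets partition the non-test subjects.
#'
#' @param plan a [split_plan].
#' @param table the [feature_table] the plan refers to.
#' @return `TRUE` invisibly; errors otherwise.
#' @export
validate_split_plan <- function(plan, table) {
  ids <- table$subject_id
  if (!all(plan$test_ids %in% ids)) stop("test ids not present in table")
  non_test <- setdiff(ids, plan$test_ids)
  if (length(plan$folds) > 0) {
    valid_all <- unlist(lapply(plan$folds, `[[`, "valid_ids"))
    for (f in seq_along(plan$folds)) {
      fold <- plan$folds[[f]]
      if (length(intersect(fold$train_ids, fold$valid_ids)) > 0)
        stop("fold ", f, ": train and valid overlap")
      if (length(intersect(fold$train_ids, plan$test_ids)) > 0 ||
          length(intersect(fold$valid_ids, plan$test_ids)) > 0)
        stop("fold ", f, ": overlaps the test set")
      if (!setequal(union(fold$train_ids, fold$valid_ids), non_test))
        stop("fold ", f, ": train + valid do not cover the non-test set")
    }
    if (anyDuplicated(valid_all) || !setequal(valid_all, non_test))
      stop("validation folds do not partition the non-test subjects")
  }
  invisible(TRUE)
}

#' Stratified test holdout
#'
#' Sets aside `round(test_fraction * n)` subjects per stratum, where
#' strata are scanner x age-tertile x sex x group.  Strata with fewer
#' than 2 subjects are merged up the hierarchy: first the age bin is
#' dropped (scanner x sex x group), then sex (scanner x group).
#'
#' @param table a [feature_table].
#' @param test_fraction fraction held out, in `[0, 1)`.
#' @param seed integer seed.
#' @return a [split_plan] with `test_ids` filled and no folds yet.
#' @export
stratified_holdout <- function(table, test_fraction = 0.2, seed = 1L) {
  stopifnot(is_feature_table(table), test_fraction >= 0, test_fraction < 1)
  if (test_fraction == 0 || nrow(table) == 0) {
    return(split_plan(character(0),
                      strata_spec = c("scanner", "age_bin", "sex", "group"),
                      seed = seed))
  }
  qs <- stats::quantile(table$age, c(1 / 3, 2 / 3), na.rm = TRUE)
  age_bin <- 1L + findInterval(table$age, qs, left.open = TRUE)
  s <- paste(table$scanner, age_bin, table$sex, table$group, sep = "|")
  merge_up <- function(s, repl) {
    tab <- table(s)
    small <- s %in% names(tab)[tab < 2]
    s[small] <- repl[small]
    s
  }
  s <- merge_up(s, paste("m1", table$scanner, table$sex, table$group, sep = "|"))
  s <- merge_up(s, paste("m2", table$scanner, table$group, sep = "|"))
  test_ids <- .with_seed(seed, {
    unlist(lapply(sort(unique(s)), function(st) {
      ids <- table$subject_id[s == st]
      n_test <- round(test_fraction * length(ids))
      if (n_test == 0) character(0) else sample(ids, n_test)
    }), use.names = FALSE)
  })
  split_plan(sort(test_ids),
             strata_spec = c("scanner", "age_bin", "sex", "group"),
             seed = seed)
}

#' Group-stratified cross-validation folds
#'
#' Splits the non-test subjects of a plan into `k` folds of near-equal
#' size, stratified by group so each fold's validation set keeps the
#' PD/HV mix, or into leave-one-out folds (`k = "loocv"`).
#'
#' @param table a [feature_table].
#' @param k number of folds, or `"loocv"`.
#' @param seed integer seed.
#' @param plan optional existing [split_plan] whose `test_ids` are
#'   excluded from the folds; folds are added to it.
#' @return a [split_plan] with `folds` filled.
#' @export
make_cv_folds <- function(table, k = 5, seed = 1L, plan = NULL) {
  stopifnot(is_feature_table(table))
  if (is.null(plan)) plan <- split_plan(seed = seed)
  keep <- !(table$subject_id %in% plan$test_ids)
  ids <- table$subject_id[keep]
  grp <- as.character(table$group)[keep]
  n <- length(ids)
  if (identical(k, "loocv")) {
    folds <- lapply(seq_len(n), function(i) {
      list(train_ids = ids[-i], valid_ids = ids[i])
    })
  } else {
    k <- as.integer(k)
    stopifnot(k >= 2, k <= n)
    assign_fold <- .with_seed(seed, {
      out <- integer(n)
      for (g in unique(grp)) {
        idx <- which(grp == g)
        out[idx] <- rep_len(seq_len(k), length(idx))[sample.int(length(idx))]
      }
      out
    })
    folds <- lapply(seq_len(k), function(f) {
      list(train_ids = ids[assign_fold != f], valid_ids = ids[assign_fold == f])
    })
    classes <- unique(grp)
    for (f in seq_len(k)) {
      gv <- grp[assign_fold == f]
      if (!all(classes %in% gv)) {
        warning("fold ", f, " is missing a class in its validation set;",
                " consider a smaller k")
      }
    }
  }
  plan$folds <- folds
  plan$seed <- seed
  plan
}
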