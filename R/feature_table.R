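#' Multi-scanner morphometry feature tables
#'
#' A `feature_table` is a plain `data.frame` carrying one row per subject:
#' the metadata columns `subject_id`, `scanner`, `group` (`"PD"` or `"HV"`),
#' `age` (years), `sex` (`"M"` or `"F"`), an optional `etiv` column
#' (estimated total intracranial volume, mm^3), followed by numeric
#' morphometry feature columns.  Feature names carry a family prefix
#' (`"FS_"` for FreeSurfer-style volumetric features, `"DOJ_"` for
#' determinant-of-Jacobian deformation features) and, for lateralised
#' regions, a `"_L"`/`"_R"` hemisphere suffix; every `"_L"` column must
#' have a matching `"_R"` partner.
#'
#' All downstream stages (harmonization, resampling, splitting, search)
#' consume and produce this one structure.
#'
#' @param x a `data.frame` with the columns described above.
#' @return `feature_table()` returns `x` validated and classed as
#'   `c("feature_table", "data.frame")`.
#' @examples
#' tbl <- feature_table(data.frame(
#'   subject_id = c("a", "b"), scanner = "s1", group = c("PD", "HV"),
#'   age = c(61, 59), sex = c("M", "F"),
#'   FS_roi1_L = c(1.2, 0.9), FS_roi1_R = c(1.1, 1.0)))
#' feature_names(tbl)
#' @export
feature_table <- function(x) {
  if (!is.data.frame(x)) stop("`x` must be a data.frame")
  x <- as.data.frame(x, stringsAsFactors = FALSE)
  req <- c("subject_id", "scanner", "group", "age", "sex")
  missing_cols <- setdiff(req, names(x))
  if (length(missing_cols) > 0) {
    stop("missing required column(s): ", paste(missing_cols, collapse = ", "))
  }
  if (anyDuplicated(x$subject_id)) {
    dup <- unique(x$subject_id[duplicated(x$subject_id)])
    stop("duplicate subject_id: ", paste(utils::head(dup, 5), collapse = ", "))
  }
  bad_grp <- setdiff(unique(as.character(x$group)), c("PD", "HV", NA))
  if (length(bad_grp) > 0) {
    stop("group values outside {PD, HV}: ", paste(bad_grp, collapse = ", "))
  }
  bad_sex <- setdiff(unique(as.character(x$sex)), c("M", "F", NA))
  if (length(bad_sex) > 0) {
    stop("sex values outside {M, F}: ", paste(bad_sex, collapse = ", "))
  }
  if (!is.numeric(x$age)) stop("column `age` must be numeric")
  if ("etiv" %in% names(x)) {
    if (!is.numeric(x$etiv)) stop("column `etiv` must be numeric")
  }
  fn <- setdiff(names(x), c(req, "etiv"))
  for (f in fn) {
    if (!is.numeric(x[[f]])) {
      stop("feature column `", f, "` is not numeric")
    }
  }
  if (anyDuplicated(fn)) stop("duplicate feature names")
  .check_lr_pairs(fn)
  class(x) <- unique(c("feature_table", class(x)))
  x
}

# every "_L" column needs its "_R" partner (and vice versa)
.check_lr_pairs <- function(fn) {
  left <- grep("_L$", fn, value = TRUE)
  right <- grep("_R$", fn, value = TRUE)
  dangling <- c(left[!(sub("_L$", "_R", left) %in% fn)],
                right[!(sub("_R$", "_L", right) %in% fn)])
  if (length(dangling) > 0) {
    stop("dangling hemisphere feature(s) without a partner: ",
         paste(dangling, collapse = ", "))
  }
  invisible(TRUE)
}

#' @rdname feature_table
#' @export
is_feature_table <- function(x) inherits(x, "feature_table")

.meta_cols <- c("subject_id", "scanner", "group", "age", "sex", "etiv")

#' @rdname feature_table
#' @export
feature_names <- function(x) setdiff(names(x), .meta_cols)

#' @rdname feature_table
#' @return `feature_matrix()` returns the numeric subjects x features
#'   matrix with subject ids as row names.
#' @export
feature_matrix <- function(x) {
  fn <- feature_names(x)
  m <- as.matrix(x[, fn, drop = FALSE])
  rownames(m) <- x$subject_id
  m
}

#' @rdname feature_table
#' @export
feature_family <- function(x) {
  fn <- if (is_feature_table(x)) feature_names(x) else x
  ifelse(startsWith(fn, "DOJ"), "DOJ", "FS")
}

# replace the feature block, keeping metadata; `m` must align by row
.set_features <- function(tbl, m) {
  stopifnot(nrow(m) == nrow(tbl))
  meta <- tbl[, intersect(.meta_cols, names(tbl)), drop = FALSE]
  out <- cbind(meta, as.data.frame(m, optional = TRUE))
  rownames(out) <- NULL
  feature_table(out)
}

# row subset that keeps the class
.ft_rows <- function(tbl, idx) {
  out <- tbl[idx, , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- class(tbl)
  out
}

#' Keep only scanners with enough subjects in both groups
#'
#' Multi-site studies commonly require a minimum number of healthy
#' volunteers and patients per scanner before a site enters the analysis;
#' the harmonization model needs both groups represented at every site to
#' separate scanner effects from group composition.
#'
#' @param table a [feature_table].
#' @param min_hv,min_pd minimum number of HV / PD subjects a scanner must
#'   have to be retained (both default to 10).
#' @return the rows of `table` belonging to eligible scanners, original
#'   order preserved; possibly zero rows.
#' @export
filter_eligible_scanners <- function(table, min_hv = 10, min_pd = 10) {
  stopifnot(is_feature_table(table), min_hv >= 0, min_pd >= 0)
  n_hv <- table(factor(table$scanner)[table$group == "HV"])
  n_pd <- table(factor(table$scanner)[table$group == "PD"])
  scanners <- unique(table$scanner)
  ok <- vapply(scanners, function(s) {
    hv <- if (s %in% names(n_hv)) n_hv[[s]] else 0L
    pd <- if (s %in% names(n_pd)) n_pd[[s]] else 0L
    hv >= min_hv && pd >= min_pd
  }, logical(1))
  .ft_rows(table, table$scanner %in% scanners[ok])
}

#' Prepare morphometry features for modelling
#'
#' Applies the standard feature preparation: FreeSurfer-style volumetric
#' (`FS_`) features are divided by each subject's estimated total
#' intracranial volume (eTIV) to correct for head size, with eTIV itself
#' appended as an additional feature; determinant-of-Jacobian (`DOJ_`)
#' features are shifted by -1 so that "no deformation" maps to 0.  The
#' feature set can then be restricted to one family.
#'
#' @param table a [feature_table].
#' @param feature_set which feature family to keep: `"DOJ_PLUS_FS"`
#'   (default, everything), `"FS_ONLY"` or `"DOJ_ONLY"`.
#' @param etiv_correct divide FS features by eTIV and append eTIV as a
#'   feature.  Requires a strictly positive `etiv` column.
#' @return a [feature_table] with transformed and restricted features.
#' @export
prepare_features <- function(table,
                             feature_set = c("DOJ_PLUS_FS", "FS_ONLY", "DOJ_ONLY"),
                             etiv_correct = FALSE) {
  stopifnot(is_feature_table(table))
  feature_set <- match.arg(feature_set)
  m <- feature_matrix(table)
  fam <- feature_family(colnames(m))
  if (etiv_correct) {
    if (!("etiv" %in% names(table)) || anyNA(table$etiv) ||
        any(table$etiv <= 0)) {
      stop("etiv_correct = TRUE requires a strictly positive `etiv` column")
    }
    fs <- fam == "FS"
    if (any(fs)) m[, fs] <- m[, fs, drop = FALSE] / table$etiv
  }
  doj <- fam == "DOJ"
  if (any(doj)) m[, doj] <- m[, doj, drop = FALSE] - 1
  keep <- switch(feature_set,
    DOJ_PLUS_FS = rep(TRUE, ncol(m)),
    FS_ONLY = fam == "FS",
    DOJ_ONLY = fam == "DOJ")
  m <- m[, keep, drop = FALSE]
  if (etiv_correct && feature_set != "DOJ_ONLY") {
    m <- cbind(m, FS_eTIV = table$etiv)
  }
  .set_features(table, m)
}

#' Demographic summary of a cohort
#'
#' Per-scanner PD/HV counts, age mean +/- sd by group and sex counts by
#' group, with a totals row, in the layout conventional for multi-site
#' demographic tables.
#'
#' @param table a non-empty [feature_table].
#' @return a `cohort_summary`: a data.frame with one row per scanner plus
#'   a `"Total"` row.
#' @export
summarize_cohort <- function(table) {
  stopifnot(is_feature_table(table), nrow(table) > 0)
  one <- function(rows, label) {
    pd <- rows[rows$group == "PD", , drop = FALSE]
    hv <- rows[rows$group == "HV", , drop = FALSE]
    data.frame(
      scanner = label,
      n_pd = nrow(pd), n_hv = nrow(hv),
      age_pd_mean = if (nrow(pd)) mean(pd$age) else NA_real_,
      age_pd_sd = if (nrow(pd) > 1) stats::sd(pd$age) else NA_real_,
      age_hv_mean = if (nrow(hv)) mean(hv$age) else NA_real_,
      age_hv_sd = if (nrow(hv) > 1) stats::sd(hv$age) else NA_real_,
      male_pd = sum(pd$sex == "M"), female_pd = sum(pd$sex == "F"),
      male_hv = sum(hv$sex == "M"), female_hv = sum(hv$sex == "F"),
      stringsAsFactors = FALSE)
  }
  scanners <- unique(table$scanner)
  rows <- do.call(rbind, lapply(scanners, function(s) {
    one(table[table$scanner == s, , drop = FALSE], s)
  }))
  total <- one(table, "Total")
  out <- rbind(rows, total)
  attr(out, "n_scanners") <- length(scanners)
  class(out) <- c("cohort_summary", "data.frame")
  out
}

#' @export
print.cohort_summary <- function(x, digits = 1, ...) {
  cat("Cohort summary:", attr(x, "n_scanners") %||% (nrow(x) - 1),
      "scanner(s)\n")
  df <- as.data.frame(x)
  num <- vapply(df, is.numeric, logical(1))
  df[num] <- lapply(df[num], round, digits = digits)
  print(df, row.names = FALSE)
  invisible(x)
}
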