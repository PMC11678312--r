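# File formats: TSV/CSV feature tables, JSON model/result serialization,
# YAML experiment configuration, and run manifests.

#' Read and write feature tables
#'
#' The canonical on-disk format is a delimited text file with one header
#' row and the columns `subject_id`, `scanner`, `group`, `age`, `sex`,
#' optionally `etiv`, followed by the numeric feature columns.  The
#' dialect is chosen by extension: `.csv` is comma-separated, anything
#' else tab-separated.
#'
#' @param path file path.
#' @return `read_feature_table()` returns a validated [feature_table].
#' @export
read_feature_table <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  sep <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
  df <- utils::read.table(path, header = TRUE, sep = sep,
                          stringsAsFactors = FALSE, check.names = FALSE)
  req <- c("subject_id", "scanner", "group", "age", "sex")
  miss <- setdiff(req, names(df))
  if (length(miss) > 0) {
    stop("file ", path, " is missing column(s): ",
         paste(miss, collapse = ", "))
  }
  fn <- setdiff(names(df), c(req, "etiv"))
  for (f in fn) {
    if (!is.numeric(df[[f]])) {
      bad <- which(is.na(suppressWarnings(as.numeric(df[[f]]))))[1]
      stop("non-numeric value in feature column `", f, "`, row ",
           bad %||% "?", " of ", path)
    }
  }
  feature_table(df)
}

#' @rdname read_feature_table
#' @param table a [feature_table] to write.
#' @export
write_feature_table <- function(table, path) {
  stopifnot(is_feature_table(table))
  sep <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
  utils::write.table(as.data.frame(table), path, sep = sep,
                     row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Serialize a fitted ComBat model to JSON
#'
#' Stores everything needed to harmonize new rows from known scanners:
#' covariate coefficients, pooled scales, per-scanner EB-adjusted
#' location/scale effects, hyperpriors and the covariate design.
#'
#' @param model a `"combat"` fit.
#' @param path output JSON path.
#' @export
combat_to_json <- function(model, path) {
  stopifnot(inherits(model, "combat"))
  payload <- model[c("feature_names", "alpha_hat", "beta_hat", "sigma_hat",
                     "batch_ids", "n_per_batch", "gamma_hat", "delta2_hat",
                     "gamma_star", "delta2_star", "design", "eb_mode",
                     "tol")]
  payload$hyperpriors <- model$hyperpriors
  jsonlite::write_json(payload, path, digits = NA, auto_unbox = TRUE,
                       matrix = "rowmajor")
  invisible(path)
}

#' @rdname combat_to_json
#' @return `combat_from_json()` rebuilds the `"combat"` object (without
#'   the fitting data, so `residuals()` is unavailable on it).
#' @export
combat_from_json <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  for (m in c("beta_hat", "gamma_hat", "delta2_hat", "gamma_star",
              "delta2_star")) {
    x[[m]] <- matrix(as.numeric(x[[m]]),
                     nrow = if (m == "beta_hat")
                       length(x[[m]]) / length(x$feature_names)
                     else length(x$batch_ids),
                     byrow = FALSE,
                     dimnames = if (m == "beta_hat") NULL
                     else list(x$batch_ids, x$feature_names))
  }
  x$alpha_hat <- stats::setNames(as.numeric(x$alpha_hat), x$feature_names)
  x$sigma_hat <- stats::setNames(as.numeric(x$sigma_hat), x$feature_names)
  x$n_per_batch <- stats::setNames(as.integer(x$n_per_batch), x$batch_ids)
  structure(x, class = "combat")
}

#' Read an experiment configuration
#'
#' YAML (or JSON) with optional blocks `cohort` (either a path to a
#' table or [cohort_config()] arguments with a `scanners` list of
#' [scanner_spec()] arguments), `features` (`feature_set`,
#' `etiv_correct`), `splits` (`test_fraction`, `k`, `seed`), `balance`
#' (see [balance_config()]) and `search` (see [search_space()]).
#' Missing blocks fall back to package defaults.
#'
#' @param path YAML/JSON config path.
#' @return a named list of resolved configuration objects.
#' @export
read_experiment_config <- function(path) {
  raw <- if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::read_json(path, simplifyVector = TRUE)
  } else {
    yaml::read_yaml(path)
  }
  out <- list()
  ch <- raw$cohort
  if (is.character(ch)) {
    out$cohort_path <- ch
  } else if (!is.null(ch)) {
    scanners <- lapply(ch$scanners, function(s) do.call(scanner_spec, s))
    args <- ch[setdiff(names(ch), "scanners")]
    out$cohort <- do.call(cohort_config, c(list(scanners = scanners), args))
  } else {
    out$cohort <- default_cohort_config()
  }
  out$features <- list(
    feature_set = raw$features$feature_set %||% "DOJ_PLUS_FS",
    etiv_correct = raw$features$etiv_correct %||% FALSE)
  out$splits <- list(test_fraction = raw$splits$test_fraction %||% 0.2,
                     k = raw$splits$k %||% 5,
                     seed = raw$splits$seed %||% 1L)
  out$balance <- do.call(balance_config, as.list(raw$balance %||% list()))
  search_args <- as.list(raw$search %||% list())
  out$search <- do.call(search_space, search_args)
  out$strategy <- raw$strategy %||% "fit_train_only"
  out
}

# a reproducibility manifest written next to every CLI output
.write_manifest <- function(out_path, stage, config, seed) {
  cfg_json <- jsonlite::toJSON(config, auto_unbox = TRUE, digits = NA,
                               force = TRUE)
  tmp <- tempfile(); writeLines(cfg_json, tmp)
  manifest <- list(stage = stage, seed = seed,
                   config_md5 = unname(tools::md5sum(tmp)),
                   package = "combatcv",
                   version = as.character(utils::packageVersion("combatcv")),
                   r_version = R.version.string,
                   timestamp = format(Sys.time(), tz = "UTC"))
  unlink(tmp)
  path <- paste0(out_path, ".manifest.json")
  jsonlite::write_json(manifest, path, auto_unbox = TRUE)
  invisible(path)
}
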