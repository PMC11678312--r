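# Class/scanner balancing and augmentation, applied to training folds
# only.  Validation and test rows must keep their natural class mix, so
# these operations are only ever handed the training fold
# (balance_training_set is the single pipeline entry point).

.balance_strata <- function(table, by) {
  by <- match.arg(tolower(by), c("group", "group_x_scanner"))
  if (by == "group") as.character(table$group)
  else paste(table$group, table$scanner, sep = "|")
}

#' Random undersampling to the smallest stratum
#'
#' Uniformly subsamples every stratum (group, or group x scanner)
#' without replacement down to the minimum stratum size.
#'
#' @param table a [feature_table] (training rows only).
#' @param by `"group"` or `"group_x_scanner"`.
#' @param seed integer seed.
#' @return a [feature_table] that is a row subset of the input, original
#'   order preserved.
#' @export
random_undersample <- function(table, by = "group", seed = 1L) {
  stopifnot(is_feature_table(table))
  s <- .balance_strata(table, by)
  m <- min(table(s))
  keep <- .with_seed(seed, {
    unlist(lapply(sort(unique(s)), function(st) {
      idx <- which(s == st)
      if (length(idx) > m) sample(idx, m) else idx
    }), use.names = FALSE)
  })
  .ft_rows(table, sort(keep))
}

#' SMOTE oversampling to the largest stratum
#'
#' Upsamples each minority stratum to the maximum stratum size with
#' synthetic rows `x + u * (x_nn - x)`, `u ~ Uniform(0, 1)`, where `x` is
#' a stratum row and `x_nn` one of its `k` nearest neighbours within the
#' stratum (Euclidean distance on the feature columns).  Metadata of a
#' synthetic row copies its base row; synthetic subjects are flagged by a
#' `"_syn<i>"` id suffix.
#'
#' @param table a [feature_table] (training rows only); each stratum that
#'   needs upsampling must have at least 2 rows.
#' @param by `"group"` or `"group_x_scanner"`.
#' @param k neighbour count (default 5, lowered with a warning when a
#'   stratum is smaller than `k + 1`).
#' @param seed integer seed.
#' @return the input rows followed by the synthetic rows.
#' @export
smote <- function(table, by = "group", k = 5, seed = 1L) {
  stopifnot(is_feature_table(table), k >= 1)
  s <- .balance_strata(table, by)
  sizes <- table(s)
  m <- max(sizes)
  feats <- feature_matrix(table)
  synth <- .with_seed(seed, {
    out <- list()
    for (st in sort(unique(s))) {
      idx <- which(s == st)
      n_syn <- m - length(idx)
      if (n_syn == 0) next
      if (length(idx) < 2) {
        stop("stratum `", st, "` has a single row; SMOTE cannot",
             " interpolate -- use method RUS or NONE instead")
      }
      k_eff <- min(k, length(idx) - 1)
      if (k_eff < k) {
        warning("stratum `", st, "`: k lowered from ", k, " to ", k_eff,
                " (stratum size ", length(idx), ")")
      }
      Xs <- feats[idx, , drop = FALSE]
      d <- as.matrix(stats::dist(Xs))
      diag(d) <- Inf
      ord <- apply(d, 1, function(r) order(r)[seq_len(k_eff)])
      nn <- if (k_eff == 1) matrix(ord, ncol = 1) else t(ord)
      base <- sample(seq_along(idx), n_syn, replace = TRUE)
      pick <- vapply(base, function(b) nn[b, sample.int(k_eff, 1)], integer(1))
      u <- stats::runif(n_syn)
      new_feats <- Xs[base, , drop = FALSE] +
        u * (Xs[pick, , drop = FALSE] - Xs[base, , drop = FALSE])
      meta <- table[idx[base], intersect(.meta_cols, names(table)), drop = FALSE]
      meta$subject_id <- sprintf("%s_syn%d", meta$subject_id, seq_len(n_syn))
      out[[st]] <- cbind(meta, as.data.frame(new_feats, optional = TRUE))
    }
    out
  })
  if (length(synth) == 0) return(table)
  new_rows <- do.call(rbind, synth)
  rownames(new_rows) <- NULL
  out <- rbind(as.data.frame(table), new_rows)
  rownames(out) <- NULL
  feature_table(out)
}

#' Left/right flip augmentation
#'
#' Appends one mirrored copy of every row, in which each `"_L"`/`"_R"`
#' feature pair is swapped and midline (unpaired) features are copied
#' unchanged.  Labels and covariates are preserved; the row count
#' doubles.  Mirrored subjects get a `"_flip"` id suffix.
#'
#' @param table a [feature_table]; a dangling `_L` without its `_R`
#'   partner is an error.
#' @return a [feature_table] with `2 * nrow(table)` rows.
#' @export
flip_augment <- function(table) {
  stopifnot(is_feature_table(table))
  fn <- feature_names(table)
  .check_lr_pairs(fn)
  swapped <- fn
  is_l <- grepl("_L$", fn); is_r <- grepl("_R$", fn)
  swapped[is_l] <- paste0(sub("_L$", "", fn[is_l]), "_R")
  swapped[is_r] <- paste0(sub("_R$", "", fn[is_r]), "_L")
  mirror <- as.data.frame(table)
  mirror[, fn] <- as.data.frame(table)[, swapped]
  mirror$subject_id <- paste0(mirror$subject_id, "_flip")
  out <- rbind(as.data.frame(table), mirror)
  rownames(out) <- NULL
  feature_table(out)
}

#' Balancing recipe for training folds
#'
#' @param method `"none"`, `"smote"` or `"rus"`.
#' @param by balance with respect to `"group"` or `"group_x_scanner"`.
#' @param flip apply [flip_augment()] first, so mirrored rows take part
#'   in the neighbour search.
#' @param smote_k SMOTE neighbour count.
#' @param seed integer seed.
#' @return a `balance_config`.
#' @export
balance_config <- function(method = "none", by = "group", flip = FALSE,
                           smote_k = 5, seed = 1L) {
  method <- match.arg(tolower(method), c("none", "smote", "rus"))
  by <- match.arg(tolower(by), c("group", "group_x_scanner"))
  stopifnot(smote_k >= 1)
  structure(list(method = method, by = by, flip = isTRUE(flip),
                 smote_k = smote_k, seed = as.integer(seed)),
            class = "balance_config")
}

#' Balance and augment a training fold
#'
#' Applies the recipe to training rows only: flip augmentation first (if
#' requested), then the balancing method.  This function is the only
#' resampling entry point the pipeline uses, and it is only ever handed
#' the training fold -- validation and test rows keep their natural
#' class distribution.
#'
#' @param train the training-fold [feature_table].
#' @param cfg a [balance_config].
#' @return the balanced training [feature_table].
#' @export
balance_training_set <- function(train, cfg = balance_config()) {
  stopifnot(is_feature_table(train), inherits(cfg, "balance_config"))
  if (cfg$flip) train <- flip_augment(train)
  switch(cfg$method,
    none = train,
    rus = random_undersample(train, by = cfg$by, seed = cfg$seed),
    smote = smote(train, by = cfg$by, k = cfg$smote_k, seed = cfg$seed))
}
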