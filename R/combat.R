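# ComBat empirical-Bayes location-scale harmonization.
#
# Model, per feature v, subject j on scanner (batch) i:
#
#   Y_ijv = alpha_v + X_j beta_v + gamma_iv + delta_iv * eps_ijv
#
# alpha_v is the batch-size-weighted grand mean (so sum_i n_i/N gamma_iv
# = 0), X the covariate design (age, sex, optionally diagnostic group),
# gamma_iv / delta_iv additive and multiplicative batch effects and
# eps ~ N(0, sigma_v^2).  Fitting standardizes the data to
# Z_ijv = (Y_ijv - alpha_v - X_j beta_v) / sigma_v, estimates per-batch
# location/scale effects on Z, shrinks them toward cross-feature priors
# (normal for gamma, inverse-gamma for delta^2) by parametric empirical
# Bayes, and removes them.
#
# Including the diagnostic group in X is the leakage pathway this package
# exists to expose: the fitted group coefficient is added back to every
# transformed row, so applying the model to validation/test rows requires
# -- and injects -- their labels.

#' Standardize features against covariates and batch structure
#'
#' The standardization step of ComBat: per-feature least squares on the
#' full design (one indicator per batch plus covariates), with the
#' batch-size-weighted grand mean as intercept, pooled residual scale
#' \eqn{\hat\sigma_v}, and standardized data
#' \eqn{Z = (Y - \hat\alpha - X\hat\beta)/\hat\sigma}.
#'
#' @param Y numeric matrix, subjects x features.
#' @param X covariate design matrix (subjects x covariates, no
#'   intercept), or `NULL` for none.
#' @param batch per-subject batch labels (>= 2 subjects per batch).
#' @return list with `alpha_hat` (length p), `beta_hat` (covariates x p),
#'   `sigma_hat` (length p), `Z` (subjects x features), `gamma_hat` and
#'   `delta2_hat` (batches x features: per-batch means and variances of
#'   `Z`), and `batch_ids`.
#' @export
combat_standardize <- function(Y, X = NULL, batch) {
  Y <- as.matrix(Y)
  n <- nrow(Y); p <- ncol(Y)
  batch <- factor(batch)
  if (any(table(batch) < 2)) {
    stop("every batch needs at least 2 subjects")
  }
  v <- apply(Y, 2, stats::var)
  if (any(v == 0)) {
    stop("zero-variance feature(s): ",
         paste(utils::head(colnames(Y)[v == 0], 5), collapse = ", "))
  }
  B <- vapply(levels(batch), function(l) as.numeric(batch == l),
              numeric(n))
  D <- if (is.null(X)) B else cbind(B, as.matrix(X))
  if (qr(D)$rank < ncol(D)) {
    stop("rank-deficient design: covariates are confounded with batch")
  }
  n_batch <- nlevels(batch)
  n_i <- as.vector(table(batch))
  Bhat <- solve(crossprod(D), crossprod(D, Y))
  alpha_hat <- as.vector(crossprod(n_i / n, Bhat[seq_len(n_batch), , drop = FALSE]))
  beta_hat <- if (is.null(X)) {
    matrix(0, 0, p)
  } else {
    Bhat[-seq_len(n_batch), , drop = FALSE]
  }
  resid <- Y - D %*% Bhat
  sigma2 <- colMeans(resid^2)  # pooled over all subjects (divisor N)
  if (any(sigma2 <= 0)) {
    stop("zero residual variance for feature(s): ",
         paste(utils::head(colnames(Y)[sigma2 <= 0], 5), collapse = ", "))
  }
  sigma_hat <- sqrt(sigma2)
  stand_mean <- matrix(alpha_hat, n, p, byrow = TRUE)
  if (!is.null(X)) stand_mean <- stand_mean + as.matrix(X) %*% beta_hat
  Z <- (Y - stand_mean) / matrix(sigma_hat, n, p, byrow = TRUE)
  gamma_hat <- rowsum(Z, batch) / n_i
  delta2_hat <- (rowsum(Z^2, batch) - n_i * gamma_hat^2) / (n_i - 1)
  list(alpha_hat = stats::setNames(alpha_hat, colnames(Y)),
       beta_hat = beta_hat, sigma_hat = stats::setNames(sigma_hat, colnames(Y)),
       Z = Z, gamma_hat = gamma_hat, delta2_hat = delta2_hat,
       batch_ids = levels(batch), n_per_batch = stats::setNames(n_i, levels(batch)))
}

#' Method-of-moments empirical-Bayes hyperpriors
#'
#' Per batch: the cross-feature mean and variance of the location
#' estimates give the normal prior `gamma_bar`, `tau2_bar`; the
#' cross-feature mean `V` and variance `S` of the scale estimates give
#' the inverse-gamma prior `lambda_bar = (V^2 + 2 S) / S`,
#' `theta_bar = (V^3 + V S) / S`.
#'
#' @param gamma_hat,delta2_hat batches x features matrices of per-batch
#'   location and squared-scale estimates (>= 2 features).
#' @return data.frame with one row per batch: `gamma_bar`, `tau2_bar`,
#'   `lambda_bar`, `theta_bar`, and logical `moments_ok` (FALSE when the
#'   scale estimates are constant across features, in which case the
#'   inverse-gamma prior is undefined and the batch falls back to no
#'   shrinkage, with a warning).
#' @export
eb_hyperpriors <- function(gamma_hat, delta2_hat) {
  gamma_hat <- as.matrix(gamma_hat); delta2_hat <- as.matrix(delta2_hat)
  if (ncol(gamma_hat) < 2) stop("need >= 2 features to estimate hyperpriors")
  gbar <- rowMeans(gamma_hat)
  t2 <- apply(gamma_hat, 1, stats::var)
  V <- rowMeans(delta2_hat)
  S <- apply(delta2_hat, 1, stats::var)
  ok <- S > 0
  lambda <- ifelse(ok, (V^2 + 2 * S) / S, NA_real_)
  theta <- ifelse(ok, (V^3 + V * S) / S, NA_real_)
  if (!all(ok)) {
    warning("constant scale estimates across features for batch(es) ",
            paste(rownames(gamma_hat)[!ok], collapse = ", "),
            "; falling back to no empirical-Bayes shrinkage there")
  }
  data.frame(batch = rownames(gamma_hat) %||% as.character(seq_along(gbar)),
             gamma_bar = gbar, tau2_bar = t2, lambda_bar = lambda,
             theta_bar = theta, moments_ok = ok,
             stringsAsFactors = FALSE, row.names = NULL)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Empirical-Bayes batch-effect adjustments
#'
#' Iterates the parametric conditional posteriors
#' \deqn{\gamma^*_{iv} = \frac{n_i \bar\tau_i^2 \hat\gamma_{iv} +
#'   \delta^{2*}_{iv} \bar\gamma_i}{n_i \bar\tau_i^2 + \delta^{2*}_{iv}}}
#' \deqn{\delta^{2*}_{iv} = \frac{\bar\theta_i + \frac12 \sum_j
#'   (Z_{ijv} - \gamma^*_{iv})^2}{n_i/2 + \bar\lambda_i - 1}}
#' to a fixed point, per batch, stopping when the largest relative
#' parameter change drops below `tol` (or at `max_iter`, with a
#' warning).  The relative-change criterion is the convention of the
#' standard ComBat implementations.
#'
#' @param Z standardized subjects x features matrix.
#' @param batch per-subject batch labels.
#' @param priors hyperprior data.frame from [eb_hyperpriors()].
#' @param tol convergence threshold on the maximum relative change.
#' @param max_iter iteration cap.
#' @return list with `gamma_star` and `delta2_star` (batches x features)
#'   and per-batch iteration counts.  Batches with `moments_ok = FALSE`
#'   keep their raw estimates.
#' @export
eb_adjust <- function(Z, batch, priors, tol = 1e-4, max_iter = 500L) {
  stopifnot(tol > 0, max_iter >= 1)
  batch <- factor(batch)
  n_i <- as.vector(table(batch))
  gamma_hat <- rowsum(as.matrix(Z), batch) / n_i
  delta2_hat <- (rowsum(as.matrix(Z)^2, batch) - n_i * gamma_hat^2) / (n_i - 1)
  gamma_star <- gamma_hat
  delta2_star <- delta2_hat
  iters <- stats::setNames(integer(nlevels(batch)), levels(batch))
  for (i in seq_len(nlevels(batch))) {
    pr <- priors[i, ]
    if (!isTRUE(pr$moments_ok)) next
    if (!all(is.finite(c(pr$gamma_bar, pr$tau2_bar, pr$lambda_bar, pr$theta_bar)))) {
      stop("non-finite hyperpriors for batch ", levels(batch)[i])
    }
    Zi <- Z[batch == levels(batch)[i], , drop = FALSE]
    n <- nrow(Zi)
    g_old <- gamma_hat[i, ]; d_old <- delta2_hat[i, ]
    it <- 0L
    repeat {
      it <- it + 1L
      g_new <- (n * pr$tau2_bar * gamma_hat[i, ] + d_old * pr$gamma_bar) /
        (n * pr$tau2_bar + d_old)
      sum2 <- colSums((Zi - matrix(g_new, n, ncol(Zi), byrow = TRUE))^2)
      d_new <- (pr$theta_bar + 0.5 * sum2) / (n / 2 + pr$lambda_bar - 1)
      # signed denominator: the convergence convention of the standard
      # ComBat implementations (kept so outputs are reproducible
      # against them); a 0/0 (parameter pinned at zero) counts as
      # converged
      rel_g <- abs(g_new - g_old) / g_old
      rel_g[is.nan(rel_g)] <- 0
      change <- max(rel_g, abs(d_new - d_old) / d_old)
      g_old <- g_new; d_old <- d_new
      if (change < tol) break
      if (it >= max_iter) {
        warning("EB adjustment for batch ", levels(batch)[i],
                " did not converge in ", max_iter,
                " iterations (last change ", signif(change, 3), ")")
        break
      }
    }
    gamma_star[i, ] <- g_old
    delta2_star[i, ] <- d_old
    iters[i] <- it
  }
  list(gamma_star = gamma_star, delta2_star = delta2_star, iterations = iters)
}

#' Fit a ComBat harmonization model
#'
#' Fits the empirical-Bayes location-scale harmonization model to a
#' [feature_table], with scanner as batch and the selected covariates.
#' The returned object can harmonize any table whose scanners were seen
#' at fit time via [predict.combat()].
#'
#' `use_group = TRUE` adds the diagnostic group (PD vs HV) to the
#' covariate design.  This protects a true group difference from removal,
#' but it makes the transform label-dependent: group labels are then
#' required to harmonize any new data, which leaks labels into
#' validation/test features inside a classification pipeline.  The fitted
#' model records this in `design$use_group` and `predict()` refuses
#' unlabeled rows.
#'
#' @param table a [feature_table]; every scanner needs at least
#'   `min_batch` subjects.
#' @param use_age,use_sex,use_group covariate switches (age and sex on by
#'   default; group off -- see Details).
#' @param eb_mode `"parametric_eb"` (default) or `"no_eb"` (raw per-batch
#'   estimates, no shrinkage; mainly for oracle testing).
#' @param min_batch minimum subjects per scanner (default 20, the common
#'   guidance of roughly twenty scans per scanner for stable ComBat
#'   estimates; lower it deliberately for small examples).
#' @param tol,max_iter convergence controls for [eb_adjust()].
#' @return an object of class `"combat"`; see [predict.combat()],
#'   [summary.combat()], [coef.combat()], [residuals.combat()].
#' @examples
#' cfg <- cohort_config(list(scanner_spec("a", 15, 15, gamma_loc = 1),
#'                           scanner_spec("b", 15, 15, gamma_loc = -1)),
#'                      n_features_fs = 10, n_features_doj = 0, seed = 7)
#' tbl <- generate_cohort(cfg)
#' fit <- combat_fit(tbl, min_batch = 4)
#' harmonized <- predict(fit, tbl)
#' @export
combat_fit <- function(table, use_age = TRUE, use_sex = TRUE,
                       use_group = FALSE,
                       eb_mode = c("parametric_eb", "no_eb"),
                       min_batch = 20, tol = 1e-4, max_iter = 500L) {
  stopifnot(is_feature_table(table))
  eb_mode <- match.arg(eb_mode)
  batch <- factor(table$scanner)
  small <- table(batch) < min_batch
  if (any(small)) {
    stop("scanner(s) below the minimum batch size of ", min_batch,
         " subjects: ", paste(names(small)[small], collapse = ", "),
         " (ComBat guidance is ~20 scans per scanner; lower `min_batch`",
         " only deliberately)")
  }
  Y <- feature_matrix(table)
  X <- .covariate_matrix(table, use_age, use_sex, use_group)
  std <- combat_standardize(Y, X, batch)
  single_batch <- length(std$batch_ids) == 1
  if (single_batch) {
    # one site: no batch structure to remove; the transform is the
    # identity (up to the standardize/destandardize round trip)
    priors <- NULL
    gamma_star <- std$gamma_hat * 0
    delta2_star <- std$delta2_hat * 0 + 1
    iters <- NULL
  } else if (eb_mode == "parametric_eb") {
    priors <- eb_hyperpriors(std$gamma_hat, std$delta2_hat)
    adj <- eb_adjust(std$Z, batch, priors, tol = tol, max_iter = max_iter)
    gamma_star <- adj$gamma_star
    delta2_star <- adj$delta2_star
    iters <- adj$iterations
  } else {
    priors <- NULL
    gamma_star <- std$gamma_hat
    delta2_star <- std$delta2_hat
    iters <- NULL
  }
  structure(list(
    feature_names = colnames(Y),
    alpha_hat = std$alpha_hat,
    beta_hat = std$beta_hat,
    sigma_hat = std$sigma_hat,
    batch_ids = std$batch_ids,
    n_per_batch = std$n_per_batch,
    gamma_hat = std$gamma_hat,
    delta2_hat = std$delta2_hat,
    gamma_star = gamma_star,
    delta2_star = delta2_star,
    hyperpriors = priors,
    Z = std$Z,
    batch = as.character(batch),
    design = list(use_age = use_age, use_sex = use_sex,
                  use_group = use_group),
    eb_mode = if (single_batch) "no_eb" else eb_mode,
    iterations = iters,
    tol = tol,
    call = match.call()), class = "combat")
}

# covariate design from table metadata; group PD -> 1, sex M -> 1
.covariate_matrix <- function(table, use_age, use_sex, use_group) {
  cols <- list()
  if (use_age) cols$age <- as.numeric(table$age)
  if (use_sex) cols$sex <- as.numeric(table$sex == "M")
  if (use_group) {
    if (anyNA(table$group)) {
      stop("group labels are required to build a label-dependent design",
           " (use_group = TRUE) but are missing for some rows")
    }
    cols$group <- as.numeric(table$group == "PD")
  }
  if (length(cols) == 0) return(NULL)
  do.call(cbind, cols)
}

#' Harmonize a feature table with a fitted ComBat model
#'
#' Applies \eqn{Y^*_{jv} = \frac{\hat\sigma_v}{\delta^*_{i(j)v}}
#' (Z_{jv} - \gamma^*_{i(j)v}) + \hat\alpha_v + X_j \hat\beta_v} to every
#' row of `newdata`, with `Z` computed from the stored fit.  Metadata
#' columns are passed through unchanged.
#'
#' Scanners never seen at fit time cannot be harmonized (their batch
#' parameters were never estimated) and raise an error.  If the model was
#' fitted with the diagnostic-group covariate, `newdata` must carry group
#' labels -- the label-leakage pathway; a message notes each such use.
#'
#' @param object a fitted `"combat"` model.
#' @param newdata a [feature_table] containing the model's feature
#'   columns and only scanners in `object$batch_ids`.
#' @param ... unused.
#' @return `newdata` with harmonized feature values.
#' @export
predict.combat <- function(object, newdata, ...) {
  stopifnot(is_feature_table(newdata))
  unseen <- setdiff(unique(newdata$scanner), object$batch_ids)
  if (length(unseen) > 0) {
    stop("scanner(s) not seen when the harmonization model was fitted: ",
         paste(unseen, collapse = ", "),
         "; completely novel scanners cannot be harmonized")
  }
  missing_feat <- setdiff(object$feature_names, feature_names(newdata))
  if (length(missing_feat) > 0) {
    stop("newdata lacks fitted feature(s): ",
         paste(utils::head(missing_feat, 5), collapse = ", "))
  }
  des <- object$design
  if (des$use_group && anyNA(newdata$group)) {
    stop("this model was fitted with the diagnostic-group covariate;",
         " harmonizing rows without group labels is impossible",
         " (this requirement is the label-leakage pathway)")
  }
  if (des$use_group) {
    message("note: harmonizing with a label-dependent (use_group) model;",
            " group labels of the transformed rows enter the features")
  }
  Y <- as.matrix(newdata[, object$feature_names, drop = FALSE])
  n <- nrow(Y); p <- ncol(Y)
  X <- .covariate_matrix(newdata, des$use_age, des$use_sex, des$use_group)
  stand_mean <- matrix(object$alpha_hat, n, p, byrow = TRUE)
  if (!is.null(X)) stand_mean <- stand_mean + X %*% object$beta_hat
  sig <- matrix(object$sigma_hat, n, p, byrow = TRUE)
  Z <- (Y - stand_mean) / sig
  bi <- match(newdata$scanner, object$batch_ids)
  g <- object$gamma_star[bi, , drop = FALSE]
  d <- sqrt(object$delta2_star)[bi, , drop = FALSE]
  Ystar <- sig / d * (Z - g) + stand_mean
  out <- newdata
  out[, object$feature_names] <- Ystar
  out
}
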