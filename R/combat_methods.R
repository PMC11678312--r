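# S3 methods for fitted "combat" harmonization models.

#' @export
print.combat <- function(x, ...) {
  cov <- c(if (x$design$use_age) "age", if (x$design$use_sex) "sex",
           if (x$design$use_group) "group")
  cat("ComBat harmonization model\n")
  cat("  features:", length(x$feature_names),
      " scanners:", length(x$batch_ids),
      " subjects:", sum(x$n_per_batch), "\n")
  cat("  covariates:", if (length(cov)) paste(cov, collapse = ", ") else "none",
      " mode:", x$eb_mode, "\n")
  if (x$design$use_group) {
    cat("  WARNING: label-dependent design (group covariate);",
        "applying this model\n  to new data requires their group labels",
        "and leaks them into the features\n")
  }
  invisible(x)
}

#' Summarize a fitted ComBat model
#'
#' Per-scanner summaries of the empirical-Bayes adjusted batch effects:
#' cross-feature mean location shift `gamma_star`, mean scale
#' `delta_star`, the prior parameters, and how much shrinkage the EB step
#' applied (1 = fully shrunk to the prior mean, 0 = raw estimate kept).
#'
#' @param object a `"combat"` fit.
#' @param ... unused.
#' @return a `summary.combat` data.frame, one row per scanner.
#' @export
summary.combat <- function(object, ...) {
  shrink <- rowMeans(abs(object$gamma_star - object$gamma_hat) /
                       pmax(abs(object$gamma_hat -
                                  rowMeans(object$gamma_hat)), 1e-12))
  out <- data.frame(
    scanner = object$batch_ids,
    n = as.vector(object$n_per_batch),
    mean_gamma_star = rowMeans(object$gamma_star),
    mean_delta_star = rowMeans(sqrt(object$delta2_star)),
    stringsAsFactors = FALSE, row.names = NULL)
  if (!is.null(object$hyperpriors)) {
    out$gamma_bar <- object$hyperpriors$gamma_bar
    out$tau2_bar <- object$hyperpriors$tau2_bar
    out$mean_shrinkage <- shrink
  }
  attr(out, "eb_mode") <- object$eb_mode
  attr(out, "design") <- object$design
  class(out) <- c("summary.combat", "data.frame")
  out
}

#' @export
print.summary.combat <- function(x, digits = 3, ...) {
  cat("Per-scanner batch effects (",
      attr(x, "eb_mode") %||% "summary", "):\n", sep = "")
  df <- as.data.frame(x)
  num <- vapply(df, is.numeric, logical(1))
  df[num] <- lapply(df[num], signif, digits = digits)
  print(df, row.names = FALSE)
  invisible(x)
}

#' Coefficients of a fitted ComBat model
#'
#' @param object a `"combat"` fit.
#' @param what `"covariates"` (default): the intercept `alpha_hat` and
#'   covariate coefficients `beta_hat`, features in columns;
#'   `"batch"`: the EB-adjusted per-scanner location effects
#'   `gamma_star`; `"scale"`: the per-scanner scale effects `delta_star`.
#' @param ... unused.
#' @export
coef.combat <- function(object, what = c("covariates", "batch", "scale"), ...) {
  what <- match.arg(what)
  switch(what,
    covariates = rbind(alpha = object$alpha_hat, object$beta_hat),
    batch = object$gamma_star,
    scale = sqrt(object$delta2_star))
}

#' Standardized residuals of a fitted ComBat model
#'
#' Returns the fully batch-adjusted standardized residuals
#' \eqn{(Z_{ijv} - \gamma^*_{iv}) / \delta^*_{iv}} of the fitting data,
#' which should be approximately N(0, 1) per feature when the
#' location-scale model holds.
#'
#' @param object a `"combat"` fit.
#' @param ... unused.
#' @return subjects x features matrix.
#' @export
residuals.combat <- function(object, ...) {
  bi <- match(object$batch, object$batch_ids)
  (object$Z - object$gamma_star[bi, , drop = FALSE]) /
    sqrt(object$delta2_star)[bi, , drop = FALSE]
}

#' Diagnostic plot of estimated batch effects
#'
#' Boxplots of the per-feature EB-adjusted location (`gamma_star`) and
#' scale (`delta_star`) effects by scanner; a harmonizable cohort shows
#' clearly separated boxes that the transform will remove.
#'
#' @param x a `"combat"` fit.
#' @param ... passed to [graphics::boxplot()].
#' @export
plot.combat <- function(x, ...) {
  old <- graphics::par(mfrow = c(1, 2), mar = c(6, 4, 2, 1))
  on.exit(graphics::par(old))
  graphics::boxplot(t(x$gamma_star), names = x$batch_ids, las = 2,
                    main = "additive batch effects", ylab = "gamma*", ...)
  graphics::abline(h = 0, lty = 2, col = "grey50")
  graphics::boxplot(t(sqrt(x$delta2_star)), names = x$batch_ids, las = 2,
                    main = "scale batch effects", ylab = "delta*", ...)
  graphics::abline(h = 1, lty = 2, col = "grey50")
  invisible(x)
}
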