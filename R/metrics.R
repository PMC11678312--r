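# Evaluation metrics and scanner-specific reporting.

#' Area under the ROC curve
#'
#' Rank-based (Mann-Whitney) AUC: the probability that a randomly chosen
#' PD subject scores higher than a randomly chosen HV subject, with ties
#' credited one half.
#'
#' @param scores per-subject continuous scores, higher = more PD-like.
#' @param labels per-subject labels: a factor/character with levels
#'   `"PD"`/`"HV"`, or a logical/0-1 vector with `TRUE`/1 = PD.
#' @return the AUC in `[0, 1]`, or `NA` (with a warning) when only one
#'   class is present.
#' @export
roc_auc <- function(scores, labels) {
  pos <- .as_pd(labels)
  n1 <- sum(pos); n0 <- sum(!pos)
  if (n1 == 0 || n0 == 0) {
    warning("AUC undefined: only one class present")
    return(NA_real_)
  }
  r <- rank(scores)
  (sum(r[pos]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

.as_pd <- function(labels) {
  if (is.logical(labels)) return(labels)
  if (is.numeric(labels)) return(labels == 1)
  as.character(labels) == "PD"
}

#' Balanced accuracy
#'
#' The mean of sensitivity (PD recall) and specificity (HV recall).
#'
#' @param predictions binary predicted labels (same encodings as
#'   `labels`).
#' @param labels true labels; both classes must be present.
#' @return `(sensitivity + specificity) / 2`, or `NA` with a warning for
#'   single-class `labels`.
#' @export
balanced_accuracy <- function(predictions, labels) {
  truth <- .as_pd(labels)
  pred <- .as_pd(predictions)
  if (all(truth) || !any(truth)) {
    warning("balanced accuracy undefined: only one class present")
    return(NA_real_)
  }
  sens <- mean(pred[truth])
  spec <- mean(!pred[!truth])
  (sens + spec) / 2
}

#' Scanner-specific evaluation report
#'
#' Computes the AUC within each scanner's subjects -- how a multi-scanner
#' classifier performs on one scanner at a time -- and aggregates across
#' scanners as mean +/- sample (n-1) standard deviation.  Scanners whose
#' subjects are all one class have no defined AUC and are flagged rather
#' than dropped silently.
#'
#' @param scores per-subject continuous scores.
#' @param labels per-subject labels (see [roc_auc()]).
#' @param scanner per-subject scanner ids.
#' @return an `evaluation_report`: list with `per_scanner` (data.frame of
#'   scanner, n, auc, defined), `overall_mean`, `overall_sd` (NA when
#'   fewer than 2 scanners have a defined AUC), and `n_scanners`.
#' @export
scanner_specific_report <- function(scores, labels, scanner) {
  stopifnot(length(scores) == length(labels),
            length(scores) == length(scanner), length(scores) > 0)
  scanners <- unique(as.character(scanner))
  per <- do.call(rbind, lapply(scanners, function(s) {
    idx <- scanner == s
    pos <- .as_pd(labels[idx])
    defined <- any(pos) && !all(pos)
    data.frame(scanner = s, n = sum(idx),
               auc = if (defined) roc_auc(scores[idx], labels[idx]) else NA_real_,
               defined = defined, stringsAsFactors = FALSE)
  }))
  aucs <- per$auc[per$defined]
  structure(list(per_scanner = per,
                 overall_mean = if (length(aucs)) mean(aucs) else NA_real_,
                 overall_sd = if (length(aucs) > 1) stats::sd(aucs) else NA_real_,
                 n_scanners = length(scanners)),
            class = "evaluation_report")
}

#' @export
print.evaluation_report <- function(x, digits = 3, ...) {
  cat("Scanner-specific AUC (", x$n_scanners, " scanners):\n", sep = "")
  df <- x$per_scanner
  df$auc <- round(df$auc, digits)
  print(df, row.names = FALSE)
  cat(sprintf("overall: %.3f +/- %s (mean +/- sample SD over scanners)\n",
              x$overall_mean,
              if (is.na(x$overall_sd)) "NA" else sprintf("%.3f", x$overall_sd)))
  invisible(x)
}

#' @export
plot.evaluation_report <- function(x, ...) {
  graphics::barplot(stats::setNames(x$per_scanner$auc, x$per_scanner$scanner),
                    las = 2, ylim = c(0, 1), ylab = "AUC", ...)
  graphics::abline(h = 0.5, lty = 2, col = "grey50")
  invisible(x)
}
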