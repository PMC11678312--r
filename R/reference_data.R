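#' Published single-scanner validation AUCs of the reference cohort
#'
#' The per-scanner validation AUCs reported for single-scanner PD/HV
#' classifiers on the 11-scanner multi-site morphometry cohort that this
#' package's synthetic generator emulates (see
#' [default_cohort_config()]).  Feeding them to
#' [scanner_specific_report()]'s aggregation reproduces the published
#' overall figure of 0.651 +/- 0.144 (mean +/- sample SD across
#' scanners), and they make a convenient worked example for the
#' reporting layer.
#'
#' @return named numeric vector of 11 AUCs.
#' @examples
#' aucs <- reference_single_scanner_aucs()
#' c(mean = mean(aucs), sd = sd(aucs))
#' @export
reference_single_scanner_aucs <- function() {
  c(NIH_1 = 0.768, NIH_2 = 0.700, NIH_3 = 0.618,
    PPMI_1 = 0.486, PPMI_2 = 0.560, PPMI_3 = 0.593,
    PPMI_4 = 0.519, PPMI_5 = 0.573, PPMI_6 = 0.617,
    Neurocon = 1.000, TaoWu = 0.727)
}

#' Aggregate a set of per-scanner AUCs
#'
#' Convenience wrapper building an [scanner_specific_report()]-shaped
#' report directly from already-computed per-scanner AUCs (e.g. the
#' published values of [reference_single_scanner_aucs()]): overall mean
#' and sample (n-1) SD across scanners.
#'
#' @param aucs named numeric vector of per-scanner AUCs; `NA` entries
#'   are treated as undefined (single-class) scanners.
#' @return an `evaluation_report`.
#' @export
aggregate_scanner_aucs <- function(aucs) {
  stopifnot(is.numeric(aucs), length(aucs) >= 1)
  nm <- names(aucs) %||% as.character(seq_along(aucs))
  per <- data.frame(scanner = nm, n = NA_integer_, auc = unname(aucs),
                    defined = !is.na(aucs), stringsAsFactors = FALSE)
  ok <- per$auc[per$defined]
  structure(list(per_scanner = per,
                 overall_mean = if (length(ok)) mean(ok) else NA_real_,
                 overall_sd = if (length(ok) > 1) stats::sd(ok) else NA_real_,
                 n_scanners = length(aucs)),
            class = "evaluation_report")
}
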