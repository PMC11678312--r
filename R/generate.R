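# Synthetic multi-scanner morphometry cohorts.
#
# The generator emulates the statistical structure a multi-site PD/HV
# morphometry analysis has to cope with: per-scanner additive (gamma) and
# multiplicative (delta) batch effects that vary across features, a
# (possibly null) group effect on a subset of features, age and sex
# covariate effects, paired left/right regional features, and optional
# scanner-group confounding in which group prevalence varies by scanner.

# evaluate `code` under a temporary RNG state; generation is a pure
# function of `seed`
.with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

#' Specify one scanner of a synthetic cohort
#'
#' @param scanner_id unique scanner label.
#' @param n_pd,n_hv subject counts per group.
#' @param gamma_loc additive scanner shift, in units of the residual
#'   standard deviation; per-feature shifts are drawn around this value.
#' @param delta_scale multiplicative scanner scale (> 0); per-feature
#'   scales are drawn log-normally around it.
#' @param age_mean,age_sd age sampling distribution (years).
#' @param male_fraction probability a subject is male.
#' @return a `scanner_spec` list.
#' @export
scanner_spec <- function(scanner_id, n_pd, n_hv, gamma_loc = 0,
                         delta_scale = 1, age_mean = 62, age_sd = 8,
                         male_fraction = 0.6) {
  stopifnot(is.character(scanner_id), length(scanner_id) == 1,
            n_pd >= 0, n_hv >= 0, delta_scale > 0,
            male_fraction >= 0, male_fraction <= 1, age_sd >= 0)
  structure(list(scanner_id = scanner_id, n_pd = as.integer(n_pd),
                 n_hv = as.integer(n_hv), gamma_loc = gamma_loc,
                 delta_scale = delta_scale, age_mean = age_mean,
                 age_sd = age_sd, male_fraction = male_fraction),
            class = "scanner_spec")
}

#' Configure a synthetic multi-scanner cohort
#'
#' @param scanners list of [scanner_spec] objects.
#' @param n_features_fs,n_features_doj number of FreeSurfer-style (`FS_`)
#'   and determinant-of-Jacobian (`DOJ_`) features.
#' @param lr_pair_fraction fraction of each family's features emitted as
#'   left/right hemisphere pairs.
#' @param group_effect_size standardized mean shift (in residual-sd units)
#'   added to affected features for PD subjects; 0 gives a null cohort.
#' @param group_effect_fraction fraction of features carrying the group
#'   effect.
#' @param age_slope,sex_shift covariate effect sizes in residual-sd units:
#'   `age_slope` per decade of age (centred at 60 y), `sex_shift` for male
#'   vs female.  Either scalars or named length-2 vectors
#'   `c(FS = , DOJ = )` for family-specific effects.
#' @param confound_strength in `[0, 1)`: how strongly group prevalence is
#'   tied to scanner identity.  Scanners alternate between PD-rich and
#'   HV-rich with prevalence `0.5 +/- 0.45 * confound_strength`; total
#'   subjects per scanner are preserved.  This models "neurobiological
#'   cofactor" confounding (site populations differing in disease mix)
#'   without touching the measurement model.
#' @param noise_sd residual standard deviation (> 0) in standardized
#'   units, before per-scanner scaling.
#' @param seed default seed used by [generate_cohort()].
#' @return a `cohort_config` list.
#' @seealso [default_cohort_config()] for the packaged 11-scanner cohort.
#' @export
cohort_config <- function(scanners, n_features_fs = 60, n_features_doj = 40,
                          lr_pair_fraction = 0.6, group_effect_size = 0.2,
                          group_effect_fraction = 0.3, age_slope = 0.1,
                          sex_shift = 0.2, confound_strength = 0,
                          noise_sd = 1, seed = 1L) {
  if (inherits(scanners, "scanner_spec")) scanners <- list(scanners)
  stopifnot(is.list(scanners), length(scanners) > 0,
            all(vapply(scanners, inherits, logical(1), "scanner_spec")),
            n_features_fs >= 0, n_features_doj >= 0,
            lr_pair_fraction >= 0, lr_pair_fraction <= 1,
            group_effect_fraction >= 0, group_effect_fraction <= 1,
            confound_strength >= 0, confound_strength < 1,
            noise_sd > 0)
  ids <- vapply(scanners, `[[`, character(1), "scanner_id")
  if (anyDuplicated(ids)) {
    stop("duplicate scanner_id: ", paste(unique(ids[duplicated(ids)]),
                                         collapse = ", "))
  }
  structure(list(scanners = scanners, n_features_fs = as.integer(n_features_fs),
                 n_features_doj = as.integer(n_features_doj),
                 lr_pair_fraction = lr_pair_fraction,
                 group_effect_size = group_effect_size,
                 group_effect_fraction = group_effect_fraction,
                 age_slope = age_slope, sex_shift = sex_shift,
                 confound_strength = confound_strength,
                 noise_sd = noise_sd, seed = as.integer(seed)),
            class = "cohort_config")
}

#' The packaged 11-scanner reference cohort configuration
#'
#' Mirrors the published demographic structure of an 11-scanner multi-site
#' PD morphometry cohort (three in-house scanners, six PPMI scanners, and
#' the Neurocon and Tao Wu datasets): 216 PD and 155 HV subjects, with the
#' per-scanner group counts, pooled age distributions and sex ratios of
#' the published demographic table.  Scanner batch-effect locations and
#' scales are package defaults chosen to span a realistic range
#' (additive shifts within one residual sd, scales 0.7-1.4).
#'
#' @param ... overrides passed on to [cohort_config()].
#' @return a `cohort_config`.
#' @export
default_cohort_config <- function(...) {
  demo <- data.frame(
    id = c("NIH_1", "NIH_2", "NIH_3", "PPMI_1", "PPMI_2", "PPMI_3",
           "PPMI_4", "PPMI_5", "PPMI_6", "Neurocon", "TaoWu"),
    n_pd = c(24, 17, 23, 16, 22, 21, 14, 14, 19, 26, 20),
    n_hv = c(12, 19, 20, 12, 12, 13, 10, 11, 10, 16, 20),
    age_mean = c(61.2, 62.7, 60.2, 62.6, 60.9, 60.1, 63.4, 59.5, 63.9,
                 68.3, 65.0),
    age_sd = c(8.7, 7.0, 7.7, 10.1, 8.5, 10.5, 7.2, 8.4, 8.6, 11.1, 5.0),
    male_fraction = c(0.639, 0.750, 0.488, 0.786, 0.647, 0.647, 0.542,
                      0.720, 0.552, 0.690, 0.575),
    gamma_loc = c(0.8, -0.5, 0.3, -1.0, 0.6, -0.2, 1.0, -0.8, 0.4,
                  -0.6, 0.2),
    delta_scale = c(1.3, 0.8, 1.1, 0.7, 1.25, 0.9, 1.4, 0.75, 1.05,
                    0.85, 1.2),
    stringsAsFactors = FALSE)
  scanners <- lapply(seq_len(nrow(demo)), function(i) {
    with(demo[i, ], scanner_spec(id, n_pd, n_hv, gamma_loc, delta_scale,
                                 age_mean, age_sd, male_fraction))
  })
  cohort_config(scanners, ...)
}

# family scales map standardized effects onto realistic raw units:
# FS features are volume-like (baselines 500-5000 mm^3, residual sd ~50),
# DOJ features sit near 1 (no deformation) with residual sd ~0.05
.family_scale <- c(FS = 50, DOJ = 0.05)

# feature layout: names, family, pair ids
.feature_layout <- function(n_fs, n_doj, lr_pair_fraction) {
  fam_names <- function(prefix, n) {
    if (n == 0) return(list(names = character(0), pair = integer(0)))
    n_pairs <- round(n * lr_pair_fraction) %/% 2
    n_unpaired <- n - 2 * n_pairs
    nm <- c(as.vector(rbind(sprintf("%s_roi%02d_L", prefix, seq_len(n_pairs)),
                            sprintf("%s_roi%02d_R", prefix, seq_len(n_pairs)))),
            sprintf("%s_mid%02d", prefix, seq_len(n_unpaired)))
    pair <- c(rep(seq_len(n_pairs), each = 2), rep(NA_integer_, n_unpaired))
    list(names = nm[seq_len(n)], pair = pair[seq_len(n)])
  }
  fs <- fam_names("FS", n_fs)
  doj <- fam_names("DOJ", n_doj)
  pair_doj <- doj$pair + ifelse(is.na(doj$pair), 0L, max(c(0L, fs$pair), na.rm = TRUE))
  list(names = c(fs$names, doj$names),
       family = c(rep("FS", n_fs), rep("DOJ", n_doj)),
       pair = c(fs$pair, pair_doj))
}

.per_family <- function(x, family) {
  if (length(x) == 1) return(rep(as.numeric(x), length(family)))
  stopifnot(all(c("FS", "DOJ") %in% names(x)))
  as.numeric(x[family])
}

#' Generate a synthetic multi-scanner cohort
#'
#' Draws a [feature_table] from the generative model
#' \deqn{Y_{jv} = b_v + s_v (e_v g_j + a_v \tilde{age}_j + m_v male_j +
#'       \gamma_{i(j)v} + \delta_{i(j)v} \epsilon_{jv})}
#' with baseline \eqn{b_v}, family scale \eqn{s_v}, group indicator
#' \eqn{g_j} (PD = 1), standardized age \eqn{\tilde{age} = (age-60)/10},
#' and noise \eqn{\epsilon \sim N(0, noise\_sd^2)}.  Per-feature scanner
#' effects are drawn `Normal(gamma_loc, 0.25 |gamma_loc| + 0.05)` and
#' `LogNormal(log delta_scale, 0.1)`, giving the cross-feature spread the
#' empirical-Bayes harmonization priors assume.  Left/right paired
#' features share their baseline and half of their noise variance.
#'
#' The true per-feature effects are attached as `attr(, "truth")` for
#' ground-truth testing.  Generation is a pure function of `seed`.
#'
#' @param config a [cohort_config].
#' @param seed integer seed (defaults to `config$seed`).
#' @return a [feature_table] with `sum(n_pd + n_hv)` rows.
#' @export
generate_cohort <- function(config, seed = config$seed) {
  stopifnot(inherits(config, "cohort_config"))
  specs <- config$scanners
  n_tot <- sum(vapply(specs, function(s) s$n_pd + s$n_hv, numeric(1)))
  if (n_tot == 0) stop("cohort has zero subjects")
  lay <- .feature_layout(config$n_features_fs, config$n_features_doj,
                         config$lr_pair_fraction)
  p <- length(lay$names)
  if (p == 0) stop("cohort has zero features")
  .with_seed(seed, {
    s_v <- .family_scale[lay$family]
    # baselines, shared within an L/R pair
    unit <- ifelse(is.na(lay$pair), -seq_along(lay$pair), lay$pair)
    first_of_unit <- !duplicated(unit)
    base_unit <- ifelse(lay$family[first_of_unit] == "FS",
                        stats::runif(sum(first_of_unit), 500, 5000),
                        stats::rnorm(sum(first_of_unit), 1, 0.02))
    baseline <- base_unit[match(unit, unit[first_of_unit])]
    # which features carry the group effect
    n_eff <- round(config$group_effect_fraction * p)
    affected <- sort(sample.int(p, n_eff))
    effect <- numeric(p)
    effect[affected] <- config$group_effect_size * config$noise_sd
    age_v <- .per_family(config$age_slope, lay$family)
    sex_v <- .per_family(config$sex_shift, lay$family)
    n_scan <- length(specs)
    gamma <- matrix(NA_real_, n_scan, p)
    delta <- matrix(NA_real_, n_scan, p)
    for (i in seq_len(n_scan)) {
      g0 <- specs[[i]]$gamma_loc
      gamma[i, ] <- stats::rnorm(p, g0, 0.25 * abs(g0) + 0.05)
      delta[i, ] <- stats::rlnorm(p, log(specs[[i]]$delta_scale), 0.1)
    }
    rows <- vector("list", n_scan)
    for (i in seq_len(n_scan)) {
      sp <- specs[[i]]
      n_i <- sp$n_pd + sp$n_hv
      if (n_i == 0) next
      if (config$confound_strength > 0) {
        sgn <- if (i %% 2 == 1) 1 else -1
        prev <- 0.5 + sgn * 0.45 * config$confound_strength
        n_pd <- max(0L, min(n_i, as.integer(round(n_i * prev))))
        n_hv <- n_i - n_pd
      } else {
        n_pd <- sp$n_pd; n_hv <- sp$n_hv
      }
      group <- c(rep("PD", n_pd), rep("HV", n_hv))
      age <- stats::rnorm(n_i, sp$age_mean, sp$age_sd)
      sex <- ifelse(stats::runif(n_i) < sp$male_fraction, "M", "F")
      eps <- matrix(stats::rnorm(n_i * p), n_i, p)
      pairs <- unique(lay$pair[!is.na(lay$pair)])
      for (pr in pairs) {
        idx <- which(lay$pair == pr)
        shared <- stats::rnorm(n_i)
        eps[, idx] <- sqrt(0.5) * matrix(shared, n_i, length(idx)) +
          sqrt(0.5) * eps[, idx, drop = FALSE]
      }
      std <- outer(group == "PD", effect) +
        outer((age - 60) / 10, age_v) +
        outer(sex == "M", sex_v) +
        matrix(gamma[i, ], n_i, p, byrow = TRUE) +
        matrix(delta[i, ], n_i, p, byrow = TRUE) * config$noise_sd * eps
      feat <- matrix(baseline, n_i, p, byrow = TRUE) +
        matrix(s_v, n_i, p, byrow = TRUE) * std
      colnames(feat) <- lay$names
      etiv <- stats::rlnorm(n_i, log(1.5e6), 0.1)
      rows[[i]] <- cbind(
        data.frame(subject_id = sprintf("%s_S%03d", sp$scanner_id, seq_len(n_i)),
                   scanner = sp$scanner_id, group = group, age = age,
                   sex = sex, etiv = etiv, stringsAsFactors = FALSE),
        as.data.frame(feat))
    }
    tbl <- feature_table(do.call(rbind, rows[!vapply(rows, is.null, logical(1))]))
    attr(tbl, "truth") <- list(
      baseline = stats::setNames(baseline, lay$names),
      scale = stats::setNames(unname(s_v), lay$names),
      effect_std = stats::setNames(effect, lay$names),
      affected = lay$names[affected],
      age_slope = stats::setNames(age_v, lay$names),
      sex_shift = stats::setNames(sex_v, lay$names),
      gamma_std = structure(gamma, dimnames = list(
        vapply(specs, `[[`, character(1), "scanner_id"), lay$names)),
      delta = structure(delta, dimnames = list(
        vapply(specs, `[[`, character(1), "scanner_id"), lay$names)),
      family = stats::setNames(lay$family, lay$names),
      pair = stats::setNames(lay$pair, lay$names))
    tbl
  })
}
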