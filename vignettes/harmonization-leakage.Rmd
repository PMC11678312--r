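---
title: "Harmonization, cross-validation, and label leakage in multi-scanner morphometry classification"
author: "combatcv"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Harmonization, cross-validation, and label leakage}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The model

ComBat treats scanner (batch) effects as a location-scale perturbation.
Per feature $v$, subject $j$ on scanner $i$:

$$Y_{ijv} = \alpha_v + X_j \beta_v + \gamma_{iv} + \delta_{iv}\,\varepsilon_{ijv},
\qquad \varepsilon_{ijv} \sim N(0, \sigma_v^2).$$

$X$ holds the biological covariates whose effects must be *preserved*
(age and sex by default; the diagnostic group only in the deliberate
leakage configuration).  Fitting proceeds in three steps:

1. **Standardization.** Per-feature least squares on the full design
   (one indicator per scanner plus $X$), with the identifying constraint
   $\sum_i (n_i/N)\,\gamma_{iv} = 0$, i.e. $\hat\alpha_v$ is the
   batch-size-weighted grand mean.  $\hat\sigma_v^2$ is the mean squared
   residual over all $N$ subjects.  The standardized data
   $Z = (Y - \hat\alpha - X\hat\beta)/\hat\sigma$ still contain the
   batch deviations.
2. **Empirical-Bayes priors.** Per scanner, the cross-feature mean and
   variance of the $\hat\gamma_{iv}$ give a normal prior
   $(\bar\gamma_i, \bar\tau_i^2)$; the cross-feature mean $V_i$ and
   variance $S_i$ of the $\hat\delta^2_{iv}$ give an inverse-gamma prior
   via the method of moments,
   $\bar\lambda_i = (V_i^2 + 2S_i)/S_i$,
   $\bar\theta_i = (V_i^3 + V_i S_i)/S_i$.
3. **Shrinkage and removal.** The conditional posteriors
   $$\gamma^*_{iv} = \frac{n_i \bar\tau_i^2 \hat\gamma_{iv} +
     \delta^{2*}_{iv}\bar\gamma_i}{n_i \bar\tau_i^2 + \delta^{2*}_{iv}},
   \qquad
   \delta^{2*}_{iv} = \frac{\bar\theta_i + \tfrac12\sum_j (Z_{ijv}-\gamma^*_{iv})^2}
        {n_i/2 + \bar\lambda_i - 1}$$
   are iterated to a fixed point and removed:
   $Y^* = (\hat\sigma/\delta^*)(Z - \gamma^*) + \hat\alpha + X\hat\beta$.

The model assumes additive/multiplicative batch effects that are
exchangeable across features within a scanner — which is exactly what
gives the empirical-Bayes step its strength (features borrow each
other's batch estimates) and its blind spot (feature-specific artefacts
are over-shrunk).

### Numerical conventions

* The EB iteration stops when the largest parameter change *relative to
  the previous iterate* drops below `tol` (default `1e-4`, cap
  `max_iter = 500` with a warning).  The relative criterion — including
  its signed denominator — is the convention of the widely used ComBat
  implementations; we keep it so that `combat_fit()` output is
  reproducible against them to ~1e-12 on shared instances (the test
  suite asserts agreement with `sva::ComBat` to 1e-6).  A 0/0 change
  (parameter pinned at zero) counts as converged.
* Zero-variance features and rank-deficient designs (e.g. a covariate
  perfectly confounded with scanner) are errors, named explicitly.
* If the per-scanner scale estimates are constant across features the
  inverse-gamma prior is undefined; that scanner falls back to its raw
  estimates with a warning (`eb_mode = "no_eb"` behaviour).
* With a single scanner there is no batch structure to estimate and the
  transform is defined as the identity, rather than the spurious
  $\sqrt{N/(N-1)}$ rescaling the estimator conventions would otherwise
  produce.
* `min_batch` defaults to 20 subjects per scanner in `combat_fit()`,
  following the common guidance of roughly twenty scans per scanner for
  stable estimates.  `harmonize_splits()` lowers the default to 4
  because fold-level fit sets are subsets of a cohort that already
  passed the full-fit threshold.

## Fit-split strategies and the leakage pathway

`harmonize_splits()` always transforms *every* row; the strategy decides
the fit set: nothing (`none`), the current fold's training rows
(`fit_train_only`), all non-test rows (`fit_train_valid`), everything
including the test set (`fit_all` — transductive: test features, though
not labels, inform the transform), or the fold's training rows with the
diagnostic group added to $X$ (`fit_train_only_group`).

The last strategy is kept deliberately.  Because the transform re-adds
$X\hat\beta$, a model with a group covariate cannot harmonize a row
without knowing its label — `predict()` errors on unlabeled rows and
messages on every label-dependent use.  Even though the *fit* uses
training rows only, the *transform* injects a label-dependent shift
$\hat\beta_{group}$ into every validation and test row, identically in
training and test.  Under a pure null with scanner-group confounding,
$\hat\beta_{group}$ is nothing but collinearity-inflated estimation
noise — yet it is *shared* noise, and a classifier reads it straight
back off the features.  This is the circularity the package exists to
demonstrate.

## What the synthetic generator emulates

`generate_cohort()` draws feature tables from the same location-scale
family the harmonizer assumes, with known ground truth attached
(`attr(, "truth")`):

* **Reference cohort** (`default_cohort_config()`): 11 scanners with the
  per-scanner PD/HV counts, pooled age distributions and sex ratios of
  the published multi-site PD cohort this package models — 216 PD and
  155 HV subjects.  (The published per-scanner rows sum to 155 HV while
  the accompanying text reports 156; the generator follows the table
  rows and we flag, rather than resolve, the one-subject discrepancy.)
  Batch-effect locations/scales per scanner are package defaults
  spanning additive shifts within one residual SD and scales 0.7–1.4,
  a range typical of multi-site volumetry after a shared pipeline.
* **Per-feature heterogeneity**: scanner effects are drawn
  $\gamma_{iv} \sim N(\gamma_i,\ 0.25|\gamma_i| + 0.05)$ and
  $\delta_{iv} \sim \mathrm{LogNormal}(\log \delta_i,\ 0.1)$, giving the
  cross-feature spread the EB priors need to be meaningful.
* **Covariates**: age effects per decade (centred at 60 y) and a
  male/female shift, in residual-SD units (defaults 0.1 and 0.2).
* **Feature families**: `FS_` features are volume-like (baselines
  500–5000 mm³, residual SD ~50 mm³, divisible by a log-normal eTIV of
  ~1.5×10⁶ mm³); `DOJ_` features sit near 1 (no deformation, so the
  −1 preparation shift centres them at 0) with residual SD ~0.05.
  A configurable fraction of features comes as `_L`/`_R` hemisphere
  pairs sharing their baseline and half their noise variance, which is
  what makes flip augmentation meaningful.
* **Confounding** (`confound_strength` $c$): group prevalence per
  scanner alternates between $0.5 \pm 0.45c$, keeping scanner sizes
  fixed.  This isolates *population* confounding from the measurement
  model: features never depend on the group in a confounded null
  cohort.
* **Encodings**, used everywhere: group PD→1, HV→0; sex M→1, F→0.

What it does **not** emulate: registration/segmentation failures,
heavy-tailed or feature-specific artefacts, site differences in age
*ranges* (only means/SDs), longitudinal structure, and genuine disease
heterogeneity.  Passing tests on these cohorts show the pipeline's
logic is right, not that real PD morphometry is this well behaved.

## Experiment design choices

* **Splits**: 20% stratified holdout over scanner × age-tertile × sex ×
  group strata (strata under 2 subjects merge upward, dropping the age
  bin first, then sex; tertiles are the package's choice for binning a
  continuous covariate for stratification).  Remaining subjects get
  group-stratified $k$-fold CV (default 5) or LOOCV for single-scanner
  runs, where the AUC is computed over the pooled leave-one-out scores.
* **Balancing** is applied to training folds only — the API makes the
  violation impossible rather than discouraged: `balance_training_set()`
  is the only entry point the pipeline uses and it only ever receives
  the training fold.  Flip augmentation runs before SMOTE/RUS so
  mirrored rows take part in the neighbour search; the order is this
  package's choice (it maximizes minority support) and is not claimed
  to match any published pipeline.  SMOTE uses $k = 5$ neighbours by
  default (the classical default) with Euclidean distance on the
  prepared features, unrescaled, since harmonized output is already
  variance-aligned.
* **Search**: `n_iter` defaults to 200 configurations (large published
  searches go to 10,000; the default keeps desk runtime sane and is
  configurable up).  Hyperparameter ranges are package defaults:
  log-uniform regularization for the linear models, depth 2–8 and
  50–500 trees for the ensembles.  Ties in the best-trial argmax break
  toward the earliest trial, for reproducibility.  Only the winning
  configuration is refitted on all non-test rows and scored once on the
  holdout.
* **Metrics**: rank-based AUC (ties credited ½, the Mann–Whitney
  convention) and balanced accuracy.  Scanner-level aggregation reports
  mean ± sample (n−1) SD across scanners with a defined AUC;
  single-class scanners are flagged, not dropped silently.

## The two packaged experiments

`leakage_demo_config()` — six scanners × 40 subjects, 240 features
(150 FS + 90 DOJ), *no* group effect, confounding 0.8 (prevalence
86%/14%).  The feature-to-subject ratio of ~1 matches the
dimensionality regime of real multi-site morphometry (hundreds of
regional features for a few hundred subjects); the label-injection
artefact grows with this ratio, so preserving it matters for a faithful
scaled-down demonstration.  The confounding level is deliberately in the
strong-cofactor regime: with mild confounding the same mechanism exists
but its magnitude shrinks with the scanner–group collinearity (readers
can verify the dose–response by lowering `confound_strength`).  Over 20
replicates the group-covariate strategy exceeds the leakage-safe one by
roughly 0.16 test AUC while the safe strategy stays at chance.

`harmonization_benefit_config()` — the complementary setting: a true
group effect (0.4 SD on 30% of features), the same batch effects, no
confounding.  Leakage-safe harmonization beats no harmonization by
~0.05 validation AUC, paired over 20 seeds.

Both experiments run with a small fixed search budget (penalized
logistic regression, 2 trials, 5-fold CV) — enough for the comparison,
small enough that the full suite and the acceptance script finish in
about a minute each; these problem sizes are the package's scaling
choice for replicated simulation.

## Known limitations

* Scanners absent from the harmonization fit cannot be transformed; the
  model has no way to predict a novel site's parameters.
* Parametric EB is the only shrinkage mode beyond `no_eb`;
  non-parametric EB, reference-site ("modified") ComBat and
  longitudinal variants are out of scope.
* The single-scanner driver refuses harmonization by construction
  (one site has no batch structure), and its pooled-LOOCV AUC is noisy
  at realistic scanner sizes — intercept-dominated configurations can
  even score *below* chance, a known artefact of pooling leave-one-out
  scores from class-imbalance-sensitive models.
* The generator's confounding knob moves group prevalence only;
  real neurobiological cofactors (severity, duration, diagnostic
  criteria differing by site) can also change feature *distributions*
  within a group, which is harder, not easier, for harmonization.
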