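# The harmonization core: standardization, hyperpriors, EB iteration,
# fitting and applying, with independent closed-form/oracle checks.

test_that("standardization recovers the weighted grand mean and symmetric batch effects", {
  tbl <- two_batch_table(n1 = 60, n2 = 60, shift = 10, seed = 2)
  Y <- feature_matrix(tbl) + 10  # batch means ~10 and ~20
  std <- combat_standardize(Y, NULL, tbl$scanner)
  # closed-form oracle: alpha is the batch-size-weighted mean of batch means
  bm <- rowsum(Y, tbl$scanner) / as.vector(table(tbl$scanner))
  expect_equal(unname(std$alpha_hat), unname(colMeans(bm)), tolerance = 1e-12)
  expect_equal(unname(std$alpha_hat), rep(15, ncol(Y)), tolerance = 0.5)
  # equal batch sizes make the standardized batch means symmetric about 0
  expect_equal(std$gamma_hat[1, ], -std$gamma_hat[2, ], tolerance = 1e-10)
  # Z is centred, with unit pooled *residual* variance per feature
  # (the batch deviations themselves stay in Z until the EB step)
  expect_equal(unname(colMeans(std$Z)), rep(0, ncol(Y)), tolerance = 1e-12)
  resid <- std$Z - std$gamma_hat[match(tbl$scanner, std$batch_ids), ]
  expect_equal(unname(colMeans(resid^2)), rep(1, ncol(Y)), tolerance = 1e-10)
})

test_that("standardization of standard-normal data is close to the identity", {
  set.seed(8)
  n <- 10000
  Y <- matrix(rnorm(2 * n), n, 2, dimnames = list(NULL, c("f1", "f2")))
  std <- combat_standardize(Y, NULL, rep("one", n))
  se_mean <- 1 / sqrt(n)
  se_sd <- 1 / sqrt(2 * n)
  expect_true(all(abs(std$alpha_hat) < 3 * se_mean))
  expect_true(all(abs(std$sigma_hat - 1) < 3 * se_sd))
})

test_that("degenerate designs and features are rejected by name", {
  tbl <- two_batch_table(p = 3)
  Y <- feature_matrix(tbl)
  Y[, 2] <- 7
  expect_error(combat_standardize(Y, NULL, tbl$scanner), "DOJ_mid02")
  # covariate identical to the batch indicator -> rank deficient
  X <- cbind(conf = as.numeric(tbl$scanner == "b1"))
  expect_error(combat_standardize(feature_matrix(tbl), X, tbl$scanner),
               "rank-deficient")
  expect_error(combat_standardize(feature_matrix(tbl), NULL,
                                  c("solo", tbl$scanner[-1])),
               "at least 2 subjects")
})

test_that("hyperprior moments match the inverse-gamma closed forms", {
  # cross-feature delta^2 of (1, 2, 3): V = 2, S = 1 -> lambda 6, theta 10
  gamma_hat <- rbind(b1 = c(0.1, 0.2, 0.3))
  delta2_hat <- rbind(b1 = c(1, 2, 3))
  pr <- eb_hyperpriors(gamma_hat, delta2_hat)
  expect_equal(pr$lambda_bar, 6)
  expect_equal(pr$theta_bar, 10)
  # and inverse-gamma(6, 10) indeed has mean 2 and variance 1
  expect_equal(pr$theta_bar / (pr$lambda_bar - 1), 2)
  expect_equal(pr$theta_bar^2 / ((pr$lambda_bar - 1)^2 * (pr$lambda_bar - 2)), 1)
  expect_equal(pr$gamma_bar, 0.2)
  expect_equal(pr$tau2_bar, stats::var(c(0.1, 0.2, 0.3)))
})

test_that("hyperprior location estimates are consistent in many features", {
  set.seed(13)
  g <- matrix(rnorm(5000, 0.5, 0.2), 1, dimnames = list("b", NULL))
  d <- matrix(1 / rgamma(5000, 6, 10), 1, dimnames = list("b", NULL))
  pr <- eb_hyperpriors(g, d)
  expect_equal(pr$gamma_bar, 0.5, tolerance = 0.01)
  expect_lt(abs(pr$tau2_bar - 0.04), 0.004)
})

test_that("constant scale estimates trigger the no-shrinkage fallback", {
  g <- rbind(b1 = c(0.1, 0.4, -0.2))
  d <- rbind(b1 = c(2, 2, 2))
  expect_warning(pr <- eb_hyperpriors(g, d), "no empirical-Bayes")
  expect_false(pr$moments_ok)
  # eb_adjust then keeps the raw estimates for that batch
  set.seed(4)
  Z <- matrix(rnorm(30), 10, 3)
  adj <- eb_adjust(Z, rep("b1", 10), pr)
  expect_equal(adj$gamma_star, rowsum(Z, rep("b1", 10)) / 10)
})

test_that("EB shrinkage vanishes for huge batches and is total for tau2 -> 0", {
  set.seed(17)
  n <- 1e5
  Z <- matrix(rnorm(n * 3, mean = rep(c(0.5, -0.3, 0.1), each = n)), n, 3)
  batch <- rep("big", n)
  g_hat <- rowsum(Z, batch) / n
  pr <- data.frame(batch = "big", gamma_bar = 0, tau2_bar = 0.05,
                   lambda_bar = 5, theta_bar = 5, moments_ok = TRUE)
  adj <- eb_adjust(Z, batch, pr)
  expect_true(all(abs(adj$gamma_star - g_hat) < 1e-3))
  # prior variance -> 0 forces gamma* to the prior mean exactly
  pr0 <- pr; pr0$tau2_bar <- 0
  adj0 <- eb_adjust(Z, batch, pr0)
  expect_true(all(adj0$gamma_star == 0))
})

test_that("the EB iteration matches an independently coded fixed point", {
  set.seed(23)
  n_per <- 25; p <- 20
  batch <- rep(c("x", "y", "z"), each = n_per)
  Z <- matrix(rnorm(3 * n_per * p), 3 * n_per, p) +
    rep(c(-0.5, 0.2, 0.6), each = n_per)
  g_hat <- rowsum(Z, batch) / n_per
  d2_hat <- (rowsum(Z^2, batch) - n_per * g_hat^2) / (n_per - 1)
  pr <- eb_hyperpriors(g_hat, d2_hat)
  adj <- eb_adjust(Z, batch, pr, tol = 1e-13, max_iter = 10000)
  # oracle: scalar per-feature iteration, written separately, absolute
  # tolerance, iterated far past convergence
  for (b in 1:3) {
    Zb <- Z[batch == c("x", "y", "z")[b], , drop = FALSE]
    for (v in seq_len(p)) {
      g <- g_hat[b, v]; d2 <- d2_hat[b, v]
      for (i in 1:10000) {
        g_new <- (n_per * pr$tau2_bar[b] * g_hat[b, v] + d2 * pr$gamma_bar[b]) /
          (n_per * pr$tau2_bar[b] + d2)
        d2_new <- (pr$theta_bar[b] + 0.5 * sum((Zb[, v] - g_new)^2)) /
          (n_per / 2 + pr$lambda_bar[b] - 1)
        if (max(abs(g_new - g), abs(d2_new - d2)) < 1e-12) break
        g <- g_new; d2 <- d2_new
      }
      expect_lt(abs(adj$gamma_star[b, v] - g_new), 1e-8)
      expect_lt(abs(adj$delta2_star[b, v] - d2_new), 1e-8)
    }
  }
})

test_that("gamma* always lies between the raw estimate and the prior mean", {
  tbl <- small_cohort(n_scanners = 4, n_per_group = 12, seed = 29)
  fit <- combat_fit(tbl, min_batch = 4)
  for (b in seq_along(fit$batch_ids)) {
    lo <- pmin(fit$gamma_hat[b, ], fit$hyperpriors$gamma_bar[b])
    hi <- pmax(fit$gamma_hat[b, ], fit$hyperpriors$gamma_bar[b])
    expect_true(all(fit$gamma_star[b, ] >= lo - 1e-10))
    expect_true(all(fit$gamma_star[b, ] <= hi + 1e-10))
  }
  expect_true(all(fit$delta2_star > 0))
  expect_true(all(fit$sigma_hat > 0))
})

test_that("small batches are refused with the ~20-scan guidance", {
  tbl <- small_cohort(n_scanners = 2, n_per_group = 8)
  expect_error(combat_fit(tbl), "~20 scans")
  expect_s3_class(combat_fit(tbl, min_batch = 4), "combat")
})

test_that("a single-site fit is the identity transform", {
  cfg <- cohort_config(scanner_spec("solo", 15, 15), n_features_fs = 0,
                       n_features_doj = 10, seed = 37)
  tbl <- generate_cohort(cfg)
  fit <- combat_fit(tbl, eb_mode = "no_eb", min_batch = 4)
  h <- predict(fit, tbl)
  expect_equal(feature_matrix(h), feature_matrix(tbl), tolerance = 1e-12)
  expect_true(max(abs(feature_matrix(h) - feature_matrix(tbl))) < 1e-10)
})

test_that("no_eb harmonization equals an independent mean/variance alignment", {
  tbl <- two_batch_table(n1 = 40, n2 = 60, shift = 3, scale = 1.7, seed = 41)
  fit <- combat_fit(tbl, use_age = FALSE, use_sex = FALSE,
                    eb_mode = "no_eb", min_batch = 4)
  h <- feature_matrix(predict(fit, tbl))
  # oracle: per feature, align each batch to the weighted grand mean and
  # rescale deviations by pooled-sigma / within-batch sd
  Y <- feature_matrix(tbl)
  batch <- tbl$scanner
  oracle <- Y
  for (v in seq_len(ncol(Y))) {
    m <- tapply(Y[, v], batch, mean)
    s <- tapply(Y[, v], batch, sd)
    n_i <- table(batch)
    alpha <- sum(n_i / nrow(Y) * m)
    sigma <- sqrt(mean((Y[, v] - m[batch])^2))
    oracle[, v] <- alpha + sigma * (Y[, v] - m[batch]) / s[batch]
  }
  expect_true(max(abs(h - oracle)) < 1e-10)
})

test_that("injected two-batch location/scale effects are recovered", {
  specs <- list(scanner_spec("ref", 250, 250, gamma_loc = 0, delta_scale = 1),
                scanner_spec("shift", 250, 250, gamma_loc = 2, delta_scale = 2))
  cfg <- cohort_config(specs, n_features_fs = 60, n_features_doj = 40,
                       group_effect_size = 0, age_slope = 0, sex_shift = 0,
                       seed = 43)
  tbl <- generate_cohort(cfg)
  truth <- attr(tbl, "truth")
  fit <- combat_fit(tbl, eb_mode = "no_eb")
  # de-standardize: per-feature batch shift in generator units
  shift_rec <- (fit$gamma_hat["shift", ] - fit$gamma_hat["ref", ]) *
    fit$sigma_hat / truth$scale
  shift_true <- truth$gamma_std["shift", ] - truth$gamma_std["ref", ]
  expect_lt(mean(abs(shift_rec - shift_true)), 0.1)
  expect_equal(mean(shift_rec), 2, tolerance = 0.1)
  ratio_rec <- sqrt(fit$delta2_hat["shift", ] / fit$delta2_hat["ref", ])
  ratio_true <- truth$delta["shift", ] / truth$delta["ref", ]
  expect_true(all(ratio_rec / ratio_true > 0.85 & ratio_rec / ratio_true < 1.18))
  expect_gt(exp(mean(log(ratio_rec))), 0.9 * 2)
  expect_lt(exp(mean(log(ratio_rec))), 1.1 * 2)
})

test_that("applying a fitted model is consistent and label-safe", {
  tbl <- small_cohort(n_scanners = 3, n_per_group = 15, seed = 47)
  fit <- combat_fit(tbl, min_batch = 4)
  h1 <- predict(fit, tbl)
  h2 <- predict(fit, tbl)
  expect_identical(feature_matrix(h1), feature_matrix(h2))
  # and equals the stored-fit reconstruction exactly
  bi <- match(fit$batch, fit$batch_ids)
  sig <- matrix(fit$sigma_hat, nrow(tbl), length(fit$sigma_hat), byrow = TRUE)
  X <- cbind(age = tbl$age, sex = as.numeric(tbl$sex == "M"))
  sm <- matrix(fit$alpha_hat, nrow(tbl), ncol(sig), byrow = TRUE) +
    X %*% fit$beta_hat
  manual <- sig / sqrt(fit$delta2_star)[bi, ] * (fit$Z - fit$gamma_star[bi, ]) + sm
  expect_equal(unname(feature_matrix(h1)), unname(manual), tolerance = 1e-12)
  # unseen scanner refused
  novel <- tbl; novel$scanner[1] <- "brand_new"
  expect_error(predict(fit, novel), "novel scanners")
  # without a group covariate, labels cannot influence the transform
  perm <- tbl; perm$group <- sample(perm$group)
  expect_identical(feature_matrix(predict(fit, perm)), feature_matrix(h1))
})

test_that("label-dependent models demand labels and say so", {
  tbl <- small_cohort(n_scanners = 3, n_per_group = 15, seed = 53)
  fit <- combat_fit(tbl, use_group = TRUE, min_batch = 4)
  expect_message(predict(fit, tbl), "label-dependent")
  stripped <- tbl; stripped$group[1:5] <- NA
  expect_error(suppressMessages(predict(fit, stripped)), "group labels")
  # flipping one subject's label changes that subject's features
  flipped <- tbl
  flipped$group[1] <- ifelse(tbl$group[1] == "PD", "HV", "PD")
  h0 <- suppressMessages(predict(fit, tbl))
  h1 <- suppressMessages(predict(fit, flipped))
  expect_false(isTRUE(all.equal(feature_matrix(h0)[1, ],
                                feature_matrix(h1)[1, ])))
  expect_equal(feature_matrix(h0)[-1, ], feature_matrix(h1)[-1, ])
})

test_that("harmonization removes batch means and equalizes scales", {
  specs <- list(scanner_spec("lo", 50, 50, gamma_loc = -1, delta_scale = 0.5),
                scanner_spec("hi", 50, 50, gamma_loc = 1, delta_scale = 2))
  cfg <- cohort_config(specs, n_features_fs = 50, n_features_doj = 50,
                       group_effect_size = 0, age_slope = 0, sex_shift = 0,
                       seed = 59)
  tbl <- generate_cohort(cfg)
  h <- feature_matrix(predict(combat_fit(tbl), tbl))
  lo <- tbl$scanner == "lo"
  d <- colMeans(h[lo, ]) - colMeans(h[!lo, ])
  se <- sqrt(apply(h[lo, ], 2, var) / 50 + apply(h[!lo, ], 2, var) / 50)
  expect_true(all(abs(d) < 4 * se))
  ratio <- apply(h[!lo, ], 2, var) / apply(h[lo, ], 2, var)
  expect_true(exp(mean(log(ratio))) > 0.8 && exp(mean(log(ratio))) < 1.25)
  expect_gt(mean(ratio > 0.7 & ratio < 1.43), 0.8)
})

test_that("a fitted model survives JSON serialization", {
  tbl <- small_cohort(n_scanners = 3, n_per_group = 15, seed = 61)
  fit <- combat_fit(tbl, min_batch = 4)
  path <- tempfile(fileext = ".json")
  combat_to_json(fit, path)
  back <- combat_from_json(path)
  expect_equal(feature_matrix(predict(back, tbl)),
               feature_matrix(predict(fit, tbl)), tolerance = 1e-12)
  unlink(path)
})
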