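test_that("random undersampling equalizes strata and subsets the input", {
  # group sizes mirroring the reference cohort: 216 PD vs 156 HV
  specs <- list(scanner_spec("s1", 116, 70), scanner_spec("s2", 100, 86))
  tbl <- generate_cohort(cohort_config(specs, n_features_fs = 4,
                                       n_features_doj = 2, seed = 9))
  out <- random_undersample(tbl, by = "group", seed = 3)
  expect_equal(as.vector(table(out$group)), c(156, 156))
  expect_true(all(out$subject_id %in% tbl$subject_id))
  # deterministic given the seed
  expect_identical(as.data.frame(random_undersample(tbl, "group", seed = 3)),
                   as.data.frame(out))
  expect_false(identical(random_undersample(tbl, "group", seed = 4)$subject_id,
                         out$subject_id))
  # already balanced strata come back unchanged as a multiset
  bal <- random_undersample(out, by = "group", seed = 5)
  expect_setequal(bal$subject_id, out$subject_id)
  # group x scanner strata
  oxs <- random_undersample(tbl, by = "group_x_scanner", seed = 6)
  cells <- table(oxs$group, oxs$scanner)
  expect_true(all(cells == min(table(tbl$group, tbl$scanner))))
})

test_that("SMOTE interpolates between minority neighbours", {
  # two minority points with k = 1: every synthetic point must lie on
  # the segment between them
  df <- data.frame(subject_id = sprintf("s%d", 1:8),
                   scanner = "sc", group = c(rep("PD", 6), "HV", "HV"),
                   age = 60, sex = "M",
                   FS_a = c(rnorm(6), 0, 10), FS_b = c(rnorm(6), 0, 10),
                   stringsAsFactors = FALSE)
  tbl <- feature_table(df)
  out <- smote(tbl, by = "group", k = 1, seed = 2)
  syn <- out[grepl("_syn", out$subject_id), ]
  expect_equal(nrow(syn), 4)  # 6 PD vs 2 HV -> 4 synthetic HVs
  lam <- syn$FS_a / 10
  expect_true(all(lam >= 0 & lam <= 1))
  expect_equal(syn$FS_a, syn$FS_b)  # colinear endpoints stay colinear
  expect_true(all(syn$group == "HV"))
})

test_that("SMOTE output contains the input and reaches the max stratum size", {
  specs <- list(scanner_spec("s1", 30, 10))
  tbl <- generate_cohort(cohort_config(specs, n_features_fs = 6,
                                       n_features_doj = 4, seed = 19))
  out <- smote(tbl, by = "group", k = 5, seed = 7)
  expect_equal(as.vector(table(out$group)), c(30, 30))
  expect_true(all(tbl$subject_id %in% out$subject_id))
  # every synthetic row is a convex combination of a minority row and
  # one of its k nearest minority neighbours (brute-force check)
  X <- feature_matrix(tbl)[tbl$group == "HV", ]
  syn <- feature_matrix(out)[grepl("_syn", out$subject_id), , drop = FALSE]
  d <- as.matrix(dist(X)); diag(d) <- Inf
  ok <- apply(syn, 1, function(z) {
    for (i in seq_len(nrow(X))) {
      for (j in order(d[i, ])[1:5]) {
        dir <- X[j, ] - X[i, ]
        lam <- sum((z - X[i, ]) * dir) / sum(dir^2)
        if (lam >= -1e-8 && lam <= 1 + 1e-8 &&
            sqrt(sum((X[i, ] + lam * dir - z)^2)) < 1e-8) return(TRUE)
      }
    }
    FALSE
  })
  expect_true(all(ok))
})

test_that("SMOTE guards degenerate strata", {
  df <- as.data.frame(tiny_table())[1:3, ]  # 2 PD, 1 HV
  tbl <- feature_table(df)
  expect_error(smote(tbl, by = "group", k = 1), "RUS or NONE")
  # balanced strata: no synthetic rows at all
  expect_identical(as.data.frame(smote(tiny_table(), "group", k = 1)),
                   as.data.frame(tiny_table()))
  # k larger than the stratum supports is lowered with a warning
  df3 <- as.data.frame(tiny_table())  # 2 PD, 2 HV
  df3 <- rbind(df3, within(df3[1, ], subject_id <- "e"))  # 3 PD, 2 HV
  expect_warning(smote(feature_table(df3), "group", k = 5, seed = 1),
                 "k lowered")
})

test_that("flip augmentation mirrors hemisphere pairs exactly", {
  tbl <- tiny_table()
  out <- flip_augment(tbl)
  expect_equal(nrow(out), 2 * nrow(tbl))
  mir <- out[grepl("_flip$", out$subject_id), ]
  expect_equal(mir$FS_roi01_L, tbl$FS_roi01_R)
  expect_equal(mir$FS_roi01_R, tbl$FS_roi01_L)
  expect_equal(mir$DOJ_mid01, tbl$DOJ_mid01)  # midline copied unchanged
  expect_equal(mir$group, tbl$group)
  expect_equal(mir$age, tbl$age)
  # group counts double exactly
  expect_equal(as.vector(table(out$group)), 2 * as.vector(table(tbl$group)))
  # a table with only midline features mirrors to identical copies
  mid <- tiny_table()[, c(names(tiny_table())[1:6], "DOJ_mid01")]
  mid <- feature_table(as.data.frame(mid))
  mout <- flip_augment(mid)
  expect_equal(mout$DOJ_mid01, rep(mid$DOJ_mid01, 2))
})

test_that("balance_training_set composes flip then the balancing method", {
  tbl <- small_cohort(n_scanners = 2, n_per_group = 10, seed = 23)
  expect_identical(balance_training_set(tbl, balance_config("none")), tbl)
  ru <- balance_training_set(tbl, balance_config("rus", "group", seed = 2))
  expect_equal(length(unique(table(ru$group))), 1)
  # flip doubles before balancing, so mirrored rows join the pool
  fl <- balance_training_set(tbl, balance_config("none", flip = TRUE))
  expect_equal(nrow(fl), 2 * nrow(tbl))
  sm <- balance_training_set(
    random_undersample(tbl, "group_x_scanner", seed = 1)[-1, ] |>
      (\(d) {class(d) <- class(tbl); d})(),
    balance_config("smote", "group_x_scanner", smote_k = 2, seed = 3))
  cells <- table(sm$group, sm$scanner)
  expect_true(all(cells == max(cells)))
})
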