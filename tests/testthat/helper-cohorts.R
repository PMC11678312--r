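# Fixture builders shared across the suite.  Everything is generated in
# code; no data files.

# hand-built two-batch table with exact batch means/scales on top of
# N(0, sd) noise; features on an O(1) scale
two_batch_table <- function(n1 = 50, n2 = 50, shift = 2, scale = 1,
                            p = 10, sd = 1, seed = 1) {
  set.seed(seed)
  base <- matrix(rnorm((n1 + n2) * p, sd = sd), n1 + n2, p)
  base[seq_len(n1) + n2, ] <- base[seq_len(n1) + n2, ] * scale + shift
  colnames(base) <- sprintf("DOJ_mid%02d", seq_len(p))
  feature_table(cbind(
    data.frame(subject_id = sprintf("s%03d", seq_len(n1 + n2)),
               scanner = rep(c("b1", "b2"), c(n2, n1)),
               group = rep(c("PD", "HV"), length.out = n1 + n2),
               age = round(runif(n1 + n2, 45, 80)),
               sex = rep(c("M", "F"), length.out = n1 + n2),
               stringsAsFactors = FALSE),
    as.data.frame(base)))
}

# tiny handmade table for structural tests
tiny_table <- function() {
  feature_table(data.frame(
    subject_id = c("a", "b", "c", "d"),
    scanner = c("s1", "s1", "s2", "s2"),
    group = c("PD", "HV", "PD", "HV"),
    age = c(61, 59, 70, 66),
    sex = c("M", "F", "M", "F"),
    etiv = c(1.4e6, 1.6e6, 1.5e6, 1.5e6),
    FS_roi01_L = c(1, 3, 5, 7),
    FS_roi01_R = c(2, 4, 6, 8),
    DOJ_mid01 = c(1.0, 1.1, 0.9, 1.05),
    stringsAsFactors = FALSE))
}

# small generated multi-scanner cohort
small_cohort <- function(n_scanners = 3, n_per_group = 15, seed = 5, ...) {
  gammas <- c(0.8, -0.6, 0.2, -0.9, 0.5)
  scanners <- lapply(seq_len(n_scanners), function(i) {
    scanner_spec(sprintf("sc%d", i), n_per_group, n_per_group,
                 gamma_loc = gammas[i], delta_scale = 1 + 0.1 * i)
  })
  generate_cohort(cohort_config(scanners, n_features_fs = 12,
                                n_features_doj = 8, seed = seed, ...))
}
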