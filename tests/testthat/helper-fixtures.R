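# Small in-code fixtures shared across test files.

# tiny FPKM matrix with exactly representable values
tiny_expr <- function() {
  m <- matrix(c(0.5, 1.25, 2, 4, 0, 8), nrow = 3, byrow = TRUE,
              dimnames = list(c("GA", "GB", "GC"), c("s1", "s2")))
  m
}

# clinical table constructor with sensible defaults
make_clinical <- function(sample, ER = "negative", PR = "negative",
                          HER2 = "negative", PAM50 = "Basal",
                          OS_time = 10.5, OS_event = 1L,
                          DMFS_time = 10.5, DMFS_event = 1L) {
  data.frame(sample = sample, ER = ER, PR = PR, HER2 = HER2, PAM50 = PAM50,
             OS_time = OS_time, OS_event = OS_event,
             DMFS_time = DMFS_time, DMFS_event = DMFS_event,
             stringsAsFactors = FALSE)
}

# a small planted cohort used by several DEG tests
small_planted_cohort <- function(seed = 42) {
  simulate_cohort(cohort_spec(n_patients = 80, n_genes = 300,
                              planted_genes = sprintf("CAND%02d", 1:10),
                              planted_down_genes = sprintf("DOWN%02d", 1:10),
                              seed = seed))
}

# independent brute-force two-sided permutation p-value via full enumeration,
# with the Welch statistic taken from stats::t.test (independent of the
# package's vectorized implementation)
brute_force_perm_p <- function(values, is_a) {
  na <- sum(is_a)
  t_of <- function(idx) {
    stats::t.test(values[idx], values[-idx], var.equal = FALSE)$statistic
  }
  t_obs <- t_of(which(is_a))
  combs <- utils::combn(length(values), na)
  t_all <- apply(combs, 2, t_of)
  mean(abs(t_all) >= abs(t_obs) - 1e-12)
}
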