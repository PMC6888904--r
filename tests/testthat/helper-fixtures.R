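# Small in-code fixtures shared across test files.

# A 3-CpG toy clock with hand-checkable weights.
toy_clock <- function() {
  clock_model(intercept = 0.696,
              coefficients = c(cg01 = 1.0, cg02 = -0.5, cg03 = 0.25),
              name = "toy")
}

# A deterministic 3 CpG x 2 sample beta matrix (with one missing value
# unless filled).
toy_betas <- function(with_na = FALSE) {
  v <- matrix(c(0.10, 0.55, 0.90,
                0.20, 0.45, 0.80),
              nrow = 3, dimnames = list(c("cg01", "cg02", "cg03"),
                                        c("samp1", "samp2")))
  if (with_na) v[2, 2] <- NA
  beta_matrix(v, platform = "450k")
}

# Random valid beta matrix for property-style tests.
random_betas <- function(n_cpg, n_samp, seed, platform = "450k",
                         prefix = "s") {
  set.seed(seed)
  v <- matrix(runif(n_cpg * n_samp), nrow = n_cpg,
              dimnames = list(sprintf("cg%03d", seq_len(n_cpg)),
                              paste0(prefix, seq_len(n_samp))))
  beta_matrix(v, platform = platform)
}

# Noise-free simulation bundle reused by identity tests.
noise_free_sim <- function(n = 20, seed = 11, accel_per_bmi = 0,
                           n_cpgs = 40) {
  cfg <- sim_config(n_subjects = n, seed = seed, beta_noise_sd = 0,
                    accel_noise_sd = 0, accel_per_bmi_unit = accel_per_bmi,
                    n_clock_cpgs = n_cpgs, epic_missing_cpgs = 0)
  cohort <- simulate_cohort(cfg)
  truth <- make_truth_clock(n_cpgs, seed = seed + 1)
  list(cfg = cfg, cohort = cohort, truth = truth)
}
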