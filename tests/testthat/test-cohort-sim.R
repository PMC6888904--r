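test_that("invalid configurations name the offending field", {
  expect_error(sim_config(n_subjects = 3), "n_subjects")
  expect_error(sim_config(accel_noise_sd = -1), "accel_noise_sd")
  expect_error(sim_config(missing_visit_prob = 1.5), "missing_visit_prob")
  expect_error(sim_config(epic_missing_cpgs = 336), "epic_missing_cpgs")
  expect_error(sim_config(traj_base_probs = c(0.5, 0.5, 0.5)),
               "traj_base_probs")
})

test_that("cohort simulation hits the configured distributions", {
  cfg <- sim_config(n_subjects = 52, seed = 101)
  cohort <- simulate_cohort(cfg)
  expect_s3_class(cohort, "cohort_table")
  expect_equal(nrow(cohort), 52)
  # sexes balanced to within 1
  expect_lte(abs(diff(table(cohort$sex))), 1)
  # severe-obesity truncation
  expect_true(all(cohort$bmi >= 40))
  expect_true(all(cohort$chron_age >= 19 & cohort$chron_age <= 55))
  # sample means within 3 SE of configured means (truncation shifts the mean
  # upward by ~1-1.5 kg/m2, well inside 3 SE at these n)
  for (s in c("male", "female")) {
    b <- cohort$bmi[cohort$sex == s]
    se <- cfg$bmi_sd_by_sex[[s]] / sqrt(length(b))
    expect_lt(abs(mean(b) - cfg$bmi_mean_by_sex[[s]]), 3 * se + 1.6)
  }
})

test_that("zero-noise cohorts reproduce configured means exactly", {
  cfg <- sim_config(n_subjects = 4, seed = 1,
                    bmi_sd_by_sex = c(male = 0, female = 0),
                    mets_component_sd = list(waist = 0, triglycerides = 0,
                                             hdl = 0, systolic_bp = 0,
                                             diastolic_bp = 0,
                                             fasting_glucose = 0))
  cohort <- simulate_cohort(cfg)
  expect_equal(cohort$bmi[cohort$sex == "male"], rep(54.4, 2))
  expect_equal(cohort$bmi[cohort$sex == "female"], rep(48.9, 2))
  thr <- atp3_thresholds()
  expect_equal(unique(cohort$triglycerides), thr$triglycerides)
  expect_equal(unique(cohort$fasting_glucose), thr$fasting_glucose)
})

test_that("cohort simulation is byte-identical under the same seed", {
  cfg <- sim_config(n_subjects = 30, seed = 77)
  expect_identical(simulate_cohort(cfg), simulate_cohort(cfg))
  cfg2 <- sim_config(n_subjects = 30, seed = 78)
  expect_false(identical(simulate_cohort(cfg), simulate_cohort(cfg2)))
})

test_that("stored syndrome flags are coherent with classify_mets", {
  cohort <- simulate_cohort(sim_config(n_subjects = 200, seed = 5))
  cls <- classify_mets(cohort)
  expect_identical(cls$mets, cohort$mets)
  expect_identical(cls$criteria_count, cohort$mets_criteria_count)
  expect_identical(cohort$mets, cohort$mets_criteria_count >= 3L)
  # configured prevalence is approximately attained
  expect_lt(abs(mean(cohort$mets) - 0.5), 3 * sqrt(0.25 / 200))
})

test_that("syndrome classification follows the threshold conventions", {
  base <- data.frame(sex = "male", waist = 90, triglycerides = 1.0, hdl = 1.5,
                     systolic_bp = 120, diastolic_bp = 70,
                     fasting_glucose = 5.0)
  # exactly waist + TG + glucose -> positive with 3 criteria
  r <- base; r$waist <- 110; r$triglycerides <- 2.0; r$fasting_glucose <- 6.0
  cls <- classify_mets(r)
  expect_true(cls$mets); expect_equal(cls$criteria_count, 3L)
  # exactly HDL + BP -> negative with 2
  r2 <- base; r2$hdl <- 0.9; r2$systolic_bp <- 140
  cls2 <- classify_mets(r2)
  expect_false(cls2$mets); expect_equal(cls2$criteria_count, 2L)
  expect_error(classify_mets(base[, -3]), "triglycerides")
})

test_that("threshold boundaries match an enumeration oracle", {
  # oracle: independent re-statement of the >=/>/< conventions per criterion
  thr <- atp3_thresholds()
  for (sex in c("male", "female")) {
    for (bits in 0:31) {
      on <- as.logical(bitwAnd(bits, 2^(0:4)))
      eps <- 0.001
      rec <- data.frame(
        sex = sex,
        # waist is strict >: the boundary value itself does not count
        waist = thr$waist[[sex]] + if (on[1]) eps else 0,
        triglycerides = thr$triglycerides - if (on[2]) 0 else eps,  # >= counts
        hdl = thr$hdl[[sex]] - if (on[3]) eps else 0,               # strict <
        systolic_bp = thr$systolic_bp - if (on[4]) 0 else eps,      # >= counts
        diastolic_bp = thr$diastolic_bp - 30,                       # never
        fasting_glucose = thr$fasting_glucose - if (on[5]) 0 else eps)
      expected <- sum(on)
      cls <- classify_mets(rec)
      expect_equal(cls$criteria_count, expected)
      expect_equal(cls$mets, expected >= 3)
    }
  }
})

test_that("truth clocks satisfy the generative inversion identity", {
  # single-CpG arithmetic: w = 1/(n*lambda), intercept = -sum(mu*w)
  tc <- make_truth_clock(1, mu_range = c(0.5, 0.5),
                         lambda_range = c(0.01, 0.01), seed = 1)
  expect_equal(unname(tc$clock$coefficients), 100)
  expect_equal(tc$clock$intercept, -50)
  # weights/intercept reproduce the calibrated age on a grid of 100 ages
  tc2 <- make_truth_clock(30, seed = 9)
  ages <- seq(5, 70, length.out = 100)
  t_true <- calibrate_age(ages)
  betas <- outer(tc2$lambda, t_true) + tc2$mu
  scores <- tc2$clock$intercept + crossprod(betas, tc2$clock$coefficients)
  expect_equal(as.numeric(scores), t_true, tolerance = 1e-9)
  # clipping risk over the design range is rejected up front
  expect_error(make_truth_clock(5, mu_range = c(0.98, 0.99),
                                lambda_range = c(0.05, 0.05), seed = 2),
               "clip")
})

test_that("noise-free methylation inverts to chronological age exactly", {
  nf <- noise_free_sim(n = 16, seed = 21)
  sim <- simulate_methylation(nf$cohort, nf$truth, "blood", nf$cfg, seed = 22)
  res <- dnam_age(sim$beta_450k, nf$truth$clock)
  expect_equal(res$dnam_age, nf$cohort$chron_age, tolerance = 1e-9)
})

test_that("the configured BMI effect appears as the regression slope", {
  nf <- noise_free_sim(n = 60, seed = 31, accel_per_bmi = 0.22)
  sim <- simulate_methylation(nf$cohort, nf$truth, "vat", nf$cfg, seed = 32)
  res <- dnam_age(sim$beta_450k, nf$truth$clock)
  accel <- res$dnam_age - nf$cohort$chron_age
  slope <- coef(lm(accel ~ nf$cohort$bmi))[2]
  expect_equal(unname(slope), 0.22, tolerance = 1e-8)
})

test_that("the EPIC matrix omits exactly the configured clock CpGs", {
  cfg <- sim_config(n_subjects = 10, seed = 41, n_clock_cpgs = 50,
                    epic_missing_cpgs = 7)
  cohort <- simulate_cohort(cfg)
  truth <- make_truth_clock(50, seed = 42)
  sim <- simulate_methylation(cohort, truth, "blood", cfg, seed = 43)
  expect_equal(nrow(sim$beta_epic$values), 43)
  expect_equal(length(sim$missing_cpgs), 7)
  expect_false(any(sim$missing_cpgs %in% cpg_ids(sim$beta_epic)))
  # clock/CpG mismatch is an error
  wrong <- make_truth_clock(49, seed = 44)
  expect_error(simulate_methylation(cohort, wrong, "blood", cfg),
               "mismatch")
})

test_that("methylation simulation is deterministic given the seed", {
  cfg <- sim_config(n_subjects = 8, seed = 51, n_clock_cpgs = 20)
  cohort <- simulate_cohort(cfg)
  truth <- make_truth_clock(20, seed = 52)
  s1 <- simulate_methylation(cohort, truth, "vat", cfg, seed = 53)
  s2 <- simulate_methylation(cohort, truth, "vat", cfg, seed = 53)
  expect_identical(s1$beta_450k$values, s2$beta_450k$values)
  expect_identical(s1$beta_epic$values, s2$beta_epic$values)
})

test_that("trajectory groups follow the base frequencies when the OR is 1", {
  cfg <- sim_config(n_subjects = 2000, seed = 61, traj_or_per_year = 1)
  cohort <- simulate_cohort(cfg)
  ts <- simulate_trajectories(cohort, rnorm(2000, 0, 5), cfg, seed = 62)
  freq <- as.numeric(table(ts$labels)) / 2000
  target <- c(0.65, 0.30, 0.05)
  se <- sqrt(target * (1 - target) / 2000)
  expect_true(all(abs(freq - target) < 3 * se))
})

test_that("noise-free trajectories equal their archetypes exactly", {
  cfg <- sim_config(n_subjects = 12, seed = 71, ebwl_noise_sd = 0,
                    missing_visit_prob = 0)
  cohort <- simulate_cohort(cfg)
  ts <- simulate_trajectories(cohort, rep(0, 12), cfg, seed = 72)
  arch <- vatclock:::traj_archetypes()
  for (s in cohort$id) {
    rows <- ts$trajectories$id == s
    expect_equal(ts$trajectories$ebwl_percent[rows],
                 unname(arch$curves[as.character(ts$labels[[s]]), ]))
  }
  # BMI back-computation is consistent with the %EBWL definition
  with(ts$trajectories, expect_equal(
    unname(ebwl(ts$baseline_bmi[id], bmi)), ebwl_percent, tolerance = 1e-12))
  # baseline at or below the ideal BMI is rejected
  bad <- cohort; bad$bmi[1] <- 24
  expect_error(simulate_trajectories(bad, rep(0, 12), cfg), "undefined")
})
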