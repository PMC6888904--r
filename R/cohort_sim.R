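#' Simulation configuration
#'
#' Bundles every knob of the synthetic-cohort generators. Defaults emulate a
#' severe-obesity bariatric-surgery cohort: 52 subjects balanced by sex,
#' BMI per sex from a normal truncated below at 40 kg/m2 (means/SDs 54.4/9.1
#' for men and 48.9/7.2 for women), chronological age uniform on 19-55 years,
#' metabolic-syndrome component levels calibrated to a 50% syndrome
#' prevalence, a 336-CpG truth clock of which 17 CpGs are absent from the
#' EPIC platform, a VAT acceleration effect of 0.15 years of epigenetic age
#' per BMI unit, and three latent weight-loss trajectory archetypes (normal /
#' intermediate / low, base frequencies 65/30/5%) whose normal-weight-loss
#' membership odds increase by a factor `traj_or_per_year` per year of
#' adjusted acceleration.
#'
#' @param n_subjects Number of subjects (>= 4).
#' @param seed Integer seed; every generator is deterministic given the
#'   config and its seed.
#' @param age_range Chronological age range in years, sampled uniformly.
#' @param bmi_mean_by_sex,bmi_sd_by_sex Named (`male`, `female`) BMI normal
#'   parameters in kg/m2.
#' @param bmi_truncation Lower BMI truncation in kg/m2 (severe-obesity
#'   design; rejection sampling).
#' @param accel_per_bmi_unit Years of epigenetic age acceleration per BMI
#'   unit in VAT (blood simulations use 0).
#' @param accel_noise_sd SD in years of the subject-level acceleration noise.
#' @param beta_noise_sd SD of the per-CpG technical beta noise
#'   (dimensionless).
#' @param n_clock_cpgs Number of CpGs in the truth clock.
#' @param epic_missing_cpgs Number of clock CpGs absent from the simulated
#'   EPIC platform (must be < `n_clock_cpgs`).
#' @param mu_range,lambda_range Ranges of the per-CpG baseline methylation
#'   and age slope (on the calibrated-age scale) of the truth clock.
#' @param mets_prevalence Target metabolic-syndrome prevalence.
#' @param mets_component_sd Named list of SDs for the five syndrome
#'   components (waist cm, triglycerides mmol/L, hdl mmol/L, systolic_bp and
#'   diastolic_bp mmHg, fasting_glucose mmol/L).
#' @param traj_or_per_year Odds ratio of normal-weight-loss membership per
#'   year of adjusted acceleration.
#' @param traj_base_probs Base trajectory-group probabilities
#'   (NWL, IWL, LWL), summing to 1.
#' @param ebwl_noise_sd SD of the per-visit %EBWL noise, percent points.
#' @param missing_visit_prob Probability that a follow-up visit is missing.
#' @param reference_bmi BMI at which acceleration is zero; `NULL` (default)
#'   centres on the cohort mean so the marginal mean DNAm age equals the mean
#'   chronological age.
#' @return A validated list of class `sim_config`.
#' @export
sim_config <- function(n_subjects = 52,
                       seed = 1L,
                       age_range = c(19, 55),
                       bmi_mean_by_sex = c(male = 54.4, female = 48.9),
                       bmi_sd_by_sex = c(male = 9.1, female = 7.2),
                       bmi_truncation = 40,
                       accel_per_bmi_unit = 0.15,
                       accel_noise_sd = 7.5,
                       beta_noise_sd = 0.02,
                       n_clock_cpgs = 336L,
                       epic_missing_cpgs = 17L,
                       mu_range = c(0.2, 0.7),
                       lambda_range = c(0.02, 0.08),
                       mets_prevalence = 0.5,
                       mets_component_sd = list(waist = 12, triglycerides = 0.6,
                                                hdl = 0.25, systolic_bp = 12,
                                                diastolic_bp = 8,
                                                fasting_glucose = 0.9),
                       traj_or_per_year = 1.21,
                       traj_base_probs = c(NWL = 0.65, IWL = 0.30, LWL = 0.05),
                       ebwl_noise_sd = 4,
                       missing_visit_prob = 0.05,
                       reference_bmi = NULL) {
  cfg <- structure(
    list(n_subjects = as.integer(n_subjects), seed = as.integer(seed),
         age_range = as.numeric(age_range),
         bmi_mean_by_sex = bmi_mean_by_sex, bmi_sd_by_sex = bmi_sd_by_sex,
         bmi_truncation = bmi_truncation,
         accel_per_bmi_unit = accel_per_bmi_unit,
         accel_noise_sd = accel_noise_sd, beta_noise_sd = beta_noise_sd,
         n_clock_cpgs = as.integer(n_clock_cpgs),
         epic_missing_cpgs = as.integer(epic_missing_cpgs),
         mu_range = as.numeric(mu_range), lambda_range = as.numeric(lambda_range),
         mets_prevalence = mets_prevalence,
         mets_component_sd = mets_component_sd,
         traj_or_per_year = traj_or_per_year,
         traj_base_probs = traj_base_probs,
         ebwl_noise_sd = ebwl_noise_sd,
         missing_visit_prob = missing_visit_prob,
         reference_bmi = reference_bmi),
    class = "sim_config")
  validate_sim_config(cfg)
  cfg
}

validate_sim_config <- function(cfg) {
  fail <- function(field, msg)
    stop(sprintf("invalid sim_config field `%s`: %s", field, msg), call. = FALSE)
  if (is.na(cfg$n_subjects) || cfg$n_subjects < 4L)
    fail("n_subjects", "must be >= 4")
  if (is.na(cfg$seed)) fail("seed", "must be an integer")
  if (length(cfg$age_range) != 2L || cfg$age_range[1L] >= cfg$age_range[2L] ||
      cfg$age_range[1L] <= 0)
    fail("age_range", "must be positive (low, high) with low < high")
  for (f in c("bmi_mean_by_sex", "bmi_sd_by_sex")) {
    v <- cfg[[f]]
    if (!is.numeric(v) || !all(c("male", "female") %in% names(v)))
      fail(f, "must be numeric with names `male` and `female`")
  }
  for (f in c("bmi_sd_by_sex", "accel_noise_sd", "beta_noise_sd", "ebwl_noise_sd"))
    if (any(cfg[[f]] < 0)) fail(f, "SDs must be >= 0")
  for (f in c("mets_prevalence", "missing_visit_prob"))
    if (cfg[[f]] < 0 || cfg[[f]] > 1) fail(f, "must be a probability in [0, 1]")
  if (cfg$n_clock_cpgs < 1L) fail("n_clock_cpgs", "must be >= 1")
  if (cfg$epic_missing_cpgs < 0L || cfg$epic_missing_cpgs >= cfg$n_clock_cpgs)
    fail("epic_missing_cpgs", "must be in [0, n_clock_cpgs)")
  if (length(cfg$lambda_range) != 2L || cfg$lambda_range[1L] <= 0 ||
      cfg$lambda_range[1L] > cfg$lambda_range[2L])
    fail("lambda_range", "must satisfy 0 < low <= high")
  if (cfg$traj_or_per_year <= 0) fail("traj_or_per_year", "must be > 0")
  if (length(cfg$traj_base_probs) != 3L || any(cfg$traj_base_probs < 0) ||
      abs(sum(cfg$traj_base_probs) - 1) > 1e-8)
    fail("traj_base_probs", "must be three nonnegative probabilities summing to 1")
  invisible(cfg)
}

#' Read a simulation configuration from YAML or JSON
#'
#' Fields present in the file override [sim_config()] defaults; unknown
#' fields are an error.
#'
#' @param path A `.yaml`/`.yml` or `.json` file.
#' @param seed Optional seed overriding the file (and the default).
#' @return A validated `sim_config`.
#' @export
read_sim_config <- function(path, seed = NULL) {
  raw <- if (grepl("\\.json$", path, ignore.case = TRUE))
    jsonlite::read_json(path, simplifyVector = TRUE)
  else yaml::read_yaml(path)
  known <- names(formals(sim_config))
  unknown <- setdiff(names(raw), known)
  if (length(unknown) > 0L)
    stop("unknown sim_config field(s) in ", path, ": ",
         paste(unknown, collapse = ", "), call. = FALSE)
  for (f in c("bmi_mean_by_sex", "bmi_sd_by_sex", "traj_base_probs",
              "mets_component_sd"))
    if (f %in% names(raw) && is.list(raw[[f]]) && f != "mets_component_sd")
      raw[[f]] <- unlist(raw[[f]])
  if (!is.null(seed)) raw$seed <- seed
  do.call(sim_config, raw)
}

#' NCEP ATP III metabolic-syndrome thresholds
#'
#' Sex-specific component cut-offs used by [classify_mets()]: waist
#' circumference > 102 cm (men) / > 88 cm (women); triglycerides
#' >= 1.7 mmol/L; HDL cholesterol < 1.03 (men) / < 1.29 (women) mmol/L;
#' blood pressure >= 130 mmHg systolic or >= 85 mmHg diastolic; fasting
#' glucose >= 5.6 mmol/L (the updated cut-off). Returned as an editable list
#' so alternative conventions (e.g. glucose >= 6.1) can be supplied.
#'
#' @return Named list of thresholds.
#' @export
atp3_thresholds <- function() {
  list(waist = c(male = 102, female = 88),          # strictly greater
       triglycerides = 1.7,                         # >=
       hdl = c(male = 1.03, female = 1.29),         # strictly less
       systolic_bp = 130,                           # >=
       diastolic_bp = 85,                           # >=
       fasting_glucose = 5.6)                       # >=
}

.mets_components <- c("waist", "triglycerides", "hdl", "systolic_bp",
                      "diastolic_bp", "fasting_glucose")

#' Classify metabolic syndrome from its five ATP III components
#'
#' Counts the satisfied criteria among waist circumference, triglycerides,
#' HDL, blood pressure (systolic or diastolic) and fasting glucose, with
#' sex-specific thresholds ([atp3_thresholds()]); a subject is positive when
#' three or more criteria are met.
#'
#' @param records Data frame with columns `sex` (`"male"`/`"female"`),
#'   `waist`, `triglycerides`, `hdl`, `systolic_bp`, `diastolic_bp`,
#'   `fasting_glucose`. One or more rows.
#' @param thresholds Threshold list in the shape of [atp3_thresholds()].
#' @return A list with `mets` (logical vector) and `criteria_count`
#'   (integer vector, 0-5).
#' @export
classify_mets <- function(records, thresholds = atp3_thresholds()) {
  needed <- c("sex", .mets_components)
  missing <- setdiff(needed, names(records))
  if (length(missing) > 0L)
    stop("missing metabolic-syndrome component field(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  for (f in needed)
    if (anyNA(records[[f]]))
      stop("missing values in component field `", f, "`", call. = FALSE)
  sex <- as.character(records$sex)
  if (!all(sex %in% c("male", "female")))
    stop("`sex` must be 'male' or 'female'", call. = FALSE)
  crit_waist <- records$waist > unname(thresholds$waist[sex])
  crit_tg <- records$triglycerides >= thresholds$triglycerides
  crit_hdl <- records$hdl < unname(thresholds$hdl[sex])
  crit_bp <- records$systolic_bp >= thresholds$systolic_bp |
    records$diastolic_bp >= thresholds$diastolic_bp
  crit_glu <- records$fasting_glucose >= thresholds$fasting_glucose
  count <- crit_waist + crit_tg + crit_hdl + crit_bp + crit_glu
  list(mets = count >= 3L, criteria_count = as.integer(count))
}

# Truncated-normal draw by rejection sampling (documented design choice).
rtruncnorm_lower <- function(n, mean, sd, lower, max_iter = 10000L) {
  if (sd == 0) {
    if (mean < lower)
      stop(sprintf("degenerate truncated normal: mean %.3g below truncation %.3g with sd 0",
                   mean, lower), call. = FALSE)
    return(rep(mean, n))
  }
  out <- numeric(0L)
  for (i in seq_len(max_iter)) {
    draw <- stats::rnorm(n - length(out), mean, sd)
    out <- c(out, draw[draw >= lower])
    if (length(out) >= n) return(out[seq_len(n)])
  }
  stop("rejection sampling for the truncated normal did not converge", call. = FALSE)
}

#' Simulate a severe-obesity cohort
#'
#' Generates subjects with balanced sexes (within 1), uniform chronological
#' age over `age_range`, per-sex BMI from a normal truncated below at
#' `bmi_truncation` (rejection sampling), and the five ATP III components.
#' Component means are placed relative to their thresholds so that each
#' criterion is met with the probability `q` solving
#' `P(Binomial(5, q) >= 3) = mets_prevalence` (the two blood-pressure
#' readings share the criterion, so each is calibrated to `1 - sqrt(1 - q)`).
#' The stored `mets` flag is always derived through [classify_mets()], so
#' flag and components are coherent by construction.
#'
#' @param config A [sim_config()].
#' @return A data frame of class `cohort_table`: `id`, `sex`, `chron_age`,
#'   `bmi`, the five component columns, `mets`, `mets_criteria_count`.
#'   Deterministic given `config` (byte-identical for equal seeds).
#' @export
simulate_cohort <- function(config = sim_config()) {
  validate_sim_config(config)
  set.seed(config$seed)
  n <- config$n_subjects
  sex <- rep(c("male", "female"), length.out = n)
  id <- sprintf("S%04d", seq_len(n))
  chron_age <- stats::runif(n, config$age_range[1L], config$age_range[2L])
  bmi <- numeric(n)
  for (s in c("male", "female")) {
    i <- sex == s
    bmi[i] <- rtruncnorm_lower(sum(i), config$bmi_mean_by_sex[[s]],
                               config$bmi_sd_by_sex[[s]], config$bmi_truncation)
  }
  # per-criterion probability hitting the target syndrome prevalence
  q <- if (config$mets_prevalence <= 0) 0
  else if (config$mets_prevalence >= 1) 1
  else stats::uniroot(function(p) stats::pbinom(2, 5, p, lower.tail = FALSE) -
                        config$mets_prevalence, c(1e-6, 1 - 1e-6))$root
  q_bp <- 1 - sqrt(1 - q)  # each BP reading independently
  thr <- atp3_thresholds()
  sds <- config$mets_component_sd
  shift <- function(sd, p) sd * stats::qnorm(p)  # qnorm(0.5) = 0
  waist <- stats::rnorm(n, unname(thr$waist[sex]) + shift(sds$waist, q), sds$waist)
  tg <- stats::rnorm(n, thr$triglycerides + shift(sds$triglycerides, q),
                     sds$triglycerides)
  hdl <- stats::rnorm(n, thr$hdl[sex] - shift(sds$hdl, q), sds$hdl)
  sbp <- stats::rnorm(n, thr$systolic_bp + shift(sds$systolic_bp, q_bp),
                      sds$systolic_bp)
  dbp <- stats::rnorm(n, thr$diastolic_bp + shift(sds$diastolic_bp, q_bp),
                      sds$diastolic_bp)
  glu <- stats::rnorm(n, thr$fasting_glucose + shift(sds$fasting_glucose, q),
                      sds$fasting_glucose)
  tg <- pmax(tg, 0.1); hdl <- pmax(hdl, 0.1); glu <- pmax(glu, 2)
  cohort <- data.frame(
    id = id, sex = sex, chron_age = chron_age, bmi = bmi, waist = waist,
    triglycerides = tg, hdl = hdl, systolic_bp = sbp, diastolic_bp = dbp,
    fasting_glucose = glu, stringsAsFactors = FALSE)
  cls <- classify_mets(cohort)
  cohort$mets <- cls$mets
  cohort$mets_criteria_count <- cls$criteria_count
  class(cohort) <- c("cohort_table", "data.frame")
  cohort
}

#' Build a generative truth clock
#'
#' Draws per-CpG baseline methylation `mu_j` and calibrated-age slope
#' `lambda_j`, then inverts them into clock weights `w_j = 1 / (n * lambda_j)`
#' and intercept `-sum(mu_j * w_j)`, so that on noise-free beta values
#' `beta_j = mu_j + lambda_j * t` the clock recovers the calibrated age `t`
#' exactly. Validates that no beta value can leave `(0, 1)` over the design
#' age range (extended by `accel_margin` years on both sides to leave room
#' for acceleration).
#'
#' @param n_cpgs Number of clock CpGs.
#' @param mu_range,lambda_range Uniform sampling ranges for `mu_j` and
#'   `lambda_j` (`0 < low <= high` for lambda).
#' @param seed Integer seed.
#' @param age_range Design chronological-age range in years.
#' @param accel_margin Extra years of acceleration the design must tolerate.
#' @param adult_age Calibration constant of the clock.
#' @return A list of class `truth_clock`: `clock` (a [clock_model()]),
#'   `mu`, `lambda` (named per-CpG vectors) and `cpg_ids`.
#' @export
make_truth_clock <- function(n_cpgs = 336L, mu_range = c(0.2, 0.7),
                             lambda_range = c(0.02, 0.08), seed = 1L,
                             age_range = c(19, 55), accel_margin = 15,
                             adult_age = 20) {
  if (lambda_range[1L] <= 0 || lambda_range[1L] > lambda_range[2L])
    stop("`lambda_range` must satisfy 0 < low <= high", call. = FALSE)
  set.seed(seed)
  ids <- sprintf("cg%08d", seq_len(n_cpgs))
  mu <- stats::setNames(stats::runif(n_cpgs, mu_range[1L], mu_range[2L]), ids)
  lambda <- stats::setNames(stats::runif(n_cpgs, lambda_range[1L], lambda_range[2L]), ids)
  t_lo <- calibrate_age(max(age_range[1L] - accel_margin, -0.9), adult_age)
  t_hi <- calibrate_age(age_range[2L] + accel_margin, adult_age)
  lo <- mu + lambda * t_lo
  hi <- mu + lambda * t_hi
  bad <- which(lo <= 0 | hi >= 1)
  if (length(bad) > 0L)
    stop(sprintf("truth clock would clip beta values over the design age range at CpG %s (range %.3f-%.3f)",
                 ids[bad[1L]], lo[bad[1L]], hi[bad[1L]]), call. = FALSE)
  w <- 1 / (n_cpgs * lambda)
  clock <- clock_model(intercept = -sum(mu * w), coefficients = w,
                       name = "truth", adult_age = adult_age,
                       original_size = n_cpgs)
  structure(list(clock = clock, mu = mu, lambda = lambda, cpg_ids = ids),
            class = "truth_clock")
}

#' Simulate paired 450k and EPIC methylation matrices for a cohort
#'
#' Each subject's latent calibrated age target is
#' `t_i = calibrate_age(chron_age_i + accel_i)` with
#' `accel_i = slope * (bmi_i - reference_bmi) + Normal(0, accel_noise_sd)`,
#' where the slope is `config$accel_per_bmi_unit` for VAT and 0 for blood,
#' and `reference_bmi` defaults to the cohort mean BMI (centred acceleration).
#' Beta values are `clip(mu_j + lambda_j * t_i + Normal(0, beta_noise_sd),
#' 0, 1)`, drawn independently per platform (shared biological target,
#' independent technical noise), so the same subjects appear on both arrays —
#' as when samples are run on both platforms for concordance. The EPIC matrix
#' omits `config$epic_missing_cpgs` clock CpGs (a deterministic random subset
#' for the given seed). An alternating platform assignment is attached for
#' building a merged dataset with disjoint sample sets.
#'
#' @param cohort A [simulate_cohort()] table.
#' @param truth A [make_truth_clock()] object.
#' @param tissue `"blood"` (no BMI effect) or `"vat"`.
#' @param config A [sim_config()].
#' @param seed Seed for this draw (default `config$seed`); pass distinct
#'   seeds for distinct tissues.
#' @return A list of class `methylation_sim`: `beta_450k` and `beta_epic`
#'   ([beta_matrix()] objects over all subjects), `platform_assignment`
#'   (named character, `"450k"`/`"epic"` per subject), `accel_true`,
#'   `target_age` (chron + accel, years), `missing_cpgs`, `tissue`.
#' @export
simulate_methylation <- function(cohort, truth, tissue = c("blood", "vat"),
                                 config = sim_config(), seed = config$seed) {
  tissue <- match.arg(tissue)
  if (!inherits(truth, "truth_clock"))
    stop("`truth` must be a truth_clock from make_truth_clock()", call. = FALSE)
  if (!is.data.frame(cohort) || nrow(cohort) == 0L)
    stop("`cohort` must be a nonempty cohort table", call. = FALSE)
  if (length(truth$cpg_ids) != config$n_clock_cpgs)
    stop(sprintf("clock/CpG mismatch: truth clock has %d CpGs but config expects %d",
                 length(truth$cpg_ids), config$n_clock_cpgs), call. = FALSE)
  validate_sim_config(config)
  set.seed(seed)
  n <- nrow(cohort)
  slope <- if (tissue == "vat") config$accel_per_bmi_unit else 0
  ref_bmi <- if (is.null(config$reference_bmi)) mean(cohort$bmi) else config$reference_bmi
  accel <- slope * (cohort$bmi - ref_bmi) +
    stats::rnorm(n, 0, config$accel_noise_sd)
  target <- cohort$chron_age + accel
  # the latent age must stay positive (the calibration is undefined at -1);
  # redraw the noise for the rare subject pushed below, i.e. truncated noise
  for (iter in seq_len(100L)) {
    low <- which(target <= 0.5)
    if (length(low) == 0L) break
    accel[low] <- slope * (cohort$bmi[low] - ref_bmi) +
      stats::rnorm(length(low), 0, config$accel_noise_sd)
    target[low] <- cohort$chron_age[low] + accel[low]
  }
  if (any(target <= 0.5))
    stop("could not keep the simulated latent age positive; reduce accel_noise_sd",
         call. = FALSE)
  t <- calibrate_age(target, truth$clock$adult_age)
  draw <- function() {
    noise <- if (config$beta_noise_sd > 0)
      matrix(stats::rnorm(length(truth$mu) * n, 0, config$beta_noise_sd),
             nrow = length(truth$mu))
    else 0
    vals <- outer(truth$lambda, t) + truth$mu + noise
    vals <- pmin(pmax(vals, 0), 1)
    dimnames(vals) <- list(truth$cpg_ids, cohort$id)
    vals
  }
  v450 <- draw()
  vepic <- draw()
  missing_cpgs <- if (config$epic_missing_cpgs > 0L)
    sort(sample(truth$cpg_ids, config$epic_missing_cpgs)) else character(0L)
  vepic <- vepic[setdiff(truth$cpg_ids, missing_cpgs), , drop = FALSE]
  assignment <- stats::setNames(rep(c("450k", "epic"), length.out = n), cohort$id)
  structure(
    list(beta_450k = beta_matrix(v450, "450k"),
         beta_epic = beta_matrix(vepic, "epic"),
         platform_assignment = assignment,
         accel_true = stats::setNames(accel, cohort$id),
         target_age = stats::setNames(target, cohort$id),
         missing_cpgs = missing_cpgs, tissue = tissue),
    class = "methylation_sim")
}

#' Split a paired methylation simulation into disjoint platform matrices
#'
#' Applies the alternating platform assignment of [simulate_methylation()]:
#' subjects assigned to 450k keep only their 450k columns and vice versa,
#' yielding the disjoint sample sets [merge_platforms()] requires.
#'
#' @param sim A `methylation_sim`.
#' @return List of two [beta_matrix()] objects (`b450k`, `bepic`).
#' @export
split_by_assignment <- function(sim) {
  stopifnot(inherits(sim, "methylation_sim"))
  a <- sim$platform_assignment
  list(b450k = beta_matrix(sim$beta_450k$values[, names(a)[a == "450k"], drop = FALSE],
                           "450k"),
       bepic = beta_matrix(sim$beta_epic$values[, names(a)[a == "epic"], drop = FALSE],
                           "epic"))
}

# %EBWL archetype curves at the seven follow-up months. Plateau-high,
# intermediate and low shapes; only group frequencies (not curves) are
# constrained by the design, so these fixed piecewise-linear shapes are a
# documented modelling choice.
traj_archetypes <- function() {
  months <- c(3, 6, 12, 18, 24, 36, 48)
  curves <- rbind(
    NWL = c(35, 60, 78, 85, 88, 87, 86),
    IWL = c(22, 40, 54, 62, 65, 64, 62),
    LWL = c(8, 18, 25, 30, 31, 29, 26))
  colnames(curves) <- months
  list(months = months, curves = curves)
}

#' Simulate postsurgery weight-loss trajectories
#'
#' Assigns each subject to one of three latent %EBWL archetypes (normal /
#' intermediate / low weight loss). The probability of the NWL archetype
#' follows a logistic model in the adjusted acceleration,
#' `logit P(NWL) = qlogis(p_NWL) + log(traj_or_per_year) * accel`, so the
#' base frequency is attained at zero (centred) acceleration; non-NWL
#' subjects fall into IWL vs LWL in their base proportion. Per-visit %EBWL
#' is the archetype value plus `Normal(0, ebwl_noise_sd)` noise; visits are
#' dropped independently with `missing_visit_prob`, and BMI is back-computed
#' as `baseline - ebwl/100 * (baseline - 25)`.
#'
#' @param cohort A cohort table with `id` and `bmi` (baseline; must exceed
#'   25 kg/m2, otherwise excess weight is undefined).
#' @param adjusted_accel Per-subject adjusted acceleration in years, aligned
#'   with `cohort`.
#' @param config A [sim_config()].
#' @param seed Seed for this draw (default `config$seed`).
#' @return A list of class `trajectory_sim`: `trajectories` (long data
#'   frame: `id`, `month`, `bmi`, `ebwl_percent`), `labels` (true group
#'   factor NWL/IWL/LWL per subject), `baseline_bmi` (named vector).
#' @export
simulate_trajectories <- function(cohort, adjusted_accel, config = sim_config(),
                                  seed = config$seed) {
  validate_sim_config(config)
  if (length(adjusted_accel) != nrow(cohort))
    stop("`adjusted_accel` must align with `cohort` (one value per subject)",
         call. = FALSE)
  if (any(cohort$bmi <= 25))
    stop("baseline BMI <= 25 kg/m2: excess body weight is undefined", call. = FALSE)
  set.seed(seed)
  arch <- traj_archetypes()
  n <- nrow(cohort)
  p <- config$traj_base_probs
  p_nwl <- stats::plogis(stats::qlogis(p[[1L]]) +
                           log(config$traj_or_per_year) * adjusted_accel)
  is_nwl <- stats::runif(n) < p_nwl
  other <- ifelse(stats::runif(n) < p[[2L]] / (p[[2L]] + p[[3L]]), "IWL", "LWL")
  labels <- factor(ifelse(is_nwl, "NWL", other), levels = c("NWL", "IWL", "LWL"))
  rows <- vector("list", n)
  for (i in seq_len(n)) {
    ebwl_i <- arch$curves[as.character(labels[i]), ] +
      stats::rnorm(length(arch$months), 0, config$ebwl_noise_sd)
    keep <- stats::runif(length(arch$months)) >= config$missing_visit_prob
    rows[[i]] <- data.frame(
      id = cohort$id[i], month = arch$months[keep],
      bmi = cohort$bmi[i] - ebwl_i[keep] / 100 * (cohort$bmi[i] - 25),
      ebwl_percent = ebwl_i[keep], stringsAsFactors = FALSE)
  }
  structure(
    list(trajectories = do.call(rbind, rows),
         labels = stats::setNames(labels, cohort$id),
         baseline_bmi = stats::setNames(cohort$bmi, cohort$id)),
    class = "trajectory_sim")
}
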