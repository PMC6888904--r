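#' Run the full simulated analysis pipeline
#'
#' Orchestrates every stage end to end on a synthetic cohort: cohort and
#' truth-clock generation, paired 450k/EPIC methylation simulation per
#' tissue (blood: no BMI effect; VAT: `accel_per_bmi_unit`), virtual-array
#' merging of the disjoint platform halves, clock reduction to the merged
#' CpG set, DNAm-age scoring, acceleration and adjusted acceleration,
#' correlation / multivariate / subgroup statistics, cross-platform
#' concordance, weight-loss trajectory simulation + clustering, logistic
#' trend models (trajectory group and metabolic syndrome), and the power
#' analysis block. Deterministic given the config seed; tissue-specific
#' sub-seeds are derived as small fixed offsets of it.
#'
#' Stage failures are re-raised with the stage name prefixed.
#'
#' @param config A [sim_config()].
#' @param tissues Tissues to simulate (default `c("blood", "vat")`).
#' @param out_dir Optional directory; when given, [make_report()] writes the
#'   report files there.
#' @param trim_quantiles Lower/upper quantiles for the age-trimmed subgroup
#'   analysis (`NULL` to skip).
#' @param stratify_by_sex Run the sex-stratified correlations and the
#'   between-sex comparison.
#' @param mets_model,traj_model Toggles for the two logistic trend models.
#' @param plots Also write simple figure files (requires `out_dir`).
#' @return A list of class `run_report`; see [make_report()] for the file
#'   layout.
#' @export
run_pipeline <- function(config = sim_config(), tissues = c("blood", "vat"),
                         out_dir = NULL, trim_quantiles = c(0.10, 0.90),
                         stratify_by_sex = TRUE, mets_model = TRUE,
                         traj_model = TRUE, plots = FALSE) {
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop(sprintf("[stage %s] %s", name, conditionMessage(e)), call. = FALSE))
  }
  validate_sim_config(config)
  tissues <- match.arg(tissues, c("blood", "vat"), several.ok = TRUE)

  cohort <- stage("simulate_cohort", simulate_cohort(config))
  truth <- stage("make_truth_clock",
                 make_truth_clock(config$n_clock_cpgs, config$mu_range,
                                  config$lambda_range, seed = config$seed + 1L,
                                  age_range = config$age_range))
  per_tissue <- list()
  adjusted <- list()
  for (ti in seq_along(tissues)) {
    tissue <- tissues[ti]
    sim <- stage(paste0("simulate_methylation_", tissue),
                 simulate_methylation(cohort, truth, tissue, config,
                                      seed = config$seed + 1L + ti))
    halves <- split_by_assignment(sim)
    merged <- stage(paste0("merge_platforms_", tissue),
                    merge_platforms(list(halves$b450k, halves$bepic)))
    red <- stage(paste0("reduce_clock_", tissue),
                 reduce_clock(truth$clock, cpg_ids(merged)))
    ages <- stage(paste0("dnam_age_", tissue), dnam_age(merged, red$clock))
    ages <- ages[match(cohort$id, ages$sample_id), ]
    conc <- stage(paste0("concordance_", tissue),
                  platform_concordance(sim$beta_450k, sim$beta_epic))
    accel <- stage(paste0("age_acceleration_", tissue),
                   age_acceleration(ages$dnam_age, cohort$chron_age, tissue))
    fit <- stage(paste0("multivariate_fit_", tissue),
                 multivariate_fit(ages$dnam_age, cohort$chron_age, cohort$bmi,
                                  cohort$sex, cohort$mets))
    adjusted[[tissue]] <- stage(paste0("adjusted_acceleration_", tissue),
                                adjusted_acceleration(ages$dnam_age,
                                                      cohort$chron_age,
                                                      cohort$sex, cohort$bmi))
    res <- list(
      tissue = tissue,
      dnam_age = ages,
      reduction_report = red$report,
      concordance = conc,
      r_chron_dnam = pearson_test(cohort$chron_age, ages$dnam_age),
      r_accel_bmi = pearson_test(accel$residual, cohort$bmi),
      multivariate = fit,
      adj_r2 = attr(fit, "adj_r2"),
      years_per_10bmi = list(
        age_normalized = years_per_10bmi(fit, "age_normalized"),
        simple = years_per_10bmi(fit, "simple")),
      acceleration = accel)
    if (stratify_by_sex) {
      res$sex_comparison <- stage(paste0("compare_groups_", tissue),
                                  compare_groups(accel$residual, cohort$sex))
      res$r_accel_bmi_by_sex <- lapply(
        stats::setNames(c("male", "female"), c("male", "female")),
        function(s) {
          i <- cohort$sex == s
          pearson_test(accel$residual[i], cohort$bmi[i])
        })
    }
    if (!is.null(trim_quantiles)) {
      dat <- cbind(cohort, accel_res = accel$residual)
      trimmed <- stage(paste0("percentile_trim_", tissue),
                       percentile_trim(dat, trim_quantiles[1L],
                                       trim_quantiles[2L], on = "chron_age"))
      res$r_accel_bmi_trimmed <- pearson_test(trimmed$accel_res, trimmed$bmi)
      res$n_trimmed <- nrow(trimmed)
    }
    if (mets_model)
      res$mets_logistic <- stage(paste0("logistic_mets_", tissue),
                                 logistic_trend(cohort$mets, adjusted[[tissue]]))
    per_tissue[[tissue]] <- res
  }

  traj <- NULL
  if (traj_model) {
    accel_for_traj <- if ("vat" %in% tissues) adjusted[["vat"]] else adjusted[[1L]]
    traj_sim <- stage("simulate_trajectories",
                      simulate_trajectories(cohort, accel_for_traj, config,
                                            seed = config$seed + 9L))
    measures <- stage("trajectory_measures",
                      trajectory_measure_matrix(traj_sim$trajectories))
    clusters <- stage("cluster_trajectories", cluster_trajectories(measures))
    keep <- match(clusters$assignments$id, cohort$id)
    nwl <- clusters$assignments$binary == "NWL"
    traj <- list(
      simulated = traj_sim, measures = measures, clusters = clusters,
      logistic = lapply(stats::setNames(tissues, tissues), function(tissue)
        stage(paste0("logistic_traj_", tissue),
              logistic_trend(nwl, adjusted[[tissue]][keep]))))
  }

  report <- structure(
    list(config = config,
         config_hash = rlang::hash(config),
         seed = config$seed,
         version = as.character(utils::packageVersion("vatclock")),
         n_subjects = nrow(cohort),
         cohort = cohort,
         power = list(
           r_full = required_r_for_power(nrow(cohort)),
           r_by_sex = stats::setNames(
             required_r_for_power(pmax(table(cohort$sex), 4L)),
             names(table(cohort$sex)))),
         tissues = per_tissue,
         trajectories = traj),
    class = "run_report")
  if (!is.null(out_dir)) make_report(report, out_dir, plots = plots)
  report
}

#' @export
print.run_report <- function(x, ...) {
  cat(sprintf("<run_report> n = %d, seed = %d, hash %s\n", x$n_subjects,
              x$seed, x$config_hash))
  for (t in x$tissues)
    cat(sprintf("  %s: r(chron, DNAm) = %.3f; r(accel, BMI) = %.3f (p = %.3g); beta_BMI = %.3f\n",
                t$tissue, t$r_chron_dnam$r, t$r_accel_bmi$r, t$r_accel_bmi$p,
                t$multivariate$estimate[t$multivariate$term == "bmi"]))
  if (!is.null(x$trajectories)) {
    f <- x$trajectories$clusters$group_freq_percent
    cat(sprintf("  trajectories: k = %d (%s)\n", x$trajectories$clusters$k,
                paste(sprintf("%s %.0f%%", names(f), f), collapse = ", ")))
  }
  invisible(x)
}

# Flatten a run_report into plain lists for JSON serialization.
report_to_list <- function(report) {
  strip <- function(x) {
    if (inherits(x, "ols_fit")) return(as.list(as.data.frame(x)))
    if (is.data.frame(x)) return(as.list(x))
    if (inherits(x, "concordance_report"))
      return(x[c("n_cpgs_compared", "n_within_threshold", "fraction_within",
                 "threshold", "n_samples_paired")])
    if (is.list(x)) return(lapply(unclass(x), strip))
    if (is.table(x)) return(as.list(x))
    x
  }
  tissues <- lapply(report$tissues, function(t) {
    t$dnam_age <- NULL; t$acceleration <- NULL
    t$multivariate <- list(terms = strip(t$multivariate),
                           adj_r2 = attr(t$multivariate, "adj_r2"))
    t$concordance$per_cpg_mean_abs_diff <- NULL
    strip(t)
  })
  traj <- if (is.null(report$trajectories)) NULL else list(
    k = report$trajectories$clusters$k,
    selected_measures = report$trajectories$clusters$selected_measures,
    group_freq_percent = as.list(report$trajectories$clusters$group_freq_percent),
    logistic = lapply(report$trajectories$logistic, function(l)
      l[c("or", "ci_low", "ci_high", "p_trend", "slope", "se")]))
  list(version = report$version, seed = report$seed,
       config_hash = report$config_hash, n_subjects = report$n_subjects,
       power = strip(report$power), tissues = tissues, trajectories = traj)
}

#' Write a run report to disk
#'
#' Writes `report.json` (full precision), tidy TSV tables (`cohort.tsv`,
#' `dnam_age_<tissue>.tsv`, `association_<tissue>.tsv` in a term / beta /
#' CI / p / adjusted-R2 layout, `trajectories.tsv`, `traj_clusters.tsv`)
#' and, optionally, simple headless-safe PNG figures (age scatter,
#' acceleration-by-sex boxplot, trajectory curves).
#'
#' @param report A `run_report` from [run_pipeline()].
#' @param out_dir Output directory (created if needed; must be writable).
#' @param plots Write figure files too.
#' @return `out_dir`, invisibly.
#' @export
make_report <- function(report, out_dir, plots = FALSE) {
  stopifnot(inherits(report, "run_report"))
  if (length(report$tissues) == 0L)
    stop("report contains no analysis blocks", call. = FALSE)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  if (!dir.exists(out_dir) || file.access(out_dir, mode = 2L) != 0L)
    stop("output directory is not writable: ", out_dir, call. = FALSE)
  tsv <- function(df, name)
    utils::write.table(df, file.path(out_dir, name), sep = "\t", quote = FALSE,
                       row.names = FALSE, na = "NA")
  jsonlite::write_json(report_to_list(report), file.path(out_dir, "report.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  tsv(report$cohort, "cohort.tsv")
  for (t in report$tissues) {
    tsv(t$dnam_age, sprintf("dnam_age_%s.tsv", t$tissue))
    assoc <- as.data.frame(t$multivariate)
    assoc$adj_r2 <- attr(t$multivariate, "adj_r2")
    assoc$years_per_10bmi_age_normalized <- t$years_per_10bmi$age_normalized
    assoc$years_per_10bmi_simple <- t$years_per_10bmi$simple
    tsv(assoc, sprintf("association_%s.tsv", t$tissue))
  }
  if (!is.null(report$trajectories)) {
    tsv(report$trajectories$simulated$trajectories, "trajectories.tsv")
    tsv(report$trajectories$clusters$assignments, "traj_clusters.tsv")
  }
  if (plots) report_plots(report, out_dir)
  invisible(out_dir)
}

# Simple base-graphics figures; never part of any numeric output.
report_plots <- function(report, out_dir) {
  safe_png <- function(name, expr) {
    grDevices::png(file.path(out_dir, name), width = 720, height = 560)
    on.exit(grDevices::dev.off(), add = TRUE)
    expr
  }
  for (t in report$tissues) {
    safe_png(sprintf("age_scatter_%s.png", t$tissue), {
      graphics::plot(report$cohort$chron_age, t$dnam_age$dnam_age,
                     xlab = "Chronological age (years)",
                     ylab = "DNAm age (years)",
                     main = sprintf("%s: r = %.2f", t$tissue, t$r_chron_dnam$r))
      graphics::abline(stats::lm(t$dnam_age$dnam_age ~ report$cohort$chron_age),
                       lty = 2)
    })
    safe_png(sprintf("accel_by_sex_%s.png", t$tissue),
             graphics::boxplot(t$acceleration$residual ~ report$cohort$sex,
                               xlab = "Sex", ylab = "Age acceleration (years)",
                               main = t$tissue))
  }
  if (!is.null(report$trajectories)) {
    tr <- report$trajectories$simulated$trajectories
    lab <- report$trajectories$clusters$assignments
    safe_png("trajectories.png", {
      graphics::plot(NULL, xlim = range(tr$month), ylim = range(tr$ebwl_percent),
                     xlab = "Month after surgery", ylab = "%EBWL")
      cols <- c(NWL = "red", IWL = "darkgreen", LWL = "black")
      for (s in unique(tr$id)) {
        i <- tr$id == s
        l <- lab$label[match(s, lab$id)]
        col <- if (!is.na(l) && l %in% names(cols)) cols[[l]] else "grey"
        graphics::lines(tr$month[i], tr$ebwl_percent[i], col = col)
      }
    })
  }
  invisible(out_dir)
}
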