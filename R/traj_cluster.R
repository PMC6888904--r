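VISIT_MONTHS <- c(3, 6, 12, 18, 24, 36, 48)

#' Percentage of excess body weight lost
#'
#' Excess weight is defined relative to an ideal BMI of 25 kg/m2:
#' `%EBWL = 100 * (initial - current) / (initial - ideal)`. Values above 100
#' (loss past the ideal) or below 0 (weight gain) are legitimate.
#'
#' @param initial_bmi Baseline BMI in kg/m2; must exceed `ideal_bmi`.
#' @param current_bmi BMI at the visit.
#' @param ideal_bmi Ideal BMI (default 25 kg/m2).
#' @return %EBWL (vectorized).
#' @export
ebwl <- function(initial_bmi, current_bmi, ideal_bmi = 25) {
  if (any(initial_bmi <= ideal_bmi))
    stop("initial BMI must exceed the ideal BMI: excess weight undefined",
         call. = FALSE)
  100 * (initial_bmi - current_bmi) / (initial_bmi - ideal_bmi)
}

# Least-squares slope of y on x; NA-safe for >= 2 points.
ls_slope <- function(x, y) {
  if (length(x) < 2L) return(NA_real_)
  stats::cov(x, y) / stats::var(x)
}

#' Summary measures of a weight-loss trajectory
#'
#' Computes a fixed ten-measure description of one subject's %EBWL series
#' over the follow-up visits: `final` (last value), `max`, `t_max` (month of
#' first maximum), `mean`, `slope_early` (least-squares slope over months
#' 3-12), `slope_late` (months 24-48), `slope_overall`, `auc_rate`
#' (trapezoid area under the curve divided by the follow-up span, %EBWL
#' units), `sd_increment` (SD of successive changes) and `rebound`
#' (`(max - final) / max` when `max > 0`, else 0). Missing visits are
#' linearly interpolated onto the standard visit months inside the observed
#' span (no extrapolation); when a slope window contains fewer than two
#' visits the overall slope is used as fallback.
#'
#' @param months Observed visit months (subset of 3, 6, 12, 18, 24, 36, 48;
#'   at least 3).
#' @param ebwl_percent %EBWL at the observed visits.
#' @return Named numeric vector of the ten measures.
#' @export
trajectory_measures <- function(months, ebwl_percent) {
  if (length(months) != length(ebwl_percent))
    stop("`months` and `ebwl_percent` must be aligned", call. = FALSE)
  ok <- !is.na(months) & !is.na(ebwl_percent)
  months <- months[ok]; ebwl_percent <- ebwl_percent[ok]
  if (length(months) < 3L)
    stop("need at least 3 observed visits", call. = FALSE)
  o <- order(months)
  months <- months[o]; ebwl_percent <- ebwl_percent[o]
  if (anyDuplicated(months)) stop("duplicate visit months", call. = FALSE)
  grid <- VISIT_MONTHS[VISIT_MONTHS >= months[1L] & VISIT_MONTHS <= months[length(months)]]
  vals <- stats::approx(months, ebwl_percent, xout = grid)$y
  n <- length(grid)
  overall <- ls_slope(grid, vals)
  window_slope <- function(lo, hi) {
    i <- grid >= lo & grid <= hi
    if (sum(i) < 2L) overall else ls_slope(grid[i], vals[i])
  }
  auc <- sum(diff(grid) * (vals[-1L] + vals[-n]) / 2)
  mx <- max(vals)
  c(final = vals[n],
    max = mx,
    t_max = grid[which.max(vals)],
    mean = mean(vals),
    slope_early = window_slope(3, 12),
    slope_late = window_slope(24, 48),
    slope_overall = overall,
    auc_rate = auc / (grid[n] - grid[1L]),
    sd_increment = stats::sd(diff(vals)),
    rebound = if (mx > 0) (mx - vals[n]) / mx else 0)
}

#' Trajectory measure matrix for a long-format cohort
#'
#' Applies [trajectory_measures()] per subject of a long table
#' (`id`, `month`, `ebwl_percent` — or `bmi` plus a `baseline_bmi` vector
#' from which %EBWL is computed). Subjects with fewer than 3 visits are
#' excluded with a message; their ids are kept in the `excluded` attribute.
#'
#' @param traj_long Long data frame with columns `id`, `month` and either
#'   `ebwl_percent` or `bmi`.
#' @param baseline_bmi Named baseline-BMI vector, required when only `bmi`
#'   is present.
#' @return Numeric matrix (subjects x measures) with subject-id rownames.
#' @export
trajectory_measure_matrix <- function(traj_long, baseline_bmi = NULL) {
  if (!all(c("id", "month") %in% names(traj_long)))
    stop("`traj_long` needs columns `id` and `month`", call. = FALSE)
  if (!("ebwl_percent" %in% names(traj_long))) {
    if (!("bmi" %in% names(traj_long)) || is.null(baseline_bmi))
      stop("need `ebwl_percent`, or `bmi` plus `baseline_bmi`", call. = FALSE)
    traj_long$ebwl_percent <- ebwl(unname(baseline_bmi[traj_long$id]),
                                   traj_long$bmi)
  }
  ids <- unique(traj_long$id)
  counts <- table(traj_long$id)
  usable <- ids[counts[ids] >= 3L]
  excluded <- setdiff(ids, usable)
  if (length(excluded) > 0L)
    message(sprintf("trajectory_measure_matrix: excluded %d subject(s) with < 3 visits",
                    length(excluded)))
  if (length(usable) == 0L) stop("no subject has >= 3 visits", call. = FALSE)
  m <- t(vapply(usable, function(s) {
    rows <- traj_long$id == s
    trajectory_measures(traj_long$month[rows], traj_long$ebwl_percent[rows])
  }, numeric(10L)))
  rownames(m) <- usable
  attr(m, "excluded") <- excluded
  m
}

#' Select nonredundant trajectory measures
#'
#' Factor-based screening of the measure matrix: (1) among pairs of
#' standardized measures with `|r| > 0.95` the later (by column order) member
#' is dropped; (2) the remainder undergoes a principal-component factor
#' decomposition of the correlation matrix, retaining factors with
#' eigenvalue > 1; (3) for each retained factor the measure with the largest
#' absolute loading is kept (ties broken by measure-name order, i.e. column
#' order of the documented measure list).
#'
#' @param measure_matrix Numeric subjects x measures matrix with measure
#'   colnames (>= 2 subjects).
#' @param cor_cutoff Redundancy cut-off for step 1 (default 0.95).
#' @return Character vector of selected measure names (original order).
#' @export
select_nonredundant <- function(measure_matrix, cor_cutoff = 0.95) {
  if (!is.matrix(measure_matrix) || is.null(colnames(measure_matrix)))
    stop("`measure_matrix` must be a matrix with measure colnames", call. = FALSE)
  if (nrow(measure_matrix) < 2L) stop("need at least 2 subjects", call. = FALSE)
  sds <- apply(measure_matrix, 2L, stats::sd)
  keep <- sds > 0
  if (!any(keep)) stop("all measures are constant", call. = FALSE)
  if (!all(keep))
    message("select_nonredundant: dropped constant measure(s): ",
            paste(colnames(measure_matrix)[!keep], collapse = ", "))
  m <- scale(measure_matrix[, keep, drop = FALSE])
  if (ncol(m) == 1L) return(colnames(m))
  cm <- stats::cor(m)
  retained <- 1L
  for (j in 2L:ncol(m))
    if (all(abs(cm[j, retained]) <= cor_cutoff)) retained <- c(retained, j)
  m <- m[, retained, drop = FALSE]
  if (ncol(m) == 1L) return(colnames(m))
  eg <- eigen(stats::cor(m), symmetric = TRUE)
  nf <- max(1L, sum(eg$values > 1))
  loadings <- eg$vectors[, seq_len(nf), drop = FALSE] %*%
    diag(sqrt(eg$values[seq_len(nf)]), nf)
  picks <- unique(vapply(seq_len(nf), function(f) {
    which.max(abs(loadings[, f]))  # first index wins ties = column order
  }, integer(1L)))
  colnames(m)[sort(picks)]
}

# Calinski-Harabasz variance-ratio criterion for a k-means fit.
ch_index <- function(km, n) {
  k <- length(km$size)
  if (k < 2L || km$tot.withinss == 0) return(Inf)
  (km$betweenss / (k - 1)) / (km$tot.withinss / (n - k))
}

#' Cluster weight-loss trajectories
#'
#' k-means on the standardized selected measures, with the number of
#' clusters chosen by the Calinski-Harabasz variance-ratio criterion over
#' `k_range` (default 2-5), 50 random restarts and a fixed internal seed.
#' Rows are put in canonical (subject-id) order before clustering, so the
#' result is invariant to input row order. Clusters are labelled by
#' descending mean final %EBWL — NWL (normal weight loss) first, then IWL,
#' then LWL — and a binary recode merges all non-NWL clusters into ILWL.
#'
#' @param measures Subjects x measures matrix (from
#'   [trajectory_measure_matrix()]), with a `final` column used for
#'   labelling.
#' @param k_range Candidate cluster counts (default `2:5`).
#' @param selected Measure names to cluster on; `NULL` (default) runs
#'   [select_nonredundant()] first.
#' @param nstart Random restarts per k (default 50).
#' @return A list of class `traj_clusters`: `assignments` (data frame `id`,
#'   `cluster`, `label`, `binary`, `final_ebwl`), `k`, `labels`,
#'   `group_freq_percent` (named, sums to 100), `selected_measures`,
#'   `ch_values` (per candidate k).
#' @export
cluster_trajectories <- function(measures, k_range = 2:5, selected = NULL,
                                 nstart = 50L) {
  if (!is.matrix(measures) || is.null(rownames(measures)))
    stop("`measures` must be a matrix with subject-id rownames", call. = FALSE)
  n <- nrow(measures)
  if (n < max(k_range) + 1L)
    stop("need more subjects than the largest candidate k", call. = FALSE)
  if (is.null(selected)) selected <- select_nonredundant(measures)
  if (!all(selected %in% colnames(measures)))
    stop("unknown selected measure(s)", call. = FALSE)
  ord <- order(rownames(measures))  # canonical order: row-order invariance
  x <- scale(measures[ord, selected, drop = FALSE])
  x[, apply(measures[ord, selected, drop = FALSE], 2L, stats::sd) == 0] <- 0
  n_distinct <- nrow(unique(x))
  ch <- stats::setNames(rep(NA_real_, length(k_range)), k_range)
  fits <- vector("list", length(k_range))
  for (i in seq_along(k_range)) {
    k <- k_range[i]
    if (n_distinct < k) next  # degenerate: fewer distinct points than centres
    set.seed(20201L)
    fits[[i]] <- stats::kmeans(x, centers = k, nstart = nstart, iter.max = 100L)
    ch[i] <- ch_index(fits[[i]], n)
  }
  if (all(is.na(ch)))
    stop("degenerate data: fewer distinct points than every candidate k",
         call. = FALSE)
  best <- which.max(ch)
  km <- fits[[best]]
  k <- k_range[best]
  final <- measures[ord, "final"]
  cl_final <- tapply(final, km$cluster, mean)
  rank_desc <- order(cl_final, decreasing = TRUE)  # cluster ids by mean final
  label_names <- if (k <= 3L) c("NWL", "IWL", "LWL")[seq_len(k)]
  else c("NWL", "IWL", paste0("LWL", seq_len(k - 2L)))
  label_of <- stats::setNames(label_names, rank_desc)
  label <- unname(label_of[as.character(km$cluster)])
  assignments <- data.frame(
    id = rownames(measures)[ord],
    cluster = unname(km$cluster),
    label = label,
    binary = ifelse(label == "NWL", "NWL", "ILWL"),
    final_ebwl = unname(final),
    stringsAsFactors = FALSE)
  # back to input order
  assignments <- assignments[match(rownames(measures), assignments$id), ]
  rownames(assignments) <- NULL
  freq <- 100 * table(factor(assignments$label, levels = label_names)) / n
  structure(
    list(assignments = assignments, k = k, labels = label_names,
         group_freq_percent = stats::setNames(as.numeric(freq), names(freq)),
         selected_measures = selected, ch_values = ch),
    class = "traj_clusters")
}

#' @export
print.traj_clusters <- function(x, ...) {
  cat(sprintf("<traj_clusters> k = %d on {%s}: %s\n", x$k,
              paste(x$selected_measures, collapse = ", "),
              paste(sprintf("%s %.1f%%", names(x$group_freq_percent),
                            x$group_freq_percent), collapse = ", ")))
  invisible(x)
}

#' Logistic trend of a binary outcome on adjusted acceleration
#'
#' Maximum-likelihood binomial logistic regression of the outcome on a
#' single continuous predictor. The odds ratio is `exp(slope)` per predictor
#' unit with a Wald 95% confidence interval; the trend p value is from the
#' likelihood-ratio test against the intercept-only model. Per-subject
#' predicted probabilities are returned for plotting.
#'
#' @param outcome Binary outcome (logical, 0/1, or two-level factor; the
#'   second level / `TRUE` / 1 is the modelled event).
#' @param predictor Continuous predictor (e.g. adjusted acceleration,
#'   years); must vary.
#' @param conf_level Confidence level (default 0.95).
#' @return A list of class `logistic_fit`: `or`, `ci_low`, `ci_high`,
#'   `p_trend`, `slope`, `se`, `n_by_class`, `fitted_prob`.
#' @export
logistic_trend <- function(outcome, predictor, conf_level = 0.95) {
  if (length(outcome) != length(predictor))
    stop("`outcome` and `predictor` must be aligned", call. = FALSE)
  y <- if (is.logical(outcome)) as.integer(outcome)
  else if (is.factor(outcome)) as.integer(outcome) - 1L
  else as.integer(outcome)
  if (!all(y %in% c(0L, 1L))) stop("`outcome` must be binary", call. = FALSE)
  if (length(y) < 10L) stop("need at least 10 observations", call. = FALSE)
  if (length(unique(y)) < 2L)
    stop("single-class outcome: both classes must be present", call. = FALSE)
  if (stats::sd(predictor) == 0)
    stop("predictor has no variation", call. = FALSE)
  fit <- suppressWarnings(stats::glm(y ~ predictor, family = stats::binomial()))
  b <- stats::coef(fit)[2L]
  se <- summary(fit)$coefficients[2L, 2L]
  eps <- 1e-8
  if (abs(b) > 20 || all(fit$fitted.values > 1 - eps | fit$fitted.values < eps))
    stop(sprintf("complete or quasi-complete separation (slope %.3g, SE %.3g): odds ratio not identifiable",
                 b, se), call. = FALSE)
  z <- stats::qnorm(1 - (1 - conf_level) / 2)
  p_trend <- stats::pchisq(fit$null.deviance - fit$deviance, df = 1L,
                           lower.tail = FALSE)
  structure(
    list(or = exp(unname(b)), ci_low = exp(unname(b - z * se)),
         ci_high = exp(unname(b + z * se)), p_trend = p_trend,
         slope = unname(b), se = unname(se),
         n_by_class = table(y), fitted_prob = unname(fit$fitted.values)),
    class = "logistic_fit")
}

#' @export
print.logistic_fit <- function(x, ...) {
  cat(sprintf("<logistic_fit> OR = %.3f (95%% CI %.3f-%.3f), trend p = %.3g\n",
              x$or, x$ci_low, x$ci_high, x$p_trend))
  invisible(x)
}
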