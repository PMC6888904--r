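#' Epigenetic age acceleration
#'
#' Acceleration is the residual from the simple OLS regression of DNAm age on
#' chronological age — the deviation from the cohort's own age trend, not
#' from the identity line. Residuals are returned in input order and sum to
#' zero.
#'
#' @param dnam_age Per-sample DNAm age in years.
#' @param chron_age Per-sample chronological age in years, aligned.
#' @param tissue Optional tissue label carried into the result.
#' @return A list of class `acceleration_result`: `residual` (years, input
#'   order), `slope`, `intercept`, `fitted`, `n`, `tissue`.
#' @export
age_acceleration <- function(dnam_age, chron_age, tissue = NULL) {
  if (length(dnam_age) != length(chron_age))
    stop("`dnam_age` and `chron_age` must be aligned", call. = FALSE)
  if (length(dnam_age) < 3L) stop("need at least 3 samples", call. = FALSE)
  if (stats::sd(chron_age) == 0)
    stop("chronological age is constant: regression slope undefined", call. = FALSE)
  fit <- stats::lm(dnam_age ~ chron_age)
  structure(
    list(residual = unname(stats::residuals(fit)),
         slope = unname(stats::coef(fit)[2L]),
         intercept = unname(stats::coef(fit)[1L]),
         fitted = unname(stats::fitted(fit)),
         n = length(dnam_age), tissue = tissue),
    class = "acceleration_result")
}

#' Adjusted epigenetic age acceleration
#'
#' Residuals of the multivariate OLS regression of DNAm age on chronological
#' age, sex and BMI — the continuous acceleration measure used as predictor
#' in logistic trend models.
#'
#' @param dnam_age,chron_age Aligned per-sample ages in years.
#' @param sex Factor or character, two levels; coded with female = 1,
#'   male = 0 (reference male).
#' @param bmi Per-sample BMI in kg/m2.
#' @return Numeric vector of adjusted residuals (years), input order.
#' @export
adjusted_acceleration <- function(dnam_age, chron_age, sex, bmi) {
  n <- length(dnam_age)
  if (length(chron_age) != n || length(sex) != n || length(bmi) != n)
    stop("all inputs must be aligned per-sample vectors", call. = FALSE)
  if (n <= 4L)
    stop("need more samples than covariates + 1", call. = FALSE)
  sex <- factor(as.character(sex), levels = c("male", "female"))
  if (anyNA(sex)) stop("`sex` must be 'male' or 'female'", call. = FALSE)
  if (length(unique(sex)) < 2L)
    stop("`sex` is constant: design would be collinear", call. = FALSE)
  fit <- stats::lm(dnam_age ~ chron_age + sex + bmi)
  if (anyNA(stats::coef(fit)))
    stop("collinear design: aliased term(s) ",
         paste(names(stats::coef(fit))[is.na(stats::coef(fit))], collapse = ", "),
         call. = FALSE)
  unname(stats::residuals(fit))
}

#' Pearson correlation test
#'
#' @param x,y Aligned numeric vectors (n >= 3, nonzero variance).
#' @return A list of class `correlation_result`: `r`, `p` (two-sided, from
#'   the t distribution with n - 2 df), `n`.
#' @export
pearson_test <- function(x, y) {
  if (length(x) != length(y)) stop("`x` and `y` must be aligned", call. = FALSE)
  ok <- stats::complete.cases(x, y)
  x <- x[ok]; y <- y[ok]
  if (length(x) < 3L) stop("need at least 3 complete pairs", call. = FALSE)
  if (stats::sd(x) == 0 || stats::sd(y) == 0)
    stop("zero variance: correlation undefined", call. = FALSE)
  ct <- stats::cor.test(x, y, method = "pearson", alternative = "two.sided")
  structure(list(r = unname(ct$estimate), p = ct$p.value, n = length(x)),
            class = "correlation_result")
}

#' @export
print.correlation_result <- function(x, ...) {
  cat(sprintf("<correlation_result> r = %.3f, p = %.3g, n = %d\n", x$r, x$p, x$n))
  invisible(x)
}

#' Smallest detectable Pearson correlation at a given power
#'
#' Fisher z approximation: the population correlation detectable with the
#' requested power in a two-sided test is
#' `tanh((qnorm(1 - alpha/2) + qnorm(power)) / sqrt(n - 3))`. At n = 52,
#' power 0.8, alpha 0.05 this gives r = 0.38.
#'
#' @param n Sample size(s), >= 4.
#' @param power Target power in (0, 1).
#' @param alpha Two-sided significance level in (0, 1).
#' @return Required correlation coefficient (vectorized over `n`).
#' @export
required_r_for_power <- function(n, power = 0.8, alpha = 0.05) {
  if (any(n < 4)) stop("`n` must be >= 4", call. = FALSE)
  if (power <= 0 || power >= 1 || alpha <= 0 || alpha >= 1)
    stop("`power` and `alpha` must be in (0, 1)", call. = FALSE)
  tanh((stats::qnorm(1 - alpha / 2) + stats::qnorm(power)) / sqrt(n - 3))
}

#' Multivariate association of BMI with epigenetic age
#'
#' OLS regression of DNAm age on chronological age, BMI, sex and (optionally)
#' metabolic syndrome, with Wald 95% confidence intervals from the t
#' distribution, per-term p values and adjusted R-squared. Estimating the
#' chronological-age term (rather than regressing pre-computed residuals)
#' yields the full coefficient table including the age slope.
#'
#' @param dnam_age,chron_age,bmi Aligned numeric vectors.
#' @param sex Two-level factor/character; female = 1, male = 0.
#' @param mets Optional logical (or 0/1) metabolic-syndrome status; omit for
#'   datasets without syndrome classification.
#' @param conf_level Confidence level (default 0.95).
#' @return A data frame of class `ols_fit` with columns `term`, `estimate`,
#'   `se`, `ci_low`, `ci_high`, `p`; attributes `adj_r2` and `n`.
#' @export
multivariate_fit <- function(dnam_age, chron_age, bmi, sex, mets = NULL,
                             conf_level = 0.95) {
  n <- length(dnam_age)
  if (n <= 5L) stop("need n > 5 for the multivariate model", call. = FALSE)
  sex <- factor(as.character(sex), levels = c("male", "female"))
  dat <- data.frame(dnam_age = dnam_age, chron_age = chron_age, bmi = bmi,
                    sex = sex)
  form <- dnam_age ~ chron_age + bmi + sex
  if (!is.null(mets)) {
    dat$mets <- as.numeric(mets)
    form <- dnam_age ~ chron_age + bmi + sex + mets
  }
  fit <- stats::lm(form, data = dat)
  if (anyNA(stats::coef(fit)))
    stop("rank-deficient design: aliased term(s) ",
         paste(names(stats::coef(fit))[is.na(stats::coef(fit))], collapse = ", "),
         call. = FALSE)
  sm <- summary(fit)
  ci <- stats::confint(fit, level = conf_level)
  term <- rownames(sm$coefficients)
  term[term == "sexfemale"] <- "sex"
  out <- data.frame(
    term = term,
    estimate = unname(sm$coefficients[, "Estimate"]),
    se = unname(sm$coefficients[, "Std. Error"]),
    ci_low = unname(ci[, 1L]),
    ci_high = unname(ci[, 2L]),
    p = unname(sm$coefficients[, "Pr(>|t|)"]),
    stringsAsFactors = FALSE)
  attr(out, "adj_r2") <- sm$adj.r.squared
  attr(out, "n") <- n
  class(out) <- c("ols_fit", "data.frame")
  out
}

#' Epigenetic aging in years per 10 BMI units
#'
#' Converts the BMI coefficient of a [multivariate_fit()] into the increase
#' of epigenetic age for a 10-point BMI increase. Two documented conventions:
#' `simple` is `10 * beta_BMI`; `age_normalized` is
#' `10 * beta_BMI / beta_chron_age`, i.e. rescaled so one year of
#' chronological age corresponds to one year of DNAm age (correcting for a
#' clock age slope below 1).
#'
#' @param fit An `ols_fit` containing a `bmi` term (and `chron_age` for
#'   `age_normalized`).
#' @param mode `"age_normalized"` (default) or `"simple"`.
#' @return Years per 10 BMI units.
#' @export
years_per_10bmi <- function(fit, mode = c("age_normalized", "simple")) {
  mode <- match.arg(mode)
  stopifnot(inherits(fit, "ols_fit"))
  b_bmi <- fit$estimate[fit$term == "bmi"]
  if (length(b_bmi) != 1L) stop("fit has no `bmi` term", call. = FALSE)
  if (mode == "simple") return(10 * b_bmi)
  b_age <- fit$estimate[fit$term == "chron_age"]
  if (length(b_age) != 1L)
    stop("fit has no `chron_age` term (required for age_normalized)", call. = FALSE)
  if (b_age == 0)
    stop("chronological-age coefficient is zero: age_normalized undefined",
         call. = FALSE)
  10 * b_bmi / b_age
}

#' Trim a cohort to the interior of an empirical quantile band
#'
#' Retains rows whose `on` value lies strictly between the lower and upper
#' empirical quantiles (type-7, linear interpolation), i.e. the boundary
#' values themselves are excluded.
#'
#' @param cohort Data frame.
#' @param lower,upper Quantile probabilities, `0 <= lower < upper <= 1`.
#' @param on Column name to trim on (default `"chron_age"`).
#' @return The trimmed data frame (attribute `quantiles` records the
#'   cut-offs).
#' @export
percentile_trim <- function(cohort, lower = 0.10, upper = 0.90,
                            on = "chron_age") {
  if (!(on %in% names(cohort))) stop("no column `", on, "` in cohort", call. = FALSE)
  if (lower < 0 || upper > 1 || lower >= upper)
    stop("need 0 <= lower < upper <= 1", call. = FALSE)
  x <- cohort[[on]]
  q <- stats::quantile(x, c(lower, upper), type = 7, names = FALSE)
  keep <- x > q[1L] & x < q[2L]
  if (!any(keep)) stop("trim leaves no subjects", call. = FALSE)
  out <- cohort[keep, , drop = FALSE]
  attr(out, "quantiles") <- q
  out
}

#' Two-group comparison of acceleration
#'
#' Independent two-sample Student's t test (equal variances by default;
#' set `var_equal = FALSE` for the Welch variant).
#'
#' @param values Numeric vector (e.g. acceleration in years).
#' @param group Two-level factor/character, aligned with `values`; each
#'   group needs n >= 2.
#' @param var_equal Pool variances (default `TRUE`).
#' @return List: `t`, `p` (two-sided), `group_means` (named), `n` (named).
#' @export
compare_groups <- function(values, group, var_equal = TRUE) {
  group <- factor(group)
  if (nlevels(group) != 2L)
    stop("`group` must have exactly two levels", call. = FALSE)
  counts <- table(group)
  if (any(counts < 2L))
    stop("each group needs at least 2 observations", call. = FALSE)
  tt <- stats::t.test(values ~ group, var.equal = var_equal)
  means <- vapply(split(values, group), mean, numeric(1L))
  list(t = unname(tt$statistic), p = tt$p.value,
       group_means = means, n = as.vector(counts))
}
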