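#' Construct an epigenetic clock model
#'
#' A clock model is an intercept plus a named vector of per-CpG weights, with
#' the adult-age constant of the nonlinear age calibration attached. DNAm age
#' for a sample is `uncalibrate_age(intercept + sum(w * beta))`.
#'
#' @param intercept Intercept on the calibrated-age scale.
#' @param coefficients Named numeric vector mapping CpG identifiers to weights.
#' @param name Clock label used in printing and reports.
#' @param adult_age Adult-age constant of the calibration transform (years).
#'   A property of the coefficient set; the canonical published value is 20.
#' @param original_size Number of CpGs in the clock the coefficients were
#'   taken from, if this model is already a reduced version (e.g. 353 for the
#'   full published clock). Used for reduction reporting; `NULL` means the
#'   current coefficient count is the original size.
#' @return An object of class `clock_model`.
#' @seealso [dnam_age()], [reduce_clock()], [read_clock_coefficients()]
#' @export
clock_model <- function(intercept, coefficients, name = "clock",
                        adult_age = 20, original_size = NULL) {
  if (!is.numeric(intercept) || length(intercept) != 1L || !is.finite(intercept))
    stop("`intercept` must be a single finite number", call. = FALSE)
  if (!is.numeric(coefficients) || length(coefficients) == 0L)
    stop("`coefficients` must be a nonempty named numeric vector", call. = FALSE)
  cpgs <- names(coefficients)
  if (is.null(cpgs) || any(!nzchar(cpgs)))
    stop("every coefficient must be named by its CpG identifier", call. = FALSE)
  if (anyDuplicated(cpgs))
    stop("duplicate CpG identifiers in clock coefficients: ",
         paste(unique(cpgs[duplicated(cpgs)]), collapse = ", "), call. = FALSE)
  if (any(!is.finite(coefficients)))
    stop("clock coefficients must all be finite", call. = FALSE)
  if (!is.numeric(adult_age) || length(adult_age) != 1L || adult_age <= 0)
    stop("`adult_age` must be a single positive number", call. = FALSE)
  if (!is.null(original_size) &&
      (!is.numeric(original_size) || original_size < length(coefficients)))
    stop("`original_size` must be >= the number of coefficients", call. = FALSE)
  structure(
    list(name = name, intercept = as.numeric(intercept),
         coefficients = coefficients, adult_age = as.numeric(adult_age),
         original_size = if (is.null(original_size)) NULL else as.integer(original_size)),
    class = "clock_model")
}

#' @export
print.clock_model <- function(x, ...) {
  cat(sprintf("<clock_model> %s: %d CpGs, intercept %.4g, adult_age %g\n",
              x$name, length(x$coefficients), x$intercept, x$adult_age))
  if (!is.null(x$original_size))
    cat(sprintf("  reduced from %d CpGs\n", x$original_size))
  invisible(x)
}

#' Nonlinear age calibration used by the epigenetic clock
#'
#' Maps chronological age onto the calibrated scale the clock is trained on:
#' logarithmic below the adult age, linear above it, continuous and strictly
#' increasing, with `calibrate_age(adult_age) == 0`.
#'
#' @param age Age(s) in years; must be greater than -1.
#' @param adult_age Adult-age constant in years (default 20).
#' @return Calibrated age value(s):
#'   `log(age + 1) - log(adult_age + 1)` for `age <= adult_age`, otherwise
#'   `(age - adult_age) / (adult_age + 1)`.
#' @export
calibrate_age <- function(age, adult_age = 20) {
  if (!is.numeric(age)) stop("`age` must be numeric", call. = FALSE)
  if (any(is.finite(age) & age <= -1) || any(!is.finite(age)))
    stop("`age` must be finite and greater than -1", call. = FALSE)
  ifelse(age <= adult_age,
         log(age + 1) - log(adult_age + 1),
         (age - adult_age) / (adult_age + 1))
}

#' Inverse of the clock age calibration
#'
#' @param m Calibrated-age value(s) (the linear score of the clock).
#' @param adult_age Adult-age constant in years (default 20).
#' @return Age in years: `(1 + adult_age) * exp(m) - 1` for `m <= 0`,
#'   otherwise `(1 + adult_age) * m + adult_age`. Inverse of
#'   [calibrate_age()] for all ages above -1, continuous at `m = 0`.
#' @export
uncalibrate_age <- function(m, adult_age = 20) {
  if (!is.numeric(m)) stop("`m` must be numeric", call. = FALSE)
  ifelse(m <= 0,
         (1 + adult_age) * exp(m) - 1,
         (1 + adult_age) * m + adult_age)
}

#' Reduce a clock to the CpGs available on a platform
#'
#' Drops clock CpGs absent from `available_cpgs`, keeping the intercept and the
#' surviving weights unchanged (no retraining or rescaling: the reduced clock
#' is built directly from the published coefficients). The report gives the
#' retained count and the percent reduction relative to the clock's original
#' size.
#'
#' @param full A [clock_model()].
#' @param available_cpgs Character vector of CpG identifiers present on the
#'   platform (or in a merged matrix).
#' @return A list with elements `clock` (the reduced `clock_model`) and
#'   `report` (list: `n_original`, `n_retained`, `n_dropped`,
#'   `percent_reduction` rounded to one decimal).
#' @export
reduce_clock <- function(full, available_cpgs) {
  stopifnot(inherits(full, "clock_model"))
  if (length(available_cpgs) == 0L)
    stop("`available_cpgs` is empty", call. = FALSE)
  keep <- names(full$coefficients) %in% available_cpgs
  if (!any(keep))
    stop("no clock CpG is present in `available_cpgs`", call. = FALSE)
  n_orig <- if (is.null(full$original_size)) length(full$coefficients) else full$original_size
  reduced <- clock_model(
    intercept = full$intercept,
    coefficients = full$coefficients[keep],
    name = paste0(full$name, "_reduced"),
    adult_age = full$adult_age,
    original_size = n_orig)
  n_ret <- sum(keep)
  list(clock = reduced,
       report = list(n_original = as.integer(n_orig),
                     n_retained = as.integer(n_ret),
                     n_dropped = as.integer(n_orig - n_ret),
                     percent_reduction = round(100 * (n_orig - n_ret) / n_orig, 1)))
}

#' Score DNA-methylation age
#'
#' Computes the linear score `m = intercept + sum_j w_j * beta_j` over the
#' clock CpGs for every sample and maps it to years with [uncalibrate_age()].
#'
#' Clock CpGs absent from the matrix are an error under
#' `missing_policy = "error"`. Under `"mean_impute"`, per-sample missing beta
#' values are imputed with the CpG's cross-sample mean (the published clock
#' software imputes missing probes similarly); CpGs absent from the matrix
#' altogether, or missing in every sample, cannot be imputed from the data
#' and raise an error — reduce the clock first with [reduce_clock()].
#' Every use of imputation is reported with a message.
#'
#' @param betas A [beta_matrix()] (CpG x sample) or a plain numeric matrix
#'   with CpG rownames and sample colnames.
#' @param clock A [clock_model()].
#' @param missing_policy `"error"` (default) or `"mean_impute"`.
#' @return A data frame with one row per sample: `sample_id`, `linear_score`,
#'   `dnam_age`, `n_cpgs_used`, `n_cpgs_missing`
#'   (`n_cpgs_used + n_cpgs_missing` equals the clock size).
#' @export
dnam_age <- function(betas, clock, missing_policy = c("error", "mean_impute")) {
  missing_policy <- match.arg(missing_policy)
  stopifnot(inherits(clock, "clock_model"))
  vals <- if (inherits(betas, "beta_matrix")) betas$values else betas
  if (!is.matrix(vals) || is.null(rownames(vals)) || is.null(colnames(vals)))
    stop("`betas` must be a beta_matrix or a matrix with CpG rownames and sample colnames",
         call. = FALSE)
  cpgs <- names(clock$coefficients)
  present <- cpgs[cpgs %in% rownames(vals)]
  absent <- setdiff(cpgs, present)
  if (length(present) == 0L)
    stop("none of the clock CpGs are present in the matrix", call. = FALSE)
  if (length(absent) > 0L && missing_policy == "error")
    stop("clock CpGs absent from the matrix: ",
         paste(utils::head(absent, 10L), collapse = ", "),
         if (length(absent) > 10L) sprintf(" (and %d more)", length(absent) - 10L),
         call. = FALSE)
  sub <- vals[present, , drop = FALSE]
  if (anyNA(sub)) {
    if (missing_policy == "error") {
      bad <- rownames(sub)[apply(is.na(sub), 1L, any)]
      stop("missing beta values for clock CpGs under policy 'error': ",
           paste(utils::head(bad, 10L), collapse = ", "), call. = FALSE)
    }
    row_means <- rowMeans(sub, na.rm = TRUE)
    all_missing <- rownames(sub)[!is.finite(row_means)]
    if (length(all_missing) > 0L)
      stop("clock CpGs missing in every sample cannot be mean-imputed: ",
           paste(utils::head(all_missing, 10L), collapse = ", "), call. = FALSE)
    n_imp <- sum(is.na(sub))
    idx <- which(is.na(sub), arr.ind = TRUE)
    sub[idx] <- row_means[idx[, 1L]]
    message(sprintf("dnam_age: mean-imputed %d missing beta value(s) across %d CpG(s)",
                    n_imp, length(unique(idx[, 1L]))))
  }
  if (length(absent) > 0L)
    message(sprintf("dnam_age: %d clock CpG(s) absent from the matrix were dropped (mean_impute policy)",
                    length(absent)))
  w <- clock$coefficients[present]
  m <- clock$intercept + as.numeric(crossprod(sub, w))
  data.frame(
    sample_id = colnames(vals),
    linear_score = m,
    dnam_age = uncalibrate_age(m, clock$adult_age),
    n_cpgs_used = length(present),
    n_cpgs_missing = length(absent),
    stringsAsFactors = FALSE)
}
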