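#' Beta value from raw intensities
#'
#' The methylation fraction at a CpG is the methylated signal divided by the
#' total signal, `beta = C / (T + C)`.
#'
#' @param methylated_signal Nonnegative methylated intensity (C).
#' @param unmethylated_signal Nonnegative unmethylated intensity (T).
#' @return `methylated / (methylated + unmethylated)`; `NA` when both signals
#'   are zero (no information at the probe). Vectorized.
#' @export
beta_from_intensities <- function(methylated_signal, unmethylated_signal) {
  if (!is.numeric(methylated_signal) || !is.numeric(unmethylated_signal))
    stop("signals must be numeric", call. = FALSE)
  if (any(methylated_signal < 0, na.rm = TRUE) ||
      any(unmethylated_signal < 0, na.rm = TRUE))
    stop("negative signal intensity", call. = FALSE)
  total <- methylated_signal + unmethylated_signal
  ifelse(total == 0, NA_real_, methylated_signal / total)
}

#' Read and write beta matrices as TSV
#'
#' On disk a beta matrix is tab-separated text with a header row, first column
#' `cpg_id` and one column per sample; the missing-value marker is `NA`.
#' Files stored sample-major (samples in rows) are read with
#' `transpose = TRUE`. Round-trip fidelity holds, including missing values.
#'
#' @param path File path.
#' @param platform Platform label to attach (`"450k"`, `"epic"`, `"merged"`).
#' @param transpose If `TRUE` the file has samples in rows and CpGs in
#'   columns (first column then holds sample ids).
#' @return `read_beta_matrix()` returns a [beta_matrix()];
#'   `write_beta_matrix()` returns `path` invisibly.
#' @export
read_beta_matrix <- function(path, platform = c("450k", "epic", "merged"),
                             transpose = FALSE) {
  platform <- match.arg(platform)
  df <- utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  if (ncol(df) < 2L)
    stop("beta matrix file needs an id column plus at least one data column",
         call. = FALSE)
  ids <- as.character(df[[1L]])
  vals <- as.matrix(df[, -1L, drop = FALSE])
  if (!is.numeric(vals))
    stop("non-numeric beta values in ", path, call. = FALSE)
  rownames(vals) <- ids
  if (transpose) vals <- t(vals)
  bad <- which(!is.na(vals) & (vals < 0 | vals > 1), arr.ind = TRUE)
  if (nrow(bad) > 0L)
    stop(sprintf("beta value out of [0, 1] in %s at CpG '%s', sample '%s': %g",
                 path, rownames(vals)[bad[1L, 1L]], colnames(vals)[bad[1L, 2L]],
                 vals[bad[1L, , drop = FALSE]]), call. = FALSE)
  beta_matrix(vals, platform = platform)
}

#' @rdname read_beta_matrix
#' @param x A [beta_matrix()].
#' @export
write_beta_matrix <- function(x, path) {
  stopifnot(inherits(x, "beta_matrix"))
  df <- data.frame(cpg_id = rownames(x$values), x$values,
                   check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     na = "NA")
  invisible(path)
}

#' Read and write clock coefficient files
#'
#' Clock coefficients are stored as CSV with columns `term,coefficient`
#' (the layout of published clock coefficient tables): one `(Intercept)` row
#' (matched case-insensitively) and one row per CpG.
#'
#' @param path File path.
#' @param name Clock label (defaults to the file name).
#' @param adult_age Adult-age calibration constant (years).
#' @param original_size Optional original clock size for reduction reporting.
#' @return `read_clock_coefficients()` returns a [clock_model()] and reports
#'   the CpG count with a message; `write_clock_coefficients()` returns
#'   `path` invisibly.
#' @export
read_clock_coefficients <- function(path, name = NULL, adult_age = 20,
                                    original_size = NULL) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (!all(c("term", "coefficient") %in% names(df)))
    stop("clock coefficient file must have columns `term` and `coefficient`",
         call. = FALSE)
  if (nrow(df) == 0L)
    stop("empty clock coefficient file: ", path, call. = FALSE)
  is_int <- tolower(df$term) == "(intercept)"
  if (sum(is_int) == 0L)
    stop("no `(Intercept)` row in ", path, call. = FALSE)
  if (sum(is_int) > 1L)
    stop("multiple `(Intercept)` rows in ", path, call. = FALSE)
  cpg <- df[!is_int, , drop = FALSE]
  if (nrow(cpg) == 0L)
    stop("clock coefficient file has an intercept but no CpG rows: ", path,
         call. = FALSE)
  if (anyDuplicated(cpg$term))
    stop("duplicate CpG terms in ", path, ": ",
         paste(unique(cpg$term[duplicated(cpg$term)]), collapse = ", "),
         call. = FALSE)
  coefs <- stats::setNames(as.numeric(cpg$coefficient), cpg$term)
  message(sprintf("read clock '%s': %d CpG coefficients",
                  if (is.null(name)) basename(path) else name, length(coefs)))
  clock_model(intercept = as.numeric(df$coefficient[is_int]),
              coefficients = coefs,
              name = if (is.null(name)) basename(path) else name,
              adult_age = adult_age, original_size = original_size)
}

#' @rdname read_clock_coefficients
#' @param clock A [clock_model()].
#' @export
write_clock_coefficients <- function(clock, path) {
  stopifnot(inherits(clock, "clock_model"))
  df <- data.frame(term = c("(Intercept)", names(clock$coefficients)),
                   coefficient = c(clock$intercept, unname(clock$coefficients)),
                   stringsAsFactors = FALSE)
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Merge beta matrices from different platforms into a virtual array
#'
#' Restricts every matrix to the intersection of their CpG sets (sorted
#' lexicographically) and concatenates the samples, emulating the "virtual
#' 450k" construction used when combining 450k and EPIC arrays. Sample sets
#' must be disjoint; the merge is commutative and associative up to the
#' documented CpG ordering.
#'
#' @param matrices List of two or more [beta_matrix()] objects.
#' @return A [beta_matrix()] with `platform = "merged"`.
#' @export
merge_platforms <- function(matrices) {
  if (!is.list(matrices) || length(matrices) < 2L)
    stop("`matrices` must be a list of at least two beta matrices", call. = FALSE)
  if (!all(vapply(matrices, inherits, logical(1L), "beta_matrix")))
    stop("every element of `matrices` must be a beta_matrix", call. = FALSE)
  samples <- unlist(lapply(matrices, sample_ids))
  if (anyDuplicated(samples))
    stop("overlapping sample ids across platforms: ",
         paste(unique(samples[duplicated(samples)]), collapse = ", "),
         call. = FALSE)
  shared <- sort(Reduce(intersect, lapply(matrices, cpg_ids)))
  if (length(shared) == 0L)
    stop("no CpGs shared by all platforms", call. = FALSE)
  merged <- do.call(cbind, lapply(matrices, function(m) m$values[shared, , drop = FALSE]))
  beta_matrix(merged, platform = "merged")
}

#' Cross-platform concordance of beta values
#'
#' For samples assayed on both platforms, computes the per-CpG mean absolute
#' beta difference across paired samples and counts the CpGs whose mean
#' difference is strictly below the threshold (the "mean beta value
#' difference lower than" convention). Samples present on only one platform
#' are dropped with a warning. Symmetric in its arguments.
#'
#' @param m1,m2 [beta_matrix()] objects sharing CpGs and (some) sample ids.
#' @param threshold Positive beta-difference threshold (default 0.1).
#' @return A list of class `concordance_report`: `n_cpgs_compared`,
#'   `n_within_threshold`, `fraction_within` (percent, one decimal in
#'   printing, full precision stored), `threshold`, `per_cpg_mean_abs_diff`
#'   (named vector), `n_samples_paired`.
#' @export
platform_concordance <- function(m1, m2, threshold = 0.1) {
  stopifnot(inherits(m1, "beta_matrix"), inherits(m2, "beta_matrix"))
  if (!is.numeric(threshold) || length(threshold) != 1L || threshold <= 0)
    stop("`threshold` must be a single positive number", call. = FALSE)
  shared <- sort(intersect(cpg_ids(m1), cpg_ids(m2)))
  if (length(shared) == 0L)
    stop("no shared CpGs between the two matrices", call. = FALSE)
  paired <- intersect(sample_ids(m1), sample_ids(m2))
  dropped <- length(union(sample_ids(m1), sample_ids(m2))) - length(paired)
  if (length(paired) == 0L)
    stop("no samples assayed on both platforms", call. = FALSE)
  if (dropped > 0L)
    warning(sprintf("platform_concordance: %d unpaired sample(s) dropped", dropped),
            call. = FALSE)
  d <- abs(m1$values[shared, paired, drop = FALSE] -
             m2$values[shared, paired, drop = FALSE])
  mad_per_cpg <- rowMeans(d, na.rm = TRUE)
  n_within <- sum(mad_per_cpg < threshold)
  structure(
    list(n_cpgs_compared = length(shared),
         n_within_threshold = as.integer(n_within),
         fraction_within = 100 * n_within / length(shared),
         threshold = threshold,
         per_cpg_mean_abs_diff = mad_per_cpg,
         n_samples_paired = length(paired)),
    class = "concordance_report")
}

#' @export
print.concordance_report <- function(x, ...) {
  cat(sprintf("<concordance_report> %d/%d CpGs (%.1f%%) with mean |beta diff| < %g over %d paired samples\n",
              x$n_within_threshold, x$n_cpgs_compared, x$fraction_within,
              x$threshold, x$n_samples_paired))
  invisible(x)
}
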