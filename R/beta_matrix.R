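#' Construct a beta-value matrix
#'
#' Container for array methylation fractions (beta values, in `[0, 1]`,
#' `NA` allowed for missing) with CpGs in rows, samples in columns and a
#' platform label.
#'
#' @param values Numeric matrix, CpG x sample, with unique rownames
#'   (CpG identifiers) and unique colnames (sample identifiers).
#' @param platform One of `"450k"`, `"epic"`, `"merged"`.
#' @return An object of class `beta_matrix` with fields `values` and
#'   `platform`.
#' @export
beta_matrix <- function(values, platform = c("450k", "epic", "merged")) {
  platform <- match.arg(platform)
  if (!is.matrix(values) || !is.numeric(values))
    stop("`values` must be a numeric matrix", call. = FALSE)
  if (is.null(rownames(values)) || is.null(colnames(values)))
    stop("`values` must have CpG rownames and sample colnames", call. = FALSE)
  if (anyDuplicated(rownames(values)))
    stop("duplicate CpG identifiers: ",
         paste(unique(rownames(values)[duplicated(rownames(values))]), collapse = ", "),
         call. = FALSE)
  if (anyDuplicated(colnames(values)))
    stop("duplicate sample identifiers: ",
         paste(unique(colnames(values)[duplicated(colnames(values))]), collapse = ", "),
         call. = FALSE)
  bad <- which(!is.na(values) & (values < 0 | values > 1), arr.ind = TRUE)
  if (nrow(bad) > 0L)
    stop(sprintf("beta value out of [0, 1] at CpG '%s', sample '%s': %g",
                 rownames(values)[bad[1L, 1L]], colnames(values)[bad[1L, 2L]],
                 values[bad[1L, , drop = FALSE]]), call. = FALSE)
  structure(list(values = values, platform = platform), class = "beta_matrix")
}

#' @export
print.beta_matrix <- function(x, ...) {
  cat(sprintf("<beta_matrix> %d CpGs x %d samples [%s]%s\n",
              nrow(x$values), ncol(x$values), x$platform,
              if (anyNA(x$values)) sprintf(", %d missing", sum(is.na(x$values))) else ""))
  invisible(x)
}

#' @rdname beta_matrix
#' @param x A `beta_matrix`.
#' @export
cpg_ids <- function(x) {
  stopifnot(inherits(x, "beta_matrix"))
  rownames(x$values)
}

#' @rdname beta_matrix
#' @export
sample_ids <- function(x) {
  stopifnot(inherits(x, "beta_matrix"))
  colnames(x$values)
}

#' @export
dim.beta_matrix <- function(x) dim(x$values)
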