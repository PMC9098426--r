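#' Expression matrix bound to a sample sheet
#'
#' Container for a features x samples abundance table together with its
#' sample annotation (condition, time in hours, replicate) and the unit the
#' values are in. All downstream stages check the unit so that, e.g., rhythm
#' detection runs on unlogged CPM and PSI on TPM.
#'
#' @param values numeric matrix, features in rows, samples in columns.
#'   Dimnames are required and become the feature/sample ids.
#' @param samples data.frame with columns `sample_id`, `condition`, `time_h`
#'   and optionally `replicate` (defaults to 1). Row order must cover the
#'   columns of `values`.
#' @param unit one of `"counts"`, `"TPM"`, `"CPM"`.
#'
#' @return An object of class `expr_matrix`: a list with elements `values`,
#'   `samples`, `unit`.
#' @export
expr_matrix <- function(values, samples, unit = c("counts", "TPM", "CPM")) {
  unit <- match.arg(unit)
  if (!is.matrix(values) || !is.numeric(values))
    stop("`values` must be a numeric matrix")
  if ((nrow(values) > 0 && is.null(rownames(values))) ||
      (ncol(values) > 0 && is.null(colnames(values))))
    stop("`values` must have feature and sample dimnames")
  if (is.null(rownames(values))) rownames(values) <- character(0)
  if (is.null(colnames(values))) colnames(values) <- character(0)
  if (any(values < 0, na.rm = TRUE))
    stop("expression values must be non-negative")
  if (anyDuplicated(colnames(values)))
    stop("sample ids must be unique")
  if (anyDuplicated(rownames(values)))
    stop("feature ids must be unique")
  samples <- as.data.frame(samples)
  req <- c("sample_id", "condition", "time_h")
  miss <- setdiff(req, names(samples))
  if (length(miss))
    stop("sample sheet is missing columns: ", paste(miss, collapse = ", "))
  if (!"replicate" %in% names(samples)) samples$replicate <- 1L
  if (!setequal(samples$sample_id, colnames(values)))
    stop("sample sheet ids do not match matrix columns")
  samples <- samples[match(colnames(values), samples$sample_id), , drop = FALSE]
  rownames(samples) <- NULL
  structure(list(values = values, samples = samples, unit = unit),
            class = "expr_matrix")
}

#' @export
print.expr_matrix <- function(x, ...) {
  cat(sprintf("expr_matrix: %d features x %d samples [%s]\n",
              nrow(x$values), ncol(x$values), x$unit))
  cat("conditions:", paste(unique(x$samples$condition), collapse = ", "), "\n")
  invisible(x)
}

#' @export
dim.expr_matrix <- function(x) dim(x$values)

#' Subset an expression matrix by features and/or samples
#'
#' @param x an [expr_matrix()].
#' @param features character vector of feature ids (or logical/integer index).
#' @param samples character vector of sample ids (or logical/integer index).
#' @return An `expr_matrix` restricted to the requested rows/columns.
#' @export
subset_expr <- function(x, features = NULL, samples = NULL) {
  stopifnot(inherits(x, "expr_matrix"))
  v <- x$values
  if (!is.null(features)) v <- v[features, , drop = FALSE]
  if (!is.null(samples)) v <- v[, samples, drop = FALSE]
  expr_matrix(v, x$samples[match(colnames(v), x$samples$sample_id), ],
              unit = x$unit)
}

#' Restrict an expression matrix to one condition
#'
#' @param x an [expr_matrix()].
#' @param condition a condition label present in the sample sheet.
#' @return An `expr_matrix` holding only that condition's samples.
#' @export
condition_slice <- function(x, condition) {
  stopifnot(inherits(x, "expr_matrix"))
  keep <- x$samples$sample_id[x$samples$condition == condition]
  if (!length(keep)) stop("no samples with condition '", condition, "'")
  subset_expr(x, samples = keep)
}

#' Write / read an expression matrix as TSV
#'
#' The matrix is written with a `feature_id` first column and sample ids as
#' header; the sample sheet travels in a sibling file.
#'
#' @param x an [expr_matrix()].
#' @param path output TSV path for the matrix.
#' @param samples_path optional path for the sample sheet TSV; defaults to
#'   `<path>` with a `.samples.tsv` suffix.
#' @return `path`, invisibly.
#' @export
write_expr_tsv <- function(x, path, samples_path = NULL) {
  stopifnot(inherits(x, "expr_matrix"))
  df <- data.frame(feature_id = rownames(x$values), x$values,
                   check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  if (is.null(samples_path))
    samples_path <- paste0(sub("\\.tsv$", "", path), ".samples.tsv")
  utils::write.table(x$samples, samples_path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' @rdname write_expr_tsv
#' @param unit unit label to attach on read.
#' @export
read_expr_tsv <- function(path, samples_path = NULL,
                          unit = c("counts", "TPM", "CPM")) {
  unit <- match.arg(unit)
  df <- utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  if (names(df)[1] != "feature_id")
    stop("first column of ", path, " must be 'feature_id'")
  v <- as.matrix(df[, -1, drop = FALSE])
  rownames(v) <- df$feature_id
  if (is.null(samples_path))
    samples_path <- paste0(sub("\\.tsv$", "", path), ".samples.tsv")
  samples <- utils::read.delim(samples_path, stringsAsFactors = FALSE)
  expr_matrix(v, samples, unit = unit)
}
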