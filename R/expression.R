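#' TMM normalization factors
#'
#' Computes trimmed-mean-of-M-values scaling factors for a raw count matrix,
#' the composition-bias correction used before CPM. Per sample versus a
#' reference column, log ratios M and average log abundances A are formed
#' over features positive in both; 30% of M (15% per tail) and 5% of A are
#' trimmed and the factor is 2 to the inverse-variance-weighted mean of the
#' surviving M values. Factors are rescaled to geometric mean 1. Unless
#' given, the reference is the sample whose upper-quartile CPM is closest to
#' the mean upper quartile.
#'
#' @param counts an [expr_matrix()] with unit `"counts"`.
#' @param ref_sample optional sample id to use as the TMM reference.
#' @return A list of class `norm_factors`: `factors` (named numeric, one per
#'   sample, geometric mean 1) and `lib_sizes` (named column sums).
#' @export
tmm_factors <- function(counts, ref_sample = NULL) {
  stopifnot(inherits(counts, "expr_matrix"))
  if (counts$unit != "counts") stop("TMM requires raw counts, got ", counts$unit)
  y <- counts$values
  lib <- colSums(y)
  if (any(lib <= 0)) stop("every sample must have a positive library size")
  refCol <- NULL
  if (!is.null(ref_sample)) {
    refCol <- match(ref_sample, colnames(y))
    if (is.na(refCol)) stop("ref_sample '", ref_sample, "' not found")
  }
  ref <- if (is.null(refCol)) {
    f75 <- apply(sweep(y, 2, lib, "/"), 2, stats::quantile, p = 0.75)
    which.min(abs(f75 - mean(f75)))
  } else refCol
  shared <- colSums(y > 0 & y[, ref] > 0)
  if (any(shared == 0))
    stop("sample(s) share no positive features with the reference: ",
         paste(colnames(y)[shared == 0], collapse = ", "))
  f <- edgeR::calcNormFactors(y, lib.size = lib, method = "TMM",
                              refColumn = ref)
  names(f) <- colnames(y)
  structure(list(factors = f, lib_sizes = lib, ref_sample = colnames(y)[ref]),
            class = "norm_factors")
}

#' Counts per million
#'
#' CPM for feature g in sample k is `y_gk / (N_k * f_k) * 1e6`, with `N_k`
#' the library size and `f_k` the TMM factor (effective library size
#' scaling).
#'
#' @param counts an [expr_matrix()] with unit `"counts"`.
#' @param factors a `norm_factors` object from [tmm_factors()]; when `NULL`
#'   all factors are taken as 1.
#' @return An [expr_matrix()] with unit `"CPM"`.
#' @export
cpm_matrix <- function(counts, factors = NULL) {
  stopifnot(inherits(counts, "expr_matrix"))
  if (counts$unit != "counts") stop("CPM requires raw counts, got ", counts$unit)
  lib <- colSums(counts$values)
  f <- if (is.null(factors)) rep(1, ncol(counts$values)) else
    factors$factors[colnames(counts$values)]
  eff <- lib * f
  if (any(eff <= 0)) stop("zero effective library size")
  v <- edgeR::cpm(counts$values, lib.size = eff)
  dimnames(v) <- dimnames(counts$values)
  expr_matrix(v, counts$samples, unit = "CPM")
}

#' Filter low-expression features and renormalize
#'
#' Keeps features whose mean CPM over all samples is at least `threshold`
#' (inclusive), then recomputes TMM factors and CPM on the retained features
#' only ("renormalized using selected features"). Set
#' `refresh_factors = FALSE` to reuse the incoming factors instead.
#'
#' @param cpm an [expr_matrix()] of CPM values (pre-filter).
#' @param counts the matching counts [expr_matrix()].
#' @param threshold minimum mean CPM, default 0.5.
#' @param refresh_factors recompute TMM on the retained features (default).
#' @param factors required when `refresh_factors = FALSE`.
#' @return list with `counts`, `factors`, `cpm` restricted to retained
#'   features, plus `kept` (ids) and `dropped` (ids).
#' @export
filter_low_expression <- function(cpm, counts, threshold = 0.5,
                                  refresh_factors = TRUE, factors = NULL) {
  stopifnot(inherits(cpm, "expr_matrix"), inherits(counts, "expr_matrix"))
  if (cpm$unit != "CPM") stop("`cpm` must be in CPM")
  if (!identical(rownames(cpm$values), rownames(counts$values)) ||
      !identical(colnames(cpm$values), colnames(counts$values)))
    stop("CPM and counts must share features and samples")
  keep <- rowMeans(cpm$values) >= threshold
  if (!any(keep)) stop("filtering removed all features")
  kept <- rownames(cpm$values)[keep]
  counts_f <- subset_expr(counts, features = kept)
  if (refresh_factors) {
    nf <- tmm_factors(counts_f)
  } else {
    if (is.null(factors)) stop("factors required when refresh_factors = FALSE")
    nf <- factors
    nf$lib_sizes <- colSums(counts_f$values)
  }
  list(counts = counts_f, factors = nf, cpm = cpm_matrix(counts_f, nf),
       kept = kept, dropped = rownames(cpm$values)[!keep])
}

#' Summarize transcript abundances to gene level
#'
#' Gene value per sample is the exact sum of its transcripts' values, the
#' same summarization tximport performs for abundance matrices. Applied to
#' TPM it is how gene-level rhythmicity series are formed; antiphase isoform
#' pairs can therefore cancel into a flat gene signal.
#'
#' @param x an [expr_matrix()] at transcript level (any unit).
#' @param tx2gene data.frame with columns `transcript_id`, `gene_id`.
#' @return An [expr_matrix()] whose features are gene ids, same unit.
#' @export
summarize_to_gene <- function(x, tx2gene) {
  stopifnot(inherits(x, "expr_matrix"))
  tx2gene <- as.data.frame(tx2gene)
  stopifnot(all(c("transcript_id", "gene_id") %in% names(tx2gene)))
  idx <- match(rownames(x$values), tx2gene$transcript_id)
  if (anyNA(idx))
    stop("transcripts missing from tx2gene map: ",
         paste(utils::head(rownames(x$values)[is.na(idx)], 10), collapse = ", "))
  g <- tx2gene$gene_id[idx]
  v <- rowsum(x$values, group = g, reorder = TRUE)
  expr_matrix(v, x$samples, unit = x$unit)
}

#' Read a tx2gene map from TSV
#'
#' @param path TSV with columns `transcript_id`, `gene_id` and optionally
#'   `biotype`.
#' @return data.frame with those columns (`biotype` defaults to "unknown").
#' @export
read_tx2gene <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  stopifnot(all(c("transcript_id", "gene_id") %in% names(df)))
  if (!"biotype" %in% names(df)) df$biotype <- "unknown"
  df
}
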