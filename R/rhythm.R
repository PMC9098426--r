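#' Cosinor fit of a fixed-period rhythm
#'
#' Least-squares fit of `y(t) = M + a*cos(w t) + b*sin(w t)` with
#' `w = 2*pi/period`. Amplitude is `A = sqrt(a^2 + b^2)`, acrophase
#' `phi = (period/(2*pi)) * atan2(b, a) mod period` (the time of the fitted
#' maximum) and relative amplitude `rAMP = A/M` (NA when `M <= 0`). A
#' constant series yields `A = 0`, `rAMP = 0` and an `NA` acrophase
#' sentinel.
#'
#' @param series numeric vector of expression values.
#' @param times sampling times in hours, same length as `series`.
#' @param period rhythm period in hours (default 24).
#' @return list with `mesor`, `amplitude`, `acrophase`, `ramp`.
#' @export
cosinor_fit <- function(series, times, period = 24) {
  stopifnot(length(series) == length(times))
  if (length(unique(times)) < 4)
    stop("cosinor fit needs at least 4 distinct timepoints")
  fit <- cosinor_fit_matrix(matrix(as.numeric(series), nrow = 1), times,
                            period)
  list(mesor = unname(fit$mesor[1]), amplitude = unname(fit$amplitude[1]),
       acrophase = unname(fit$acrophase[1]), ramp = unname(fit$ramp[1]))
}

# vectorized cosinor over rows of a features x samples matrix; also returns
# residual sums of squares of the harmonic and intercept-only models
cosinor_fit_matrix <- function(V, times, period = 24) {
  w <- 2 * pi / period
  X <- cbind(1, cos(w * times), sin(w * times))
  B <- solve(crossprod(X), crossprod(X, t(V)))   # 3 x features
  M <- B[1, ]; a <- B[2, ]; b <- B[3, ]
  A <- sqrt(a^2 + b^2)
  flat <- A <= 1e-10 * pmax(abs(M), 1)
  A[flat] <- 0
  phi <- ((period / (2 * pi)) * atan2(b, a)) %% period
  phi[flat] <- NA_real_
  ramp <- ifelse(M > 0, A / M, NA_real_)
  ramp[flat] <- ifelse(M[flat] > 0, 0, NA_real_)
  res <- t(V) - X %*% B
  rss1 <- colSums(res^2)
  ybar <- colMeans(t(V))
  rss0 <- colSums(sweep(t(V), 2, ybar)^2)
  list(mesor = M, amplitude = A, acrophase = phi, ramp = ramp,
       rss1 = rss1, rss0 = rss0, n = length(times))
}

# harmonic-regression F-test p-values, vectorized over matrix rows
harmonic_f_pvalues <- function(V, times, period = 24) {
  fit <- cosinor_fit_matrix(V, times, period)
  n <- fit$n
  df2 <- n - 3
  if (df2 < 1) stop("harmonic F-test needs more timepoints than parameters")
  Fstat <- ((fit$rss0 - fit$rss1) / 2) / (fit$rss1 / df2)
  p <- stats::pf(Fstat, 2, df2, lower.tail = FALSE)
  p[fit$rss0 <= 1e-12 * pmax(fit$rss1, 1)] <- 1   # constant series
  p[!is.finite(p)] <- 1
  pmin(pmax(p, .Machine$double.xmin), 1)
}

# umbrella orderings, Mack-Wolfe weights and null moments for k phase groups
# with sizes n_i; rotation r places group r at the umbrella peak
umbrella_weights <- function(sizes) {
  k <- length(sizes)
  W <- array(0, c(k, k, k)); E <- numeric(k); SD <- numeric(k)
  N <- sum(sizes)
  q <- floor(k / 2) + 1
  for (p in seq_len(k)) {
    o <- ((p - 1 + ceiling(k / 2) + 0:(k - 1)) %% k) + 1
    for (m in seq_len(k - 1)) for (m2 in (m + 1):k) {
      if (m2 <= q) W[o[m], o[m2], p] <- W[o[m], o[m2], p] + 1
      if (m >= q) W[o[m2], o[m], p] <- W[o[m2], o[m], p] + 1
    }
    n_o <- sizes[o]
    N1 <- sum(n_o[1:q]); N2 <- sum(n_o[q:k]); np <- n_o[q]
    E[p] <- (N1^2 + N2^2 - sum(sizes^2) - np^2) / 4
    V <- (2 * (N1^3 + N2^3) + 3 * (N1^2 + N2^2) -
            sum(sizes^2 * (2 * sizes + 3)) - np^2 * (2 * np + 3) +
            12 * np * N1 * N2 - 12 * np^2 * N) / 72
    SD[p] <- sqrt(max(V, 1e-12))
  }
  list(W = W, E = E, SD = SD)
}

# fold times into phase groups; returns 1-based group index and sizes
phase_groups <- function(times, period) {
  ph <- round(times %% period, 9)
  lev <- sort(unique(ph))
  if (length(lev) < 2) stop("fewer than 2 phase groups after folding")
  g <- match(ph, lev)
  list(g = g, sizes = tabulate(g, nbins = length(lev)), phases = lev)
}

# all permutations of 1..n (n small), one per row
all_permutations <- function(n) {
  if (n == 1) return(matrix(1L, 1, 1))
  sub <- all_permutations(n - 1L)
  out <- matrix(0L, nrow(sub) * n, n)
  r <- 0L
  for (pos in seq_len(n)) {
    blk <- matrix(0L, nrow(sub), n)
    blk[, pos] <- n
    blk[, -pos] <- sub
    out[r + seq_len(nrow(sub)), ] <- blk
    r <- r + nrow(sub)
  }
  out
}

# permutation umbrella p-values for a features x samples matrix
umbrella_test_matrix <- function(V, times, period = 24, n_perm = 1000,
                                 seed = 1, exact = c("auto", "never",
                                                     "always")) {
  exact <- match.arg(exact)
  pg <- phase_groups(times, period)
  uw <- umbrella_weights(pg$sizes)
  n <- length(times)
  do_exact <- switch(exact,
                     auto = n <= 8,
                     always = TRUE,
                     never = FALSE)
  if (do_exact && n > 9) stop("exact enumeration infeasible for n > 9")
  if (do_exact) {
    perms <- all_permutations(n)
    res <- umbrella_exact_pvalues(V, pg$g - 1L, perms - 1L, as.numeric(uw$W),
                                  uw$E, uw$SD)
  } else {
    if (n_perm < 100) stop("n_perm must be at least 100")
    perms <- with_seed(seed, {
      t(vapply(seq_len(n_perm), function(i) sample.int(n), integer(n)))
    })
    res <- umbrella_perm_pvalues(V, pg$g - 1L, perms - 1L, as.numeric(uw$W),
                                 uw$E, uw$SD)
  }
  res$p
}

#' Test one series for ~24 h rhythmicity
#'
#' `method = "rank_umbrella"` (default) folds the sampling times modulo the
#' period into phase groups and computes a Mack-Wolfe umbrella rank
#' statistic maximized over circular peak positions; the p-value comes from
#' a seeded permutation null (midranks under ties), or from exhaustive
#' enumeration of all sample permutations when the series is short
#' (`exact`). `method = "harmonic_F"` is the parametric F-test of the
#' cosinor model against an intercept-only model.
#'
#' @param series numeric vector.
#' @param times sampling times in hours.
#' @param period rhythm period (default 24).
#' @param method `"rank_umbrella"` or `"harmonic_F"`.
#' @param n_perm permutations for the sampled null (>= 100).
#' @param seed integer seed for the permutation draw.
#' @param exact `"auto"` (exhaustive when <= 8 samples), `"never"`,
#'   `"always"`.
#' @return p-value in (0, 1]. An exactly constant series gives p = 1.
#' @export
rhythm_test <- function(series, times, period = 24,
                        method = c("rank_umbrella", "harmonic_F"),
                        n_perm = 1000, seed = 1,
                        exact = c("auto", "never", "always")) {
  method <- match.arg(method)
  stopifnot(length(series) == length(times))
  V <- matrix(as.numeric(series), nrow = 1)
  if (method == "harmonic_F")
    return(unname(harmonic_f_pvalues(V, times, period)))
  unname(umbrella_test_matrix(V, times, period, n_perm = n_perm, seed = seed,
                              exact = match.arg(exact)))
}

#' Detect rhythmic features in an expression matrix
#'
#' Runs [rhythm_test()] on every feature, adjusts p-values with
#' Benjamini-Hochberg across all tested features of the matrix, estimates
#' cosinor parameters, and flags features rhythmic when `q < alpha_q` and
#' `rAMP >= min_ramp` (the two gates applied to unlogged CPM series).
#'
#' @param x an [expr_matrix()] of unlogged abundances (CPM or TPM; counts
#'   are rejected). Slice to one condition first ([condition_slice()]).
#' @param period rhythm period in hours.
#' @param alpha_q BH-adjusted significance cutoff (default 0.05).
#' @param min_ramp relative-amplitude cutoff (default 0.1).
#' @param method,n_perm,seed,exact passed to the per-feature test.
#' @return data.frame with `feature_id`, `mesor`, `amplitude`, `acrophase`,
#'   `ramp`, `p`, `q`, `rhythmic`.
#' @export
detect_rhythmic <- function(x, period = 24, alpha_q = 0.05, min_ramp = 0.1,
                            method = c("rank_umbrella", "harmonic_F"),
                            n_perm = 1000, seed = 1,
                            exact = c("auto", "never", "always")) {
  stopifnot(inherits(x, "expr_matrix"))
  if (x$unit == "counts")
    stop("rhythm detection needs unlogged CPM (or TPM), not raw counts")
  if (nrow(x$values) == 0) stop("empty expression matrix")
  if (length(unique(x$samples$condition)) > 1)
    warning("matrix mixes conditions; rhythm detection is usually run ",
            "per condition")
  method <- match.arg(method)
  times <- x$samples$time_h
  V <- x$values
  p <- if (method == "harmonic_F") harmonic_f_pvalues(V, times, period)
       else umbrella_test_matrix(V, times, period, n_perm = n_perm,
                                 seed = seed, exact = match.arg(exact))
  fit <- cosinor_fit_matrix(V, times, period)
  q <- stats::p.adjust(p, method = "BH")
  rhythmic <- q < alpha_q & !is.na(fit$ramp) & fit$ramp >= min_ramp
  data.frame(feature_id = rownames(V), mesor = unname(fit$mesor),
             amplitude = unname(fit$amplitude),
             acrophase = unname(fit$acrophase), ramp = unname(fit$ramp),
             p = unname(p), q = unname(q), rhythmic = unname(rhythmic),
             row.names = NULL)
}

#' Histogram of acrophases in fixed-width bins
#'
#' Bins the acrophases of rhythmic features into `[0,w), [w,2w), ...`
#' covering one period.
#'
#' @param fits a rhythm table from [detect_rhythmic()]; only rows flagged
#'   rhythmic are counted (all rows if no `rhythmic` column).
#' @param bin_width bin width in hours (default 3).
#' @param period period in hours (default 24).
#' @return named integer vector of counts, one per bin, summing to the
#'   number of rhythmic features.
#' @export
acrophase_bins <- function(fits, bin_width = 3, period = 24) {
  if ("rhythmic" %in% names(fits)) fits <- fits[fits$rhythmic, , drop = FALSE]
  phi <- fits$acrophase %% period
  nb <- ceiling(period / bin_width)
  idx <- pmin(floor(phi / bin_width), nb - 1)
  lab <- sprintf("[%g,%g)", bin_width * (0:(nb - 1)),
                 pmin(bin_width * (1:nb), period))
  counts <- tabulate(idx + 1, nbins = nb)
  stats::setNames(as.integer(counts), lab)
}

#' Gene- versus transcript-level rhythmicity discordance
#'
#' Classifies each gene by whether the gene-level series and/or at least one
#' of its transcripts is rhythmic: `both_rhythmic`, `gene_only` (rhythmic
#' gene, no rhythmic transcript: arrhythmic transcripts summing to a
#' rhythmic gene), `transcripts_only` (e.g. antiphase isoforms cancelling at
#' the gene level), or `neither`.
#'
#' @param gene_fits rhythm table of gene-level features.
#' @param transcript_fits rhythm table of transcript-level features.
#' @param tx2gene data.frame with `transcript_id`, `gene_id`.
#' @return data.frame with `gene_id`, `class`, `n_rhythmic_transcripts`,
#'   `n_expressed_transcripts`.
#' @export
gene_transcript_discordance <- function(gene_fits, transcript_fits, tx2gene) {
  tx2gene <- as.data.frame(tx2gene)
  g_of_tx <- tx2gene$gene_id[match(transcript_fits$feature_id,
                                   tx2gene$transcript_id)]
  if (anyNA(g_of_tx))
    stop("transcripts missing from tx2gene map")
  missing_g <- setdiff(unique(g_of_tx), gene_fits$feature_id)
  if (length(missing_g))
    stop("gene(s) absent from the gene-level table: ",
         paste(utils::head(missing_g, 5), collapse = ", "))
  out <- lapply(unique(g_of_tx), function(g) {
    txr <- transcript_fits$rhythmic[g_of_tx == g]
    gr <- gene_fits$rhythmic[gene_fits$feature_id == g]
    cls <- if (gr && any(txr)) "both_rhythmic"
           else if (gr) "gene_only"
           else if (any(txr)) "transcripts_only"
           else "neither"
    data.frame(gene_id = g, class = cls,
               n_rhythmic_transcripts = sum(txr),
               n_expressed_transcripts = length(txr))
  })
  do.call(rbind, out)
}
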