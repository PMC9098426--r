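#' Candidate within-gene pairs of rhythmic transcripts
#'
#' All unordered pairs of rhythmic transcripts of the same gene
#' (lexicographic order within a pair); genes with fewer than two rhythmic
#' transcripts yield none.
#'
#' @param rhythm_table transcript-level table from [detect_rhythmic()].
#' @param tx2gene data.frame with `transcript_id`, `gene_id`.
#' @return data.frame with `gene_id`, `transcript_a`, `transcript_b`.
#' @export
enumerate_pairs <- function(rhythm_table, tx2gene) {
  tx2gene <- as.data.frame(tx2gene)
  rhy <- rhythm_table$feature_id[rhythm_table$rhythmic %in% TRUE]
  g <- tx2gene$gene_id[match(rhy, tx2gene$transcript_id)]
  if (anyNA(g)) stop("rhythmic transcripts missing from tx2gene map")
  out <- lapply(split(rhy, g), function(tx) {
    tx <- sort(tx)
    if (length(tx) < 2) return(NULL)
    idx <- utils::combn(length(tx), 2)
    data.frame(transcript_a = tx[idx[1, ]], transcript_b = tx[idx[2, ]])
  })
  keep <- !vapply(out, is.null, logical(1))
  if (!any(keep))
    return(data.frame(gene_id = character(), transcript_a = character(),
                      transcript_b = character()))
  res <- do.call(rbind, Map(function(g, d) cbind(gene_id = g, d),
                            names(out)[keep], out[keep]))
  rownames(res) <- NULL
  res
}

#' Differential-rhythmicity test for one transcript pair
#'
#' Both series are standardized to unit mesor (divided by their fitted M) so
#' that pure expression-level offsets do not register as rhythm differences,
#' then a joint harmonic regression with series-indicator interactions is
#' fitted and the equality of the two cosine/sine coefficient pairs is
#' tested with a 2-df F-test. The circular phase difference and amplitude
#' ratio come from the separate cosinor fits.
#'
#' @param series_a,series_b numeric vectors on the same time grid.
#' @param times sampling times in hours.
#' @param period rhythm period (default 24).
#' @param standardize divide each series by its fitted mesor (default TRUE).
#' @return list with `p`, `delta_phase` (hours in `[0, period/2]`),
#'   `amp_ratio` (`rAMP_b / rAMP_a` under standardization, `A_b / A_a`
#'   otherwise), `phase_a`, `phase_b`.
#' @export
pair_test <- function(series_a, series_b, times, period = 24,
                      standardize = TRUE) {
  stopifnot(length(series_a) == length(times),
            length(series_b) == length(times))
  fa <- cosinor_fit(series_a, times, period)
  fb <- cosinor_fit(series_b, times, period)
  if (stats::sd(series_a) == 0 || stats::sd(series_b) == 0)
    stop("constant series give a singular differential-rhythmicity design")
  if (standardize) {
    if (fa$mesor <= 0 || fb$mesor <= 0)
      stop("mesor standardization requires positive fitted mesors")
    ya <- series_a / fa$mesor; yb <- series_b / fb$mesor
  } else {
    ya <- series_a; yb <- series_b
  }
  w <- 2 * pi / period
  y <- c(ya, yb)
  grp <- rep(0:1, each = length(times))
  cs <- cos(w * c(times, times)); sn <- sin(w * c(times, times))
  Xf <- cbind(1, grp, cs, sn, grp * cs, grp * sn)
  Xr <- Xf[, 1:4]
  rss <- function(X) {
    b <- solve(crossprod(X), crossprod(X, y))
    sum((y - X %*% b)^2)
  }
  rss_f <- rss(Xf); rss_r <- rss(Xr)
  df2 <- length(y) - ncol(Xf)
  num <- rss_r - rss_f
  p <- if (num <= 1e-12 * max(rss_r, 1)) 1 else if (rss_f <= 0) 0 else
    stats::pf((num / 2) / (rss_f / df2), 2, df2, lower.tail = FALSE)
  dphi <- if (is.na(fa$acrophase) || is.na(fb$acrophase)) NA_real_ else {
    d <- abs(fa$acrophase - fb$acrophase) %% period
    min(d, period - d)
  }
  ratio <- if (standardize) fb$ramp / fa$ramp else fb$amplitude / fa$amplitude
  list(p = p, delta_phase = dphi, amp_ratio = ratio,
       phase_a = fa$acrophase, phase_b = fb$acrophase)
}

#' Test all within-gene rhythmic transcript pairs of one condition
#'
#' Runs [pair_test()] on every pair from [enumerate_pairs()], adjusts the
#' p-values with Benjamini-Hochberg over all tested pairs of the condition,
#' and classifies phase bins and biotype pairings via [classify_pairs()].
#'
#' @param x an [expr_matrix()] (one condition) holding the transcript
#'   series.
#' @param rhythm_table transcript rhythm table for the same samples.
#' @param tx2gene data.frame with `transcript_id`, `gene_id`, `biotype`.
#' @param period rhythm period (default 24).
#' @param alpha_q FDR cutoff (default 0.05).
#' @param min_shift phase-shift cutoff in hours (default 3).
#' @param standardize see [pair_test()].
#' @return data.frame, one row per pair; see [classify_pairs()].
#' @export
diff_rhythm_pairs <- function(x, rhythm_table, tx2gene, period = 24,
                              alpha_q = 0.05, min_shift = 3,
                              standardize = TRUE) {
  stopifnot(inherits(x, "expr_matrix"))
  pairs <- enumerate_pairs(rhythm_table, tx2gene)
  if (!nrow(pairs)) {
    return(data.frame(gene_id = character(), transcript_a = character(),
                      transcript_b = character(), phase_a = numeric(),
                      phase_b = numeric(), delta_phase = numeric(),
                      amp_ratio = numeric(), p = numeric(), q = numeric(),
                      shifted = logical(), phase_bin = character(),
                      biotype_pair = character()))
  }
  times <- x$samples$time_h
  tests <- lapply(seq_len(nrow(pairs)), function(i) {
    pair_test(x$values[pairs$transcript_a[i], ],
              x$values[pairs$transcript_b[i], ],
              times, period, standardize)
  })
  res <- cbind(pairs,
               phase_a = vapply(tests, `[[`, 0, "phase_a"),
               phase_b = vapply(tests, `[[`, 0, "phase_b"),
               delta_phase = vapply(tests, `[[`, 0, "delta_phase"),
               amp_ratio = vapply(tests, `[[`, 0, "amp_ratio"),
               p = vapply(tests, `[[`, 0, "p"))
  res$q <- stats::p.adjust(res$p, method = "BH")
  classify_pairs(res, alpha_q = alpha_q, min_shift = min_shift,
                 tx2gene = tx2gene)
}

#' Classify tested isoform pairs into phase bins and biotype pairings
#'
#' A pair is `shifted` (differentially rhythmic and phase-shifted) when
#' `q < alpha_q` and its circular phase difference is at least `min_shift`
#' hours. Phase bins follow 3-h edges: `<3`, `[3,6)`, `[6,9)`, `>=9` (the
#' circular difference cannot exceed half the period). The biotype pairing
#' is the unordered, "/"-joined pair of transcript biotypes.
#'
#' @param results pair table with `p` and `q` columns (BH over all tested
#'   pairs of the condition).
#' @param alpha_q FDR cutoff (default 0.05).
#' @param min_shift phase-shift cutoff in hours (default 3).
#' @param tx2gene optional map with `biotype` for the biotype pairing.
#' @return the table with `shifted`, `diff_rhythmic`, `phase_bin` and
#'   `biotype_pair` columns added.
#' @export
classify_pairs <- function(results, alpha_q = 0.05, min_shift = 3,
                           tx2gene = NULL) {
  results$diff_rhythmic <- results$q < alpha_q
  results$shifted <- results$diff_rhythmic &
    !is.na(results$delta_phase) & results$delta_phase >= min_shift
  bins <- c("<3", "[3,6)", "[6,9)", ">=9")
  idx <- pmin(floor(results$delta_phase / 3), 3) + 1
  results$phase_bin <- ifelse(is.na(results$delta_phase), NA_character_,
                              bins[idx])
  if (!is.null(tx2gene) && "biotype" %in% names(tx2gene)) {
    ba <- tx2gene$biotype[match(results$transcript_a, tx2gene$transcript_id)]
    bb <- tx2gene$biotype[match(results$transcript_b, tx2gene$transcript_id)]
    results$biotype_pair <- mapply(function(x, y)
      paste(sort(c(x, y)), collapse = "/"), ba, bb)
  } else {
    results$biotype_pair <- NA_character_
  }
  rownames(results) <- NULL
  results
}
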