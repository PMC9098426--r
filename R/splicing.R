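#' Percent-spliced-in per sample and event
#'
#' PSI of an event in a sample is the summed TPM of its inclusion-form
#' transcripts divided by the summed TPM of all its transcripts; it is
#' undefined (NA) where the total is zero. The mean PSI is taken over
#' defined samples only.
#'
#' @param events event table from [extract_events()] (or [read_ioe()]).
#' @param tpm an [expr_matrix()] with unit `"TPM"` at transcript level.
#' @return list of class `psi_table`: `psi` (events x samples matrix, NA
#'   where undefined), `events` (the event table), `mean_psi`,
#'   `defined_frac` (fraction of samples with defined PSI), `samples` (the
#'   sample sheet), `spliced` (logical, NA until [flag_spliced()]).
#' @export
psi_per_sample <- function(events, tpm) {
  stopifnot(inherits(tpm, "expr_matrix"))
  if (tpm$unit != "TPM") stop("PSI requires TPM input, got ", tpm$unit)
  inc <- split_tx_set(events$inclusion_transcripts)
  tot <- split_tx_set(events$total_transcripts)
  missing_tx <- setdiff(unique(unlist(tot)), rownames(tpm$values))
  if (length(missing_tx))
    stop("event transcripts absent from TPM matrix: ",
         paste(utils::head(missing_tx, 5), collapse = ", "))
  V <- tpm$values
  psi <- matrix(NA_real_, nrow(events), ncol(V),
                dimnames = list(events$event_id, colnames(V)))
  for (i in seq_len(nrow(events))) {
    num <- colSums(V[inc[[i]], , drop = FALSE])
    den <- colSums(V[tot[[i]], , drop = FALSE])
    ok <- den > 0
    psi[i, ok] <- num[ok] / den[ok]
  }
  defined <- rowSums(!is.na(psi))
  mean_psi <- ifelse(defined > 0, rowMeans(psi, na.rm = TRUE), NA_real_)
  structure(list(psi = psi, events = events, mean_psi = unname(mean_psi),
                 defined_frac = unname(defined / ncol(V)),
                 samples = tpm$samples,
                 spliced = rep(NA, nrow(events))),
            class = "psi_table")
}

#' @export
print.psi_table <- function(x, ...) {
  cat(sprintf("psi_table: %d events x %d samples (%d flagged spliced)\n",
              nrow(x$psi), ncol(x$psi), sum(x$spliced %in% TRUE)))
  invisible(x)
}

#' Flag events as alternatively spliced
#'
#' An event counts as spliced when its mean PSI lies strictly between
#' `psi_low` and `psi_high` (both bounds excluded), i.e. both forms are
#' substantially used.
#'
#' @param pt a `psi_table` from [psi_per_sample()].
#' @param psi_low,psi_high open-interval bounds (defaults 0.1 and 0.9).
#' @return the `psi_table` with its `spliced` flags filled (NA when mean PSI
#'   is undefined).
#' @export
flag_spliced <- function(pt, psi_low = 0.1, psi_high = 0.9) {
  stopifnot(inherits(pt, "psi_table"), psi_low >= 0, psi_high <= 1,
            psi_low < psi_high)
  pt$spliced <- !is.na(pt$mean_psi) & pt$mean_psi > psi_low &
    pt$mean_psi < psi_high
  pt$spliced[is.na(pt$mean_psi)] <- NA
  pt
}

#' Spliced and testable gene sets per event type
#'
#' A gene is "spliced by event type E" when at least one of its type-E
#' events is flagged spliced. Events defined in fewer than
#' `min_defined_frac` of the samples are excluded. The `tested` sets list
#' every gene with at least one sufficiently-defined type-E event,
#' regardless of the spliced flag (the universe for gain/loss bookkeeping).
#'
#' @param pt a `psi_table` after [flag_spliced()].
#' @param min_defined_frac minimum fraction of samples with defined PSI
#'   (default 0.5).
#' @return list with `spliced` and `tested`, each a named list (event type
#'   -> character vector of gene ids).
#' @export
spliced_genes <- function(pt, min_defined_frac = 0.5) {
  stopifnot(inherits(pt, "psi_table"))
  if (all(is.na(pt$spliced)) && nrow(pt$events) > 0)
    stop("run flag_spliced() first")
  ok <- pt$defined_frac >= min_defined_frac
  types <- sort(unique(pt$events$event_type))
  spliced <- lapply(types, function(ty) {
    sel <- ok & pt$events$event_type == ty & pt$spliced %in% TRUE
    sort(unique(pt$events$gene_id[sel]))
  })
  tested <- lapply(types, function(ty) {
    sel <- ok & pt$events$event_type == ty
    sort(unique(pt$events$gene_id[sel]))
  })
  names(spliced) <- names(tested) <- types
  list(spliced = spliced, tested = tested)
}

#' Classify gain and loss of splicing events between knockout and control
#'
#' Per event type, a gene is a `gain` when it is spliced in the knockout but
#' not in the control, a `loss` when spliced in the control but not the
#' knockout, `shared` when spliced in both and `absent` when testable in
#' both but spliced in neither. Each record carries flags for whether the
#' gene has a rhythmic transcript and a protein-coding transcript, for
#' stratified summaries.
#'
#' @param wt_sets,ko_sets outputs of [spliced_genes()] for the control and
#'   knockout condition (event-type keys must match).
#' @param circadian_transcripts optional character vector of rhythmic
#'   transcript ids (any condition).
#' @param tx2gene optional data.frame with `transcript_id`, `gene_id`,
#'   `biotype`, needed for the annotation flags.
#' @return data.frame with `gene_id`, `event_type`, `status`,
#'   `has_circadian_transcript`, `has_protein_coding_transcript`.
#' @export
classify_gain_loss <- function(wt_sets, ko_sets,
                               circadian_transcripts = NULL,
                               tx2gene = NULL) {
  for (s in list(wt_sets, ko_sets))
    if (!all(c("spliced", "tested") %in% names(s)))
      stop("gene sets must carry 'spliced' and 'tested' per event type")
  if (!setequal(names(wt_sets$spliced), names(ko_sets$spliced)) ||
      !setequal(names(wt_sets$tested), names(ko_sets$tested)))
    stop("event-type keys differ between WT and KO gene sets")
  out <- list()
  for (ty in sort(names(wt_sets$spliced))) {
    wt <- wt_sets$spliced[[ty]]; ko <- ko_sets$spliced[[ty]]
    universe <- sort(union(wt_sets$tested[[ty]], ko_sets$tested[[ty]]))
    if (!length(universe)) next
    status <- ifelse(universe %in% wt & universe %in% ko, "shared",
              ifelse(universe %in% wt, "loss",
              ifelse(universe %in% ko, "gain", "absent")))
    out[[ty]] <- data.frame(gene_id = universe, event_type = ty,
                            status = status)
  }
  res <- do.call(rbind, out)
  if (is.null(res))
    res <- data.frame(gene_id = character(), event_type = character(),
                      status = character())
  res$has_circadian_transcript <- NA
  res$has_protein_coding_transcript <- NA
  if (!is.null(tx2gene)) {
    tx2gene <- as.data.frame(tx2gene)
    if (!is.null(circadian_transcripts)) {
      circ_genes <- unique(tx2gene$gene_id[
        tx2gene$transcript_id %in% circadian_transcripts])
      res$has_circadian_transcript <- res$gene_id %in% circ_genes
    }
    if ("biotype" %in% names(tx2gene)) {
      pc_genes <- unique(tx2gene$gene_id[tx2gene$biotype == "protein_coding"])
      res$has_protein_coding_transcript <- res$gene_id %in% pc_genes
    }
  }
  rownames(res) <- NULL
  res
}

#' Mann-Whitney U test (midranks; exact under small n)
#'
#' Two-sided rank-sum test. When both groups have at most `exact_max`
#' observations the p-value is computed by exhaustive enumeration of all
#' group-label assignments (valid under ties via midranks); otherwise the
#' normal approximation with tie correction is used (no continuity
#' correction).
#'
#' @param x,y numeric vectors.
#' @param exact_max exact-enumeration threshold per group (default 8).
#' @return list with `u` (U statistic of `x`) and `p`.
#' @export
mann_whitney_test <- function(x, y, exact_max = 8) {
  n1 <- length(x); n2 <- length(y); N <- n1 + n2
  stopifnot(n1 >= 1, n2 >= 1)
  pooled <- c(x, y)
  r <- rank(pooled)                      # midranks
  u_obs <- sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2
  mu <- n1 * n2 / 2
  if (n1 <= exact_max && n2 <= exact_max) {
    idx <- utils::combn(N, n1)
    dev <- abs(u_obs - mu)
    cnt <- 0L
    for (j in seq_len(ncol(idx))) {
      u <- sum(r[idx[, j]]) - n1 * (n1 + 1) / 2
      if (abs(u - mu) >= dev - 1e-9) cnt <- cnt + 1L
    }
    return(list(u = u_obs, p = cnt / ncol(idx)))
  }
  ties <- table(pooled)
  sigma2 <- n1 * n2 / 12 * ((N + 1) - sum(ties^3 - ties) / (N * (N - 1)))
  if (sigma2 <= 0) return(list(u = u_obs, p = 1))
  z <- (u_obs - mu) / sqrt(sigma2)
  list(u = u_obs, p = min(1, 2 * stats::pnorm(-abs(z))))
}

#' Differential splicing between two conditions
#'
#' For every event quantified in both conditions, compares per-sample PSI
#' values between knockout and control with a two-sided Mann-Whitney test;
#' `delta_psi` is mean PSI (KO) minus mean PSI (WT). Events with fewer than
#' `min_defined` defined samples in either condition are marked untestable.
#'
#' @param pt_wt,pt_ko `psi_table` objects for control and knockout built on
#'   the same event set.
#' @param alpha significance cutoff on the raw p-value (default 0.05).
#' @param min_defined minimum defined samples per condition (default 3).
#' @return data.frame with `event_id`, `gene_id`, `event_type`,
#'   `mean_psi_wt`, `mean_psi_ko`, `delta_psi`, `p`, `significant`,
#'   `testable`.
#' @export
differential_splicing <- function(pt_wt, pt_ko, alpha = 0.05,
                                  min_defined = 3) {
  stopifnot(inherits(pt_wt, "psi_table"), inherits(pt_ko, "psi_table"))
  common <- intersect(pt_wt$events$event_id, pt_ko$events$event_id)
  iw <- match(common, pt_wt$events$event_id)
  ik <- match(common, pt_ko$events$event_id)
  res <- lapply(seq_along(common), function(j) {
    a <- pt_wt$psi[iw[j], ]; b <- pt_ko$psi[ik[j], ]
    a <- a[!is.na(a)]; b <- b[!is.na(b)]
    testable <- length(a) >= min_defined && length(b) >= min_defined
    p <- NA_real_
    if (testable) p <- mann_whitney_test(b, a)$p
    data.frame(event_id = common[j],
               gene_id = pt_wt$events$gene_id[iw[j]],
               event_type = pt_wt$events$event_type[iw[j]],
               mean_psi_wt = pt_wt$mean_psi[iw[j]],
               mean_psi_ko = pt_ko$mean_psi[ik[j]],
               delta_psi = pt_ko$mean_psi[ik[j]] - pt_wt$mean_psi[iw[j]],
               p = p,
               significant = if (testable) p < alpha else NA,
               testable = testable)
  })
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  out
}

#' Write a PSI matrix as TSV
#'
#' @param pt a `psi_table`.
#' @param path output path; undefined PSI written as "NA".
#' @return `path`, invisibly.
#' @export
write_psi_tsv <- function(pt, path) {
  df <- data.frame(event_id = rownames(pt$psi), pt$psi, check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     na = "NA")
  invisible(path)
}
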