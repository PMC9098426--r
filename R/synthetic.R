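#' Time-course sampling design
#'
#' The default mirrors a dense circadian course: 16 timepoints every 3 h
#' starting at 9 h (spanning 45 h), one replicate, a single condition.
#'
#' @param n_timepoints number of timepoints (>= 4).
#' @param t_start first sampling time, hours.
#' @param dt sampling interval, hours (> 0).
#' @param n_replicates replicates per timepoint (>= 1).
#' @param conditions character vector of condition labels; the first is the
#'   reference.
#' @param seed integer seed driving all simulation randomness.
#' @return list of class `simulation_design`, including the vector of
#'   sampling `times`.
#' @export
simulation_design <- function(n_timepoints = 16, t_start = 9, dt = 3,
                              n_replicates = 1, conditions = "WT", seed = 1) {
  stopifnot(n_timepoints >= 4, dt > 0, n_replicates >= 1,
            length(conditions) >= 1)
  structure(list(n_timepoints = as.integer(n_timepoints), t_start = t_start,
                 dt = dt, n_replicates = as.integer(n_replicates),
                 conditions = conditions, seed = as.integer(seed),
                 times = t_start + dt * seq(0, n_timepoints - 1)),
            class = "simulation_design")
}

#' Per-transcript rhythmic signal parameters
#'
#' Builds the signal-spec table consumed by [simulate_timecourse()]. The
#' noiseless expectation of a transcript at time t is
#' `mesor * (1 + rel_amplitude * cos(2*pi*(t - acrophase)/period))`;
#' multiplicative log-normal noise with coefficient of variation `noise_cv`
#' is layered on top (mean preserved).
#'
#' @param transcript_id character vector.
#' @param mesor positive baseline abundance (TPM).
#' @param rel_amplitude relative amplitude in \[0, 1\]; 0 gives a flat signal.
#' @param acrophase peak time, hours in \[0, period).
#' @param period rhythm period in hours (default 24).
#' @param noise_cv multiplicative coefficient of variation (>= 0).
#' @return data.frame with one row per transcript.
#' @export
signal_specs <- function(transcript_id, mesor = 10, rel_amplitude = 0,
                         acrophase = 0, period = 24, noise_cv = 0) {
  df <- data.frame(transcript_id = transcript_id, mesor = mesor,
                   rel_amplitude = rel_amplitude, acrophase = acrophase,
                   period = period, noise_cv = noise_cv,
                   stringsAsFactors = FALSE)
  stopifnot(all(df$mesor >= 0), all(df$rel_amplitude >= 0),
            all(df$rel_amplitude <= 1), all(df$period > 0),
            all(df$noise_cv >= 0))
  if (anyDuplicated(df$transcript_id)) stop("duplicate transcript_id in specs")
  df
}

#' Condition effect applied to a non-reference condition
#'
#' @param kind one of `"rhythm_loss"`, `"phase_shift"`, `"amplitude_scale"`,
#'   `"isoform_switch"`, `"expression_knockout"`.
#' @param condition the (non-reference) condition label the effect acts on.
#' @param transcripts target transcript ids (all kinds except
#'   `isoform_switch`).
#' @param gene target gene id (`isoform_switch`).
#' @param delta_hours phase shift in hours (`phase_shift`).
#' @param factor amplitude multiplier (`amplitude_scale`).
#' @param fractions named vector of new isoform fractions summing to 1 over
#'   the gene's expressed transcripts (`isoform_switch`); the gene's total
#'   expected abundance is preserved.
#' @return list of class `condition_effect`.
#' @export
condition_effect <- function(kind = c("rhythm_loss", "phase_shift",
                                      "amplitude_scale", "isoform_switch",
                                      "expression_knockout"),
                             condition, transcripts = NULL, gene = NULL,
                             delta_hours = NULL, factor = NULL,
                             fractions = NULL) {
  kind <- match.arg(kind)
  if (kind == "isoform_switch") {
    if (is.null(gene) || is.null(fractions) || is.null(names(fractions)))
      stop("isoform_switch needs `gene` and named `fractions`")
    if (abs(sum(fractions) - 1) > 1e-8)
      stop("isoform fractions must sum to 1")
  } else if (is.null(transcripts)) {
    stop(kind, " needs target `transcripts`")
  }
  if (kind == "phase_shift" && is.null(delta_hours))
    stop("phase_shift needs `delta_hours`")
  if (kind == "amplitude_scale" && is.null(factor))
    stop("amplitude_scale needs `factor`")
  structure(list(kind = kind, condition = condition,
                 transcripts = transcripts, gene = gene,
                 delta_hours = delta_hours, factor = factor,
                 fractions = fractions),
            class = "condition_effect")
}

# toy gene builders ---------------------------------------------------------

# each returns a list of exon matrices (one per transcript), genomic coords
# relative to 0; randomness: exon/intron lengths
toy_gene_shapes <- list(
  SE = function(L) {
    e1 <- c(0, L[1]); i1 <- L[2]; e2 <- c(e1[2] + i1, e1[2] + i1 + L[3])
    i2 <- L[4]; e3 <- c(e2[2] + i2, e2[2] + i2 + L[5])
    list(rbind(e1, e2, e3), rbind(e1, e3))
  },
  RI = function(L) {
    e1 <- c(0, L[1]); i1 <- L[2]; e2 <- c(e1[2] + i1, e1[2] + i1 + L[3])
    list(rbind(e1, e2), rbind(c(e1[1], e2[2])))
  },
  MX = function(L) {
    e1 <- c(0, L[1])
    ea <- c(e1[2] + L[2], e1[2] + L[2] + L[3])
    eb <- c(ea[2] + L[4], ea[2] + L[4] + L[5])
    e3 <- c(eb[2] + L[6], eb[2] + L[6] + L[7])
    list(rbind(e1, ea, e3), rbind(e1, eb, e3))
  },
  # two introns sharing their right end; overlapping left-flank exons
  alt_left = function(L) {
    d2 <- L[1] + L[2]                       # longer left exon
    a <- d2 + L[3]
    e2 <- c(a, a + L[4])
    list(rbind(c(0, L[1]), e2), rbind(c(0, d2), e2))
  },
  # two introns sharing their left end; overlapping right-flank exons
  alt_right = function(L) {
    d <- L[1]; a1 <- d + L[2]; a2 <- a1 + L[3]; e <- a2 + L[4]
    list(rbind(c(0, d), c(a1, e)), rbind(c(0, d), c(a2, e)))
  },
  # disjoint alternative leftmost exons into a shared right exon
  term_left = function(L) {
    f1 <- c(0, L[1]); f2 <- c(f1[2] + L[2], f1[2] + L[2] + L[3])
    a <- f2[2] + L[4]; e2 <- c(a, a + L[5])
    list(rbind(f1, e2), rbind(f2, e2))
  },
  # disjoint alternative rightmost exons out of a shared left exon
  term_right = function(L) {
    e1 <- c(0, L[1]); l1 <- c(e1[2] + L[2], e1[2] + L[2] + L[3])
    l2 <- c(l1[2] + L[4], l1[2] + L[4] + L[5])
    list(rbind(e1, l1), rbind(e1, l2))
  })

# shape realizing an event type on a given strand (terminal/boundary event
# semantics follow transcription direction)
shape_for_type <- function(type, strand) {
  switch(type,
         SE = "SE", RI = "RI", MX = "MX",
         A5 = if (strand == "+") "alt_left" else "alt_right",
         A3 = if (strand == "+") "alt_right" else "alt_left",
         AF = if (strand == "+") "term_left" else "term_right",
         AL = if (strand == "+") "term_right" else "term_left",
         stop("unknown event code: ", type))
}

#' Generate a toy annotation realizing requested event types
#'
#' Builds `n_genes_per_type` two-transcript genes for every requested local
#' event mode, with randomized exon/intron lengths, strands alternating
#' across genes and transcript biotypes drawn from a small realistic menu.
#' By construction [extract_events()] recovers exactly one event of the
#' requested type per gene.
#'
#' @param event_menu subset of `c("A3","A5","AF","AL","MX","RI","SE")`.
#' @param n_genes_per_type genes to build per event type.
#' @param seed integer seed (RNG state is restored on exit).
#' @return A [transcript_annotation()].
#' @export
generate_annotation <- function(event_menu = c("A3", "A5", "AF", "AL", "MX",
                                               "RI", "SE"),
                                n_genes_per_type = 1, seed = 1) {
  allowed <- c("A3", "A5", "AF", "AL", "MX", "RI", "SE")
  bad <- setdiff(event_menu, allowed)
  if (length(bad)) stop("unknown event code(s): ", paste(bad, collapse = ", "))
  event_menu <- unique(event_menu)
  with_seed(seed, {
    genes <- list(); txs <- list(); exons <- list()
    offset <- 0L; counter <- 0L
    for (type in event_menu) for (k in seq_len(n_genes_per_type)) {
      counter <- counter + 1L
      strand <- if (counter %% 2L == 1L) "+" else "-"
      gid <- sprintf("G%s%03d", type, k)
      L <- sample(50:250, 8, replace = TRUE)
      chains <- toy_gene_shapes[[shape_for_type(type, strand)]](L)
      bio <- c("protein_coding",
               if (type == "RI") "retained_intron" else
                 sample(c("protein_coding", "processed_transcript",
                          "retained_intron"), 1))
      for (ti in seq_along(chains)) {
        tid <- sprintf("%s.T%d", gid, ti)
        m <- chains[[ti]] + offset
        txs[[tid]] <- data.frame(transcript_id = tid, gene_id = gid,
                                 biotype = bio[ti])
        exons[[tid]] <- data.frame(transcript_id = tid, start = m[, 1],
                                   end = m[, 2])
      }
      genes[[gid]] <- data.frame(gene_id = gid, chrom = "chr1",
                                 strand = strand)
      offset <- offset + max(chains[[1]][, 2], chains[[2]][, 2]) + 1000L
    }
    transcript_annotation(do.call(rbind, genes), do.call(rbind, txs),
                          do.call(rbind, exons))
  })
}

# evaluate an expression with a private RNG stream, restoring global state
with_seed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()))
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())))
  }
  set.seed(seed)
  expr
}

#' Simulate a time-course transcript expression experiment
#'
#' For every condition/replicate/timepoint, each transcript's expected TPM
#' follows its cosinor signal spec, modified by any condition effects;
#' multiplicative log-normal noise (mean-preserving) is applied; counts are
#' drawn Poisson with per-sample totals `lib_size`, allocated proportionally
#' to TPM times transcript length (summed exon length).
#'
#' @param annotation a [transcript_annotation()].
#' @param design a [simulation_design()].
#' @param specs signal-spec table from [signal_specs()]; transcripts of the
#'   annotation absent from `specs` are simulated as unexpressed.
#' @param effects list of [condition_effect()] objects.
#' @param lib_size target per-sample count total (default 1e6).
#' @return list with `tpm` and `counts` ([expr_matrix()] objects sharing a
#'   sample sheet) and `truth` (design, specs, effects) for assertions.
#' @export
simulate_timecourse <- function(annotation, design, specs,
                                effects = list(), lib_size = 1e6) {
  stopifnot(inherits(annotation, "transcript_annotation"),
            inherits(design, "simulation_design"))
  tx_all <- annotation$transcripts$transcript_id
  unknown <- setdiff(specs$transcript_id, tx_all)
  if (length(unknown))
    stop("signal spec references unknown transcript(s): ",
         paste(utils::head(unknown, 5), collapse = ", "))
  if (inherits(effects, "condition_effect")) effects <- list(effects)
  for (ef in effects) {
    if (!ef$condition %in% design$conditions)
      stop("effect targets unknown condition '", ef$condition, "'")
    if (ef$condition == design$conditions[1])
      stop("effects must target a non-reference condition")
  }
  # full parameter table (unexpressed transcripts get mesor 0)
  base <- signal_specs(tx_all)
  base$mesor <- 0
  idx <- match(specs$transcript_id, tx_all)
  for (col in c("mesor", "rel_amplitude", "acrophase", "period", "noise_cv"))
    base[[col]][idx] <- specs[[col]]
  t2g <- annotation_tx2gene(annotation)
  times <- design$times

  sheets <- list(); tpm_cols <- list()
  with_seed(design$seed, {
    for (cond in design$conditions) {
      par <- base
      switches <- list()
      for (ef in effects) {
        if (ef$condition != cond) next
        if (ef$kind == "isoform_switch") { switches[[ef$gene]] <- ef; next }
        j <- match(ef$transcripts, par$transcript_id)
        if (anyNA(j)) stop("effect targets unknown transcript")
        if (ef$kind == "rhythm_loss") par$rel_amplitude[j] <- 0
        if (ef$kind == "expression_knockout") par$mesor[j] <- 0
        if (ef$kind == "amplitude_scale")
          par$rel_amplitude[j] <-
            pmin(1, pmax(0, par$rel_amplitude[j] * ef$factor))
        if (ef$kind == "phase_shift")
          par$acrophase[j] <-
            (par$acrophase[j] + ef$delta_hours) %% par$period[j]
      }
      # expected TPM: transcripts x timepoints
      mu <- par$mesor * (1 + par$rel_amplitude *
        cos(2 * pi * outer(-par$acrophase, times, "+") / par$period))
      rownames(mu) <- par$transcript_id
      for (g in names(switches)) {
        tx_g <- t2g$transcript_id[t2g$gene_id == g]
        fr <- switches[[g]]$fractions
        if (!all(names(fr) %in% tx_g))
          stop("isoform_switch fractions name transcripts outside gene ", g)
        tot <- colSums(mu[tx_g, , drop = FALSE])
        mu[tx_g, ] <- 0
        mu[names(fr), ] <- outer(as.numeric(fr), tot)
      }
      sdlog <- sqrt(log(1 + par$noise_cv^2))
      for (rep_i in seq_len(design$n_replicates)) {
        for (ti in seq_along(times)) {
          noise <- exp(stats::rnorm(nrow(mu), -sdlog^2 / 2, sdlog))
          noise[sdlog == 0] <- 1
          sid <- sprintf("%s_t%02d_r%d", cond, ti, rep_i)
          tpm_cols[[sid]] <- mu[, ti] * noise
          sheets[[sid]] <- data.frame(sample_id = sid, condition = cond,
                                      time_h = times[ti], replicate = rep_i)
        }
      }
    }
    tpm <- do.call(cbind, tpm_cols)
    rownames(tpm) <- tx_all
    sheet <- do.call(rbind, sheets)
    len <- transcript_lengths(annotation)[tx_all]
    counts <- apply(tpm, 2, function(col) {
      w <- col * len
      s <- sum(w)
      if (s == 0) return(rep(0L, length(w)))
      stats::rpois(length(w), lib_size * w / s)
    })
    rownames(counts) <- tx_all
    list(tpm = expr_matrix(tpm, sheet, unit = "TPM"),
         counts = expr_matrix(counts, sheet, unit = "counts"),
         truth = list(design = unclass(design), specs = base,
                      effects = lapply(effects, unclass)))
  })
}

#' Write simulation ground truth as JSON
#'
#' @param truth the `truth` element returned by [simulate_timecourse()].
#' @param path output JSON path.
#' @return `path`, invisibly.
#' @export
write_ground_truth <- function(truth, path) {
  jsonlite::write_json(truth, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}
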