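#' Assemble and validate a pipeline configuration
#'
#' A configuration is a plain list (optionally read from YAML with
#' [read_pipeline_config()]) with three blocks: `paths` (annotation GTF,
#' TPM/counts TSVs, sample sheet, optional gene-set files, `out_dir`),
#' `parameters` (thresholds and seeds; defaults below) and `conditions`
#' (`reference`, optional `comparisons`). In-memory objects can be supplied
#' under `data` (`annotation`, `tpm`, `counts`) instead of paths.
#'
#' Parameter defaults: `period = 24`, `alpha_q = 0.05`, `min_ramp = 0.1`,
#' `psi_low = 0.1`, `psi_high = 0.9`, `min_shift_h = 3`,
#' `diffsplice_alpha = 0.05`, `cpm_threshold = 0.5`, `n_perm = 1000`,
#' `seed = 1`, `method = "rank_umbrella"`.
#'
#' @param config a list as described.
#' @return the validated config with defaults filled in.
#' @export
pipeline_config <- function(config) {
  defaults <- list(period = 24, alpha_q = 0.05, min_ramp = 0.1,
                   psi_low = 0.1, psi_high = 0.9, min_shift_h = 3,
                   diffsplice_alpha = 0.05, cpm_threshold = 0.5,
                   n_perm = 1000, seed = 1, method = "rank_umbrella")
  par <- utils::modifyList(defaults, config$parameters %||% list())
  if (!(par$psi_low >= 0 && par$psi_low < par$psi_high && par$psi_high <= 1))
    stop("need 0 <= psi_low < psi_high <= 1")
  if (par$min_shift_h < 0 || par$min_shift_h > par$period / 2)
    stop("min_shift_h must lie in [0, period/2]")
  config$parameters <- par
  if (is.null(config$conditions$reference))
    stop("config$conditions$reference is required")
  config
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Read a pipeline configuration from YAML
#'
#' @param path YAML file.
#' @return validated config list (see [pipeline_config()]).
#' @export
read_pipeline_config <- function(path) {
  pipeline_config(yaml::read_yaml(path))
}

run_stage <- function(name, expr) {
  tryCatch(expr, error = function(e)
    stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
         call. = FALSE))
}

# normalize one condition's counts: TMM -> CPM -> mean-CPM filter -> re-TMM
normalize_condition <- function(counts_cond, threshold) {
  nf <- tmm_factors(counts_cond)
  cpm0 <- cpm_matrix(counts_cond, nf)
  filter_low_expression(cpm0, counts_cond, threshold = threshold)
}

#' Run the full circadian splicing pipeline
#'
#' Executes normalization (TMM/CPM, mean-CPM filter), rhythm detection at
#' transcript and gene level per condition, local-event extraction, PSI and
#' spliced-gene sets per condition, gain/loss classification and
#' differential splicing for every knockout-versus-reference comparison,
#' within-gene differential rhythmicity of isoform pairs per condition, and
#' gene-set summaries. All stage tables are written to
#' `config$paths$out_dir` as TSV, together with a JSON run manifest and a
#' JSON summary of headline counts.
#'
#' @param config a [pipeline_config()] list (or YAML path).
#' @return (invisibly) a list with every stage result plus `summary`.
#' @export
run_pipeline <- function(config) {
  if (is.character(config)) config <- read_pipeline_config(config)
  config <- pipeline_config(config)
  par <- config$parameters
  out_dir <- config$paths$out_dir %||% "."
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)

  ann <- run_stage("annotation", {
    if (!is.null(config$data$annotation)) config$data$annotation
    else read_gtf(config$paths$annotation)
  })
  t2g <- annotation_tx2gene(ann)
  tpm <- run_stage("expression input", {
    if (!is.null(config$data$tpm)) config$data$tpm
    else read_expr_tsv(config$paths$tpm, config$paths$sample_sheet,
                       unit = "TPM")
  })
  counts <- run_stage("expression input", {
    if (!is.null(config$data$counts)) config$data$counts
    else read_expr_tsv(config$paths$counts, config$paths$sample_sheet,
                       unit = "counts")
  })
  conds <- unique(tpm$samples$condition)
  ref <- config$conditions$reference
  if (!ref %in% conds) stop("reference condition '", ref, "' not in data")
  comps <- config$conditions$comparisons %||% setdiff(conds, ref)

  message("circasplice: ", length(conds), " condition(s), reference ", ref)
  norm <- list(); rhy_tx <- list(); rhy_gene <- list(); discord <- list()
  psi <- list(); gsets <- list(); pairs <- list()
  for (cn in conds) {
    message("  [", cn, "] normalize + rhythm")
    cc <- condition_slice(counts, cn)
    norm[[cn]] <- run_stage(paste0("normalize:", cn),
                            normalize_condition(cc, par$cpm_threshold))
    rhy_tx[[cn]] <- run_stage(paste0("rhythm-transcript:", cn),
      detect_rhythmic(norm[[cn]]$cpm, period = par$period,
                      alpha_q = par$alpha_q, min_ramp = par$min_ramp,
                      method = par$method, n_perm = par$n_perm,
                      seed = par$seed, exact = "never"))
    gc <- summarize_to_gene(cc, t2g)
    gnorm <- run_stage(paste0("normalize-gene:", cn),
                       normalize_condition(gc, par$cpm_threshold))
    rhy_gene[[cn]] <- run_stage(paste0("rhythm-gene:", cn),
      detect_rhythmic(gnorm$cpm, period = par$period, alpha_q = par$alpha_q,
                      min_ramp = par$min_ramp, method = par$method,
                      n_perm = par$n_perm, seed = par$seed, exact = "never"))
    keep_tx <- rhy_tx[[cn]][
      t2g$gene_id[match(rhy_tx[[cn]]$feature_id, t2g$transcript_id)] %in%
        rhy_gene[[cn]]$feature_id, ]
    discord[[cn]] <- run_stage(paste0("discordance:", cn),
      gene_transcript_discordance(rhy_gene[[cn]], keep_tx, t2g))
  }

  events <- run_stage("events", extract_events(ann))
  for (cn in conds) {
    message("  [", cn, "] PSI")
    pt <- run_stage(paste0("psi:", cn),
                    psi_per_sample(events, condition_slice(tpm, cn)))
    psi[[cn]] <- flag_spliced(pt, par$psi_low, par$psi_high)
    gsets[[cn]] <- spliced_genes(psi[[cn]])
    pairs[[cn]] <- run_stage(paste0("diffrhythm:", cn),
      diff_rhythm_pairs(norm[[cn]]$cpm, rhy_tx[[cn]], t2g,
                        period = par$period, alpha_q = par$alpha_q,
                        min_shift = par$min_shift_h))
  }

  changes <- list(); dsplice <- list()
  circ_tx <- unique(unlist(lapply(rhy_tx, function(t)
    t$feature_id[t$rhythmic])))
  for (cn in comps) {
    message("  [", cn, " vs ", ref, "] gain/loss + differential splicing")
    changes[[cn]] <- run_stage(paste0("gain-loss:", cn),
      classify_gain_loss(gsets[[ref]], gsets[[cn]],
                         circadian_transcripts = circ_tx, tx2gene = t2g))
    dsplice[[cn]] <- run_stage(paste0("diff-splice:", cn),
      differential_splicing(psi[[ref]], psi[[cn]],
                            alpha = par$diffsplice_alpha))
  }

  sf_report <- NULL; hallmarks <- NULL
  if (!is.null(config$paths$gene_sets$splicing_factors)) {
    sf <- load_gene_sets(config$paths$gene_sets$splicing_factors)
    sf_report <- run_stage("sf-report",
      sf_rhythm_matrix(rhy_tx, unique(unlist(sf)), t2g, reference = ref))
  }
  if (!is.null(config$paths$gene_sets$hallmarks)) {
    hm <- load_gene_sets(config$paths$gene_sets$hallmarks)
    class_lists <- list()
    for (cn in conds)
      class_lists[[paste0("phase_shifted_", cn)]] <-
        unique(pairs[[cn]]$gene_id[pairs[[cn]]$shifted])
    for (cn in comps) {
      class_lists[[paste0("gain_", cn)]] <-
        changes[[cn]]$gene_id[changes[[cn]]$status == "gain"]
      class_lists[[paste0("loss_", cn)]] <-
        changes[[cn]]$gene_id[changes[[cn]]$status == "loss"]
    }
    hallmarks <- hallmark_association(class_lists, hm)
  }

  summary <- list(
    conditions = conds, reference = ref,
    n_rhythmic_transcripts = vapply(rhy_tx, function(t) sum(t$rhythmic), 0L),
    n_rhythmic_genes = vapply(rhy_gene, function(t) sum(t$rhythmic), 0L),
    discordance = lapply(discord, function(d) as.list(table(d$class))),
    gain_loss = lapply(changes, function(ch)
      lapply(split(ch$status, ch$event_type), function(s) as.list(table(s)))),
    n_spliced_genes = lapply(gsets, function(g)
      vapply(g$spliced, length, 0L)),
    pairs_per_phase_bin = lapply(pairs, function(p)
      as.list(table(p$phase_bin[p$shifted]))),
    n_pairs_tested = vapply(pairs, nrow, 0L))
  if (!is.null(sf_report))
    summary$sf_rhythmic_gene_counts <- as.list(sf_report$rhythmic_gene_counts)

  # write stage tables + manifest
  wt <- function(df, name) utils::write.table(
    df, file.path(out_dir, name), sep = "\t", quote = FALSE,
    row.names = FALSE, na = "NA")
  for (cn in conds) {
    wt(rhy_tx[[cn]], paste0("rhythm_transcripts_", cn, ".tsv"))
    wt(rhy_gene[[cn]], paste0("rhythm_genes_", cn, ".tsv"))
    wt(discord[[cn]], paste0("discordance_", cn, ".tsv"))
    write_psi_tsv(psi[[cn]], file.path(out_dir, paste0("psi_", cn, ".tsv")))
    wt(pairs[[cn]], paste0("isoform_pairs_", cn, ".tsv"))
  }
  write_ioe(events, file.path(out_dir, "events.ioe"))
  for (cn in comps) {
    wt(changes[[cn]], paste0("event_changes_", cn, "_vs_", ref, ".tsv"))
    wt(dsplice[[cn]], paste0("diff_splice_", cn, "_vs_", ref, ".tsv"))
  }
  if (!is.null(sf_report)) {
    wt(data.frame(gene_id = rownames(sf_report$matrix), sf_report$matrix,
                  check.names = FALSE), "sf_rhythm_matrix.tsv")
  }
  if (!is.null(hallmarks)) wt(hallmarks$memberships, "hallmark_memberships.tsv")
  manifest <- list(package = "circasplice",
                   version = as.character(utils::packageVersion("circasplice")),
                   parameters = par,
                   conditions = list(reference = ref, comparisons = comps),
                   paths = config$paths)
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  jsonlite::write_json(summary, file.path(out_dir, "summary.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(list(annotation = ann, events = events, normalized = norm,
                 rhythm_transcripts = rhy_tx, rhythm_genes = rhy_gene,
                 discordance = discord, psi = psi, spliced_gene_sets = gsets,
                 event_changes = changes, diff_splice = dsplice,
                 isoform_pairs = pairs, sf_report = sf_report,
                 hallmarks = hallmarks, summary = summary))
}
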