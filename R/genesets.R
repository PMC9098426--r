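#' Load gene-set collections
#'
#' Reads gene sets from GMT files (`set<TAB>description<TAB>gene...`) or
#' from two-column TSV files with header `set_name`, `genes` (gene ids
#' comma-joined). Duplicated genes within a set are collapsed with a
#' warning; an empty set is an error.
#'
#' @param paths character vector of file paths.
#' @param format `"auto"` (by extension), `"gmt"` or `"tsv"`.
#' @return named list of character vectors (one element per set).
#' @export
load_gene_sets <- function(paths, format = c("auto", "gmt", "tsv")) {
  format <- match.arg(format)
  out <- list()
  for (path in paths) {
    fmt <- if (format != "auto") format else
      if (grepl("\\.gmt$", path, ignore.case = TRUE)) "gmt" else "tsv"
    if (fmt == "gmt") {
      for (line in readLines(path)) {
        if (!nzchar(line)) next
        f <- strsplit(line, "\t", fixed = TRUE)[[1]]
        if (length(f) < 3) stop("malformed GMT line in ", path)
        out[[f[1]]] <- f[-(1:2)]
      }
    } else {
      df <- utils::read.delim(path, stringsAsFactors = FALSE)
      if (!all(c("set_name", "genes") %in% names(df)))
        stop("gene-set TSV needs columns set_name, genes: ", path)
      for (i in seq_len(nrow(df))) {
        g <- as.character(df$genes[i])
        if (is.na(g)) g <- ""
        out[[df$set_name[i]]] <- strsplit(g, ",", fixed = TRUE)[[1]]
      }
    }
  }
  for (nm in names(out)) {
    g <- out[[nm]][nzchar(out[[nm]])]
    if (!length(g)) stop("gene set '", nm, "' is empty")
    if (anyDuplicated(g)) {
      warning("duplicated gene ids collapsed in set '", nm, "'")
      g <- unique(g)
    }
    out[[nm]] <- g
  }
  if (!length(out)) stop("no gene sets loaded")
  out
}

#' Write a gene-set collection as TSV
#'
#' @param collection named list of character vectors.
#' @param path output path (columns `set_name`, `genes` comma-joined).
#' @return `path`, invisibly.
#' @export
write_gene_sets <- function(collection, path) {
  df <- data.frame(set_name = names(collection),
                   genes = vapply(collection, paste, "", collapse = ","))
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Categorical splicing-factor rhythmicity matrix across conditions
#'
#' For every splicing-factor gene expressed in the data, reports per
#' condition whether at least one of its transcripts is rhythmic, plus
#' per-condition counts and the set of SFs that are rhythmic in the
#' reference condition but in none of the others (rhythmicity lost in every
#' knockout).
#'
#' @param rhythm_tables named list (condition -> transcript rhythm table
#'   from [detect_rhythmic()]).
#' @param sf_genes character vector of splicing-factor gene ids.
#' @param tx2gene data.frame with `transcript_id`, `gene_id`.
#' @param reference reference condition label (default: first table).
#' @return list with `matrix` (logical, SF gene x condition),
#'   `rhythmic_gene_counts`, `rhythmic_transcript_counts`, `lost_in_all_ko`
#'   and `not_expressed` (SF genes absent from the data).
#' @export
sf_rhythm_matrix <- function(rhythm_tables, sf_genes, tx2gene,
                             reference = names(rhythm_tables)[1]) {
  stopifnot(length(names(rhythm_tables)) == length(rhythm_tables),
            reference %in% names(rhythm_tables))
  tx2gene <- as.data.frame(tx2gene)
  expressed <- unique(tx2gene$gene_id[
    tx2gene$transcript_id %in% rhythm_tables[[1]]$feature_id])
  sf_in <- sort(intersect(sf_genes, expressed))
  not_expressed <- sort(setdiff(sf_genes, expressed))
  conds <- names(rhythm_tables)
  m <- matrix(FALSE, length(sf_in), length(conds),
              dimnames = list(sf_in, conds))
  tx_counts <- stats::setNames(integer(length(conds)), conds)
  for (cn in conds) {
    tab <- rhythm_tables[[cn]]
    rtx <- tab$feature_id[tab$rhythmic %in% TRUE]
    gg <- tx2gene$gene_id[match(rtx, tx2gene$transcript_id)]
    m[, cn] <- sf_in %in% gg
    tx_counts[cn] <- sum(gg %in% sf_in)
  }
  ko <- setdiff(conds, reference)
  lost <- if (length(ko))
    rownames(m)[m[, reference] & rowSums(m[, ko, drop = FALSE]) == 0]
  else character()
  list(matrix = m, rhythmic_gene_counts = colSums(m),
       rhythmic_transcript_counts = tx_counts,
       lost_in_all_ko = lost, not_expressed = not_expressed)
}

#' Hypergeometric over-representation of gene sets
#'
#' Upper-tail hypergeometric probability P(X >= k) of observing `k` query
#' genes in a set of size `K` (restricted to the universe) when `n` genes
#' are drawn from a universe of size `N`; BH adjustment across sets.
#'
#' @param query character vector of genes of interest (must lie in
#'   `universe`).
#' @param universe character vector of background genes (e.g. all expressed
#'   genes after filtering).
#' @param collection named list of gene sets.
#' @return data.frame with `set_name`, `overlap`, `query_size`, `set_size`,
#'   `universe_size`, `p`, `q`.
#' @export
hypergeom_enrichment <- function(query, universe, collection) {
  query <- unique(query); universe <- unique(universe)
  off <- setdiff(query, universe)
  if (length(off))
    stop("query genes outside the universe: ",
         paste(utils::head(off, 5), collapse = ", "))
  N <- length(universe); n <- length(query)
  rows <- lapply(names(collection), function(nm) {
    set <- intersect(collection[[nm]], universe)
    K <- length(set)
    k <- length(intersect(query, set))
    p <- if (K == 0) 1 else
      stats::phyper(k - 1, K, N - K, n, lower.tail = FALSE)
    data.frame(set_name = nm, overlap = k, query_size = n, set_size = K,
               universe_size = N, p = p)
  })
  out <- do.call(rbind, rows)
  out$q <- stats::p.adjust(out$p, method = "BH")
  rownames(out) <- NULL
  out
}

#' Hallmark membership of result-class gene lists
#'
#' Joins each class of result genes (e.g. genes with phase-shifted isoform
#' pairs, gain/loss genes) against a hallmark collection; genes belonging to
#' no hallmark are omitted from the membership table.
#'
#' @param class_lists named list (class -> character vector of gene ids).
#' @param collection named list of hallmark gene sets.
#' @return list with `memberships` (data.frame `class`, `gene_id`,
#'   `set_name`) and `counts` (class x set integer matrix).
#' @export
hallmark_association <- function(class_lists, collection) {
  mem <- list()
  for (cl in names(class_lists)) for (nm in names(collection)) {
    hit <- intersect(unique(class_lists[[cl]]), collection[[nm]])
    if (length(hit))
      mem[[length(mem) + 1L]] <- data.frame(class = cl, gene_id = hit,
                                            set_name = nm)
  }
  memberships <- if (length(mem)) do.call(rbind, mem) else
    data.frame(class = character(), gene_id = character(),
               set_name = character())
  counts <- matrix(0L, length(class_lists), length(collection),
                   dimnames = list(names(class_lists), names(collection)))
  for (i in seq_len(nrow(memberships)))
    counts[memberships$class[i], memberships$set_name[i]] <-
      counts[memberships$class[i], memberships$set_name[i]] + 1L
  list(memberships = memberships, counts = counts)
}
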