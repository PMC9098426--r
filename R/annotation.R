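#' Transcript annotation container
#'
#' Holds the gene/transcript/exon models that local splicing events are
#' computed from. Exon intervals are stored 0-based half-open and sorted;
#' GTF input/output converts at the boundary.
#'
#' @param genes data.frame with columns `gene_id`, `chrom`, `strand`
#'   ("+"/"-").
#' @param transcripts data.frame with columns `transcript_id`, `gene_id` and
#'   optionally `biotype` (defaults to "unknown").
#' @param exons data.frame with columns `transcript_id`, `start`, `end`
#'   (0-based half-open).
#' @return An object of class `transcript_annotation`.
#' @export
transcript_annotation <- function(genes, transcripts, exons) {
  genes <- as.data.frame(genes); transcripts <- as.data.frame(transcripts)
  exons <- as.data.frame(exons)
  stopifnot(all(c("gene_id", "chrom", "strand") %in% names(genes)),
            all(c("transcript_id", "gene_id") %in% names(transcripts)),
            all(c("transcript_id", "start", "end") %in% names(exons)))
  if (!"biotype" %in% names(transcripts))
    transcripts$biotype <- rep("unknown", nrow(transcripts))
  if (!all(genes$strand %in% c("+", "-")))
    stop("gene strand must be '+' or '-'")
  if (anyDuplicated(genes$gene_id)) stop("duplicate gene ids")
  if (anyDuplicated(transcripts$transcript_id)) stop("duplicate transcript ids")
  if (!all(transcripts$gene_id %in% genes$gene_id))
    stop("transcript references unknown gene")
  if (!all(exons$transcript_id %in% transcripts$transcript_id))
    stop("exon references unknown transcript")
  if (any(exons$end <= exons$start))
    stop("exon with end <= start")
  exons <- exons[order(match(exons$transcript_id, transcripts$transcript_id),
                       exons$start), c("transcript_id", "start", "end")]
  rownames(exons) <- NULL
  # exons within a transcript must be disjoint
  by_tx <- split(exons, exons$transcript_id)
  for (tx in by_tx) {
    if (nrow(tx) > 1 && any(tx$start[-1] < tx$end[-nrow(tx)]))
      stop("overlapping exons in transcript ", tx$transcript_id[1])
  }
  structure(list(genes = genes[, c("gene_id", "chrom", "strand")],
                 transcripts = transcripts[, c("transcript_id", "gene_id",
                                               "biotype")],
                 exons = exons),
            class = "transcript_annotation")
}

#' @export
print.transcript_annotation <- function(x, ...) {
  cat(sprintf("transcript_annotation: %d genes, %d transcripts, %d exons\n",
              nrow(x$genes), nrow(x$transcripts), nrow(x$exons)))
  invisible(x)
}

#' Transcript-to-gene map of an annotation
#'
#' @param annotation a [transcript_annotation()].
#' @return data.frame with `transcript_id`, `gene_id`, `biotype`.
#' @export
annotation_tx2gene <- function(annotation) {
  stopifnot(inherits(annotation, "transcript_annotation"))
  annotation$transcripts
}

#' Transcript effective lengths (summed exon length)
#'
#' @param annotation a [transcript_annotation()].
#' @return named numeric vector of summed exon lengths per transcript.
#' @export
transcript_lengths <- function(annotation) {
  stopifnot(inherits(annotation, "transcript_annotation"))
  len <- rowsum(annotation$exons$end - annotation$exons$start,
                group = annotation$exons$transcript_id, reorder = FALSE)
  stats::setNames(as.numeric(len), rownames(len))
}

#' Read transcript annotation from GTF
#'
#' Imports exon features (other feature types are ignored), converting
#' 1-based inclusive GTF coordinates to the package's 0-based half-open
#' convention. Missing `transcript_biotype` attributes default to "unknown".
#'
#' @param path a GTF file.
#' @return A [transcript_annotation()].
#' @export
read_gtf <- function(path) {
  gr <- rtracklayer::import(path, format = "gtf")
  md <- S4Vectors::mcols(gr)
  keep <- !is.na(md$type) & md$type == "exon"
  gr <- gr[keep]; md <- md[keep, , drop = FALSE]
  if (length(gr) == 0) {
    warning("no exon features in ", path, "; returning empty annotation")
    return(transcript_annotation(
      data.frame(gene_id = character(), chrom = character(),
                 strand = character()),
      data.frame(transcript_id = character(), gene_id = character()),
      data.frame(transcript_id = character(), start = integer(),
                 end = integer())))
  }
  gid <- as.character(md$gene_id)
  tid <- as.character(md$transcript_id)
  bad <- which(is.na(gid) | is.na(tid) | gid == "" | tid == "")
  if (length(bad))
    stop("exon feature(s) missing gene_id/transcript_id attribute at record ",
         paste(utils::head(bad, 5), collapse = ", "))
  biotype <- if ("transcript_biotype" %in% names(md))
    as.character(md$transcript_biotype) else rep(NA_character_, length(gr))
  biotype[is.na(biotype)] <- "unknown"
  exons <- data.frame(transcript_id = tid,
                      start = GenomicRanges::start(gr) - 1L,
                      end = GenomicRanges::end(gr))
  tx <- unique(data.frame(transcript_id = tid, gene_id = gid,
                          biotype = biotype))
  if (anyDuplicated(tx$transcript_id))
    stop("transcript with inconsistent gene_id/biotype attributes")
  ge <- unique(data.frame(gene_id = gid,
                          chrom = as.character(GenomicRanges::seqnames(gr)),
                          strand = as.character(GenomicRanges::strand(gr))))
  if (anyDuplicated(ge$gene_id))
    stop("gene with inconsistent chrom/strand across exons")
  transcript_annotation(ge, tx, exons)
}

#' Write transcript annotation to GTF
#'
#' Emits exon features only, with `gene_id`, `transcript_id` and
#' `transcript_biotype` attributes; internal 0-based half-open coordinates
#' are converted back to 1-based inclusive.
#'
#' @param annotation a [transcript_annotation()].
#' @param path output GTF path.
#' @return `path`, invisibly.
#' @export
write_gtf <- function(annotation, path) {
  stopifnot(inherits(annotation, "transcript_annotation"))
  ex <- annotation$exons
  tx <- annotation$transcripts[match(ex$transcript_id,
                                     annotation$transcripts$transcript_id), ]
  ge <- annotation$genes[match(tx$gene_id, annotation$genes$gene_id), ]
  if (nrow(ex) == 0) {
    writeLines(character(), path)
    return(invisible(path))
  }
  gr <- GenomicRanges::GRanges(
    seqnames = ge$chrom,
    ranges = IRanges::IRanges(start = ex$start + 1L, end = ex$end),
    strand = ge$strand)
  S4Vectors::mcols(gr) <- S4Vectors::DataFrame(
    source = "circasplice", type = "exon",
    gene_id = tx$gene_id, transcript_id = ex$transcript_id,
    transcript_biotype = tx$biotype)
  rtracklayer::export(gr, path, format = "gtf")
  invisible(path)
}
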