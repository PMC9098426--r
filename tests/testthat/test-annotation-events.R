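test_that("GTF round trip preserves the annotation and its conventions", {
  ann <- generate_annotation(n_genes_per_type = 2, seed = 3)
  path <- tempfile(fileext = ".gtf")
  write_gtf(ann, path)
  back <- read_gtf(path)
  # compare content irrespective of row order
  ord <- function(a) {
    a$genes <- a$genes[order(a$genes$gene_id), ]
    a$transcripts <- a$transcripts[order(a$transcripts$transcript_id), ]
    a$exons <- a$exons[order(a$exons$transcript_id, a$exons$start), ]
    lapply(a, function(d) { rownames(d) <- NULL; d })
  }
  expect_equal(ord(unclass(back)), ord(unclass(ann)))
})

test_that("GTF coordinates convert 1-based inclusive to 0-based half-open", {
  path <- tempfile(fileext = ".gtf")
  writeLines(paste("chr1", "src", "exon", "101", "200", ".", "+", ".",
                   'gene_id "G1"; transcript_id "T1";', sep = "\t"), path)
  ann <- read_gtf(path)
  expect_equal(ann$exons$start, 100)
  expect_equal(ann$exons$end, 200)
  expect_equal(ann$transcripts$biotype, "unknown")
  # zero exon features -> empty annotation with a warning
  writeLines(paste("chr1", "src", "gene", "1", "500", ".", "+", ".",
                   'gene_id "G1";', sep = "\t"), path)
  expect_warning(empty <- read_gtf(path), "no exon features")
  expect_equal(nrow(empty$genes), 0)
})

test_that("event extraction matches the exhaustive pairwise oracle", {
  # 50+ random multi-isoform genes covering all 7 modes, both strands
  ann <- generate_annotation(n_genes_per_type = 8, seed = 7)
  got <- extract_events(ann)
  want <- oracle_events(ann)
  expect_gte(nrow(got), 56)
  expect_setequal(got$event_id, want$event_id)
  m <- match(got$event_id, want$event_id)
  expect_identical(got$inclusion_transcripts, want$inclusion_transcripts[m])
  expect_identical(got$total_transcripts, want$total_transcripts[m])
  expect_true(all(table(got$event_type) >= 8))
})

test_that("three-transcript genes union supporters per coordinate signature", {
  # e1-e2-e3, e1-e3, and e1-e2-e3 with a longer e3 share the same SE intron
  ann <- transcript_annotation(
    genes = data.frame(gene_id = "G", chrom = "chr1", strand = "+"),
    transcripts = data.frame(transcript_id = c("T1", "T2", "T3"),
                             gene_id = "G"),
    exons = data.frame(
      transcript_id = c("T1", "T1", "T1", "T2", "T2", "T3", "T3", "T3"),
      start = c(0, 200, 400, 0, 400, 0, 200, 400),
      end = c(100, 300, 500, 100, 500, 100, 300, 600)))
  ev <- extract_events(ann)
  se <- ev[ev$event_type == "SE", ]
  expect_equal(nrow(se), 1L)
  expect_identical(se$inclusion_transcripts, "T1,T3")
  expect_identical(se$total_transcripts, "T1,T2,T3")
  keep <- c("event_id", "inclusion_transcripts", "total_transcripts")
  expect_equal(extract_events(ann)[, keep], oracle_events(ann)[, keep],
               ignore_attr = TRUE)
})

test_that("extraction is invariant to transcript order and strand-aware", {
  ann <- generate_annotation(n_genes_per_type = 3, seed = 9)
  perm <- sample(nrow(ann$transcripts))
  ann2 <- transcript_annotation(ann$genes, ann$transcripts[perm, ],
                                ann$exons)
  expect_identical(extract_events(ann), extract_events(ann2))
  # mirroring coordinates and flipping strand preserves A5/AF labels
  # (definitions follow transcription direction, not genomic left/right)
  for (type in c("A5", "A3", "AF", "AL")) {
    ann <- generate_annotation(type, 1, seed = 4)
    hi <- max(ann$exons$end) + 10
    mirrored <- transcript_annotation(
      transform(ann$genes, strand = ifelse(strand == "+", "-", "+")),
      ann$transcripts,
      data.frame(transcript_id = ann$exons$transcript_id,
                 start = hi - ann$exons$end, end = hi - ann$exons$start))
    expect_identical(extract_events(mirrored)$event_type, type)
  }
})

test_that("single-transcript genes yield no events", {
  ann <- transcript_annotation(
    genes = data.frame(gene_id = "G", chrom = "chr1", strand = "+"),
    transcripts = data.frame(transcript_id = "T1", gene_id = "G"),
    exons = data.frame(transcript_id = "T1", start = 0, end = 100))
  expect_equal(nrow(extract_events(ann)), 0L)
})

test_that("ioe files round-trip and validate the subset invariant", {
  ann <- generate_annotation(n_genes_per_type = 2, seed = 6)
  ev <- extract_events(ann)
  path <- tempfile(fileext = ".ioe")
  write_ioe(ev, path)
  back <- read_ioe(path)
  expect_equal(back, ev[, colnames(back)])
  # header-only file for an empty event list
  write_ioe(ev[0, ], path)
  expect_equal(length(readLines(path)), 1L)
  expect_equal(nrow(read_ioe(path)), 0L)
  # inclusion not a proper subset -> error
  bad <- ev[1, ]
  bad$inclusion_transcripts <- bad$total_transcripts
  write_ioe(bad, path)
  expect_error(read_ioe(path), "proper subset")
})
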