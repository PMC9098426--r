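#' Enumerate local alternative-splicing events from an annotation
#'
#' Scans every gene's transcript structures for the seven local event modes:
#' alternative 3'/5' splice site (A3/A5), alternative first/last exon
#' (AF/AL), mutually exclusive exons (MX), retained intron (RI) and skipped
#' exon (SE). Events are defined from exon/junction coordinate signatures
#' with strict boundary matching, so more than two transcripts can support
#' one event; A3/A5/AF/AL semantics follow the direction of transcription
#' (a shared genomic-left intron boundary is a shared donor on "+" but a
#' shared acceptor on "-").
#'
#' Inclusion-form conventions: SE, the exon-inclusion form; RI, the
#' intron-retained form; A5/A3, the form with the longer exonic extension
#' (shorter intron); MX, the form using the transcription-direction upstream
#' internal exon; AF/AL, the form whose alternative terminal exon lies more
#' distal from the shared exon.
#'
#' @param annotation a [transcript_annotation()].
#' @return data.frame with columns `event_id`, `event_type`, `gene_id`,
#'   `chrom`, `strand`, `inclusion_transcripts`, `total_transcripts`
#'   (transcript sets sorted and comma-joined), ordered by gene and event id.
#' @export
extract_events <- function(annotation) {
  stopifnot(inherits(annotation, "transcript_annotation"))
  out <- list()
  for (gi in seq_len(nrow(annotation$genes))) {
    g <- annotation$genes[gi, ]
    tx_ids <- annotation$transcripts$transcript_id[
      annotation$transcripts$gene_id == g$gene_id]
    if (length(tx_ids) < 2) next
    chains <- lapply(tx_ids, function(t) {
      e <- annotation$exons[annotation$exons$transcript_id == t, , drop = FALSE]
      m <- as.matrix(e[order(e$start), c("start", "end")])
      storage.mode(m) <- "integer"
      m
    })
    names(chains) <- tx_ids
    out[[length(out) + 1L]] <-
      gene_local_events(g$gene_id, g$chrom, g$strand, chains)
  }
  ev <- do.call(rbind, out)
  if (is.null(ev))
    ev <- data.frame(event_id = character(), event_type = character(),
                     gene_id = character(), chrom = character(),
                     strand = character(),
                     inclusion_transcripts = character(),
                     total_transcripts = character())
  ev <- unique(ev)
  ev[order(ev$gene_id, ev$event_id), , drop = FALSE] -> ev
  rownames(ev) <- NULL
  ev
}

# event table row constructor; transcript sets are sorted + comma-joined
event_row <- function(gene_id, chrom, strand, type, coords, incl, total) {
  incl <- sort(unique(incl)); total <- sort(unique(total))
  data.frame(
    event_id = paste0(gene_id, ";", type, ":", chrom, ":", coords, ":", strand),
    event_type = type, gene_id = gene_id, chrom = chrom, strand = strand,
    inclusion_transcripts = paste(incl, collapse = ","),
    total_transcripts = paste(total, collapse = ","))
}

# all events of one gene; chains = named list of sorted exon matrices
gene_local_events <- function(gene_id, chrom, strand, chains) {
  tx_ids <- names(chains)
  introns <- lapply(chains, function(m) {
    if (nrow(m) < 2) matrix(numeric(0), 0, 2) else
      cbind(m[-nrow(m), 2], m[-1, 1])
  })
  ikey <- function(a, b) paste(a, b, sep = "-")
  # transcripts holding each intron / each exact exon
  tx_by_intron <- list(); tx_by_exon <- list()
  for (t in tx_ids) {
    im <- introns[[t]]
    for (r in seq_len(nrow(im))) {
      k <- ikey(im[r, 1], im[r, 2])
      tx_by_intron[[k]] <- c(tx_by_intron[[k]], t)
    }
    em <- chains[[t]]
    for (r in seq_len(nrow(em))) {
      k <- ikey(em[r, 1], em[r, 2])
      tx_by_exon[[k]] <- c(tx_by_exon[[k]], t)
    }
  }
  rows <- list()
  add <- function(row) rows[[length(rows) + 1L]] <<- row

  ## SE and MX: consecutive intron pairs (a,b),(c,d) with middle exon [b,c)
  pair_df <- do.call(rbind, lapply(tx_ids, function(t) {
    im <- introns[[t]]
    if (nrow(im) < 2) return(NULL)
    data.frame(tx = t, a = im[-nrow(im), 1], b = im[-nrow(im), 2],
               c = im[-1, 1], d = im[-1, 2])
  }))
  if (!is.null(pair_df)) {
    sig <- paste(pair_df$a, pair_df$b, pair_df$c, pair_df$d)
    for (s in unique(sig)) {
      p <- pair_df[sig == s, ][1, ]
      incl <- unique(pair_df$tx[sig == s])
      skip <- tx_by_intron[[ikey(p$a, p$d)]]
      if (!is.null(skip))
        add(event_row(gene_id, chrom, strand, "SE",
                      sprintf("%d-%d:%d-%d", p$a, p$b, p$c, p$d),
                      incl, c(incl, skip)))
    }
    # MX: two pairs sharing outer boundaries (a, d), non-overlapping middles
    outer <- paste(pair_df$a, pair_df$d)
    for (o in unique(outer)) {
      sub <- pair_df[outer == o, ]
      mids <- unique(sub[, c("b", "c")])
      if (nrow(mids) < 2) next
      mids <- mids[order(mids$b, mids$c), ]
      for (i in seq_len(nrow(mids) - 1)) for (j in (i + 1):nrow(mids)) {
        m1 <- mids[i, ]; m2 <- mids[j, ]          # m1 genomically left
        if (m1$c > m2$b) next                      # overlapping middles
        t1 <- unique(sub$tx[sub$b == m1$b & sub$c == m1$c])
        t2 <- unique(sub$tx[sub$b == m2$b & sub$c == m2$c])
        incl <- if (strand == "+") t1 else t2      # upstream internal exon
        add(event_row(gene_id, chrom, strand, "MX",
                      sprintf("%d-%d:%d-%d:%d-%d:%d-%d",
                              sub$a[1], m1$b, m1$c, sub$d[1],
                              sub$a[1], m2$b, m2$c, sub$d[1]),
                      incl, c(t1, t2)))
      }
    }
  }

  ## RI: consecutive exon pair [s,a),[b,e) vs single exon [s,e)
  flank_df <- do.call(rbind, lapply(tx_ids, function(t) {
    m <- chains[[t]]
    if (nrow(m) < 2) return(NULL)
    data.frame(tx = t, s = m[-nrow(m), 1], a = m[-nrow(m), 2],
               b = m[-1, 1], e = m[-1, 2])
  }))
  if (!is.null(flank_df)) {
    sig <- paste(flank_df$s, flank_df$a, flank_df$b, flank_df$e)
    for (s in unique(sig)) {
      p <- flank_df[sig == s, ][1, ]
      spliced <- unique(flank_df$tx[sig == s])
      retained <- tx_by_exon[[ikey(p$s, p$e)]]
      if (!is.null(retained))
        add(event_row(gene_id, chrom, strand, "RI",
                      sprintf("%d:%d-%d:%d", p$s, p$a, p$b, p$e),
                      retained, c(retained, spliced)))
    }
  }

  ## A5/A3/AF/AL: introns sharing exactly one boundary
  all_introns <- do.call(rbind, lapply(tx_ids, function(t) {
    im <- introns[[t]]
    if (!nrow(im)) return(NULL)
    m <- chains[[t]]
    # flanking exon extents and terminal flags for each intron
    data.frame(tx = t, a = im[, 1], b = im[, 2],
               ls = m[-nrow(m), 1],                  # left-flank exon start
               re = m[-1, 2],                        # right-flank exon end
               l_first = seq_len(nrow(im)) == 1,     # left flank is leftmost
               r_last = seq_len(nrow(im)) == nrow(im))
  }))
  if (!is.null(all_introns)) {
    # shared right boundary, variable left (donor on +, acceptor on -)
    for (aa in unique(all_introns$b)) {
      grp <- all_introns[all_introns$b == aa, ]
      ds <- sort(unique(grp$a))
      if (length(ds) < 2) next
      for (i in seq_len(length(ds) - 1)) for (j in (i + 1):length(ds)) {
        d1 <- ds[i]; d2 <- ds[j]                    # d1 < d2: longer intron d1
        g1 <- grp[grp$a == d1, ]; g2 <- grp[grp$a == d2, ]
        splice <- FALSE; term <- FALSE
        for (x in seq_len(nrow(g1))) for (y in seq_len(nrow(g2))) {
          if (g2$ls[y] < d1) splice <- TRUE         # flank exons overlap
          else if (g1$l_first[x] && g2$l_first[y]) term <- TRUE
        }
        coords <- sprintf("%d-%d:%d-%d", d1, aa, d2, aa)
        t1 <- unique(g1$tx); t2 <- unique(g2$tx)
        if (splice)
          add(event_row(gene_id, chrom, strand,
                        if (strand == "+") "A5" else "A3",
                        coords, t2, c(t1, t2)))     # shorter intron included
        if (term)
          add(event_row(gene_id, chrom, strand,
                        if (strand == "+") "AF" else "AL",
                        coords, t1, c(t1, t2)))     # distal terminal included
      }
    }
    # shared left boundary, variable right (acceptor on +, donor on -)
    for (dd in unique(all_introns$a)) {
      grp <- all_introns[all_introns$a == dd, ]
      as_ <- sort(unique(grp$b))
      if (length(as_) < 2) next
      for (i in seq_len(length(as_) - 1)) for (j in (i + 1):length(as_)) {
        a1 <- as_[i]; a2 <- as_[j]                  # a1 < a2: shorter intron a1
        g1 <- grp[grp$b == a1, ]; g2 <- grp[grp$b == a2, ]
        splice <- FALSE; term <- FALSE
        for (x in seq_len(nrow(g1))) for (y in seq_len(nrow(g2))) {
          if (a2 < g1$re[x]) splice <- TRUE
          else if (g1$r_last[x] && g2$r_last[y]) term <- TRUE
        }
        coords <- sprintf("%d-%d:%d-%d", dd, a1, dd, a2)
        t1 <- unique(g1$tx); t2 <- unique(g2$tx)
        if (splice)
          add(event_row(gene_id, chrom, strand,
                        if (strand == "+") "A3" else "A5",
                        coords, t1, c(t1, t2)))
        if (term)
          add(event_row(gene_id, chrom, strand,
                        if (strand == "+") "AL" else "AF",
                        coords, t2, c(t1, t2)))
      }
    }
  }
  if (!length(rows)) return(NULL)
  do.call(rbind, rows)
}

#' Split a comma-joined transcript set column
#'
#' @param x character vector of comma-joined transcript ids.
#' @return list of character vectors.
#' @export
split_tx_set <- function(x) strsplit(x, ",", fixed = TRUE)

#' Write / read SUPPA-style event tables (.ioe)
#'
#' Tab-separated interchange with columns `seqname`, `gene_id`, `event_id`,
#' `inclusion_transcripts`, `total_transcripts` (comma-joined sets).
#' Reading validates that every inclusion set is a proper subset of its
#' total set.
#'
#' @param events event data.frame from [extract_events()].
#' @param path file path.
#' @return `path` invisibly (write); the event data.frame (read).
#' @export
write_ioe <- function(events, path) {
  df <- data.frame(seqname = events$chrom, gene_id = events$gene_id,
                   event_id = events$event_id,
                   inclusion_transcripts = events$inclusion_transcripts,
                   total_transcripts = events$total_transcripts)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_ioe
#' @export
read_ioe <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE,
                          colClasses = "character")
  need <- c("seqname", "gene_id", "event_id", "inclusion_transcripts",
            "total_transcripts")
  miss <- setdiff(need, names(df))
  if (length(miss)) stop("ioe file missing columns: ",
                         paste(miss, collapse = ", "))
  inc <- split_tx_set(df$inclusion_transcripts)
  tot <- split_tx_set(df$total_transcripts)
  bad <- which(!mapply(function(i, t) all(i %in% t) && length(i) < length(t),
                       inc, tot))
  if (length(bad))
    stop("inclusion set not a proper subset of total set for event(s): ",
         paste(utils::head(df$event_id[bad], 5), collapse = ", "))
  # reconstruct event_type/strand from the id: gene;TYPE:chrom:...:strand
  rest <- sub("^[^;]*;", "", df$event_id)
  data.frame(event_id = df$event_id,
             event_type = sub(":.*$", "", rest),
             gene_id = df$gene_id, chrom = df$seqname,
             strand = sub("^.*:", "", rest),
             inclusion_transcripts = df$inclusion_transcripts,
             total_transcripts = df$total_transcripts)
}
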