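# Independent reference implementations used to validate the package's
# computational paths. Each oracle is written from the definition, on a
# different code path from the implementation it checks.

make_sheet <- function(times, condition = "WT") {
  data.frame(sample_id = sprintf("%s_s%02d", condition, seq_along(times)),
             condition = condition, time_h = times, replicate = 1L)
}

make_expr <- function(values, times, condition = "WT", unit = "CPM") {
  sheet <- make_sheet(times, condition)
  if (is.null(colnames(values))) colnames(values) <- sheet$sample_id
  else sheet$sample_id <- colnames(values)
  if (is.null(rownames(values)))
    rownames(values) <- sprintf("f%04d", seq_len(nrow(values)))
  expr_matrix(values, sheet, unit = unit)
}

## ---- brute-force local-event oracle ---------------------------------------
# Pairwise exhaustive pattern matcher: every ordered transcript pair of a
# gene is tested against the seven event definitions directly on the two
# exon chains; events are then unioned by identifier.

oracle_introns <- function(ex) {
  if (nrow(ex) < 2) return(matrix(numeric(0), 0, 2))
  cbind(ex[-nrow(ex), 2], ex[-1, 1])
}

# events supported by ordered pair (X = chain x, Y = chain y); returns rows
# (type, coords, incl_tx, excl_tx)
oracle_pair <- function(gene, chrom, strand, tx_x, ex_x, tx_y, ex_y) {
  ix <- oracle_introns(ex_x); iy <- oracle_introns(ex_y)
  rows <- list()
  put <- function(type, coords, incl, excl)
    rows[[length(rows) + 1L]] <<- data.frame(type = type, coords = coords,
                                             incl = incl, excl = excl)
  has_intron <- function(im, a, b)
    any(im[, 1] == a & im[, 2] == b)
  has_exon <- function(em, s, e) any(em[, 1] == s & em[, 2] == e)
  # SE: X carries the exon, Y skips it
  if (nrow(ix) >= 2) for (r in seq_len(nrow(ix) - 1)) {
    a <- ix[r, 1]; b <- ix[r, 2]; cc <- ix[r + 1, 1]; d <- ix[r + 1, 2]
    if (has_intron(iy, a, d))
      put("SE", sprintf("%d-%d:%d-%d", a, b, cc, d), tx_x, tx_y)
  }
  # RI: X spliced (consecutive exons), Y retains
  if (nrow(ex_x) >= 2) for (r in seq_len(nrow(ex_x) - 1)) {
    s <- ex_x[r, 1]; a <- ex_x[r, 2]; b <- ex_x[r + 1, 1]; e <- ex_x[r + 1, 2]
    if (has_exon(ex_y, s, e))
      put("RI", sprintf("%d:%d-%d:%d", s, a, b, e), tx_y, tx_x)
  }
  # MX: consecutive intron pairs sharing outer boundaries, disjoint middles
  if (nrow(ix) >= 2 && nrow(iy) >= 2)
    for (r in seq_len(nrow(ix) - 1)) for (r2 in seq_len(nrow(iy) - 1)) {
      if (ix[r, 1] != iy[r2, 1] || ix[r + 1, 2] != iy[r2 + 1, 2]) next
      m1 <- c(ix[r, 2], ix[r + 1, 1]); m2 <- c(iy[r2, 2], iy[r2 + 1, 1])
      if (m1[1] == m2[1] && m1[2] == m2[2]) next
      lo <- if (m1[1] < m2[1]) m1 else m2; hi <- if (m1[1] < m2[1]) m2 else m1
      if (lo[2] > hi[1]) next                       # overlapping middles
      coords <- sprintf("%d-%d:%d-%d:%d-%d:%d-%d", ix[r, 1], lo[1], lo[2],
                        ix[r + 1, 2], ix[r, 1], hi[1], hi[2], ix[r + 1, 2])
      # inclusion = transcription-direction upstream middle exon form
      incl <- if ((strand == "+") == (m1[1] < m2[1])) tx_x else tx_y
      excl <- if (incl == tx_x) tx_y else tx_x
      put("MX", coords, incl, excl)
    }
  # splice-site / terminal events: introns sharing one boundary
  for (r in seq_len(nrow(ix))) for (r2 in seq_len(nrow(iy))) {
    a1 <- ix[r, 1]; b1 <- ix[r, 2]; a2 <- iy[r2, 1]; b2 <- iy[r2, 2]
    if (b1 == b2 && a1 != a2) {                     # shared right end
      dl <- min(a1, a2); dh <- max(a1, a2)
      tx_l <- if (a1 < a2) tx_x else tx_y          # longer-intron form
      tx_s <- if (a1 < a2) tx_y else tx_x
      # flank exon = exon immediately left of intron r / r2
      fx <- ex_x[r, ]; fy <- ex_y[r2, ]
      flank_short <- if (a1 < a2) fy else fx
      coords <- sprintf("%d-%d:%d-%d", dl, b1, dh, b1)
      if (flank_short[1] < dl) {                    # overlapping flanks
        put(if (strand == "+") "A5" else "A3", coords, tx_s, tx_l)
      } else if ((if (a1 < a2) r == 1 else r2 == 1) &&
                 (if (a1 < a2) r2 == 1 else r == 1)) {
        put(if (strand == "+") "AF" else "AL", coords, tx_l, tx_s)
      }
    }
    if (a1 == a2 && b1 != b2) {                     # shared left end
      bl <- min(b1, b2); bh <- max(b1, b2)
      tx_s <- if (b1 < b2) tx_x else tx_y          # shorter-intron form
      tx_l <- if (b1 < b2) tx_y else tx_x
      fx <- ex_x[r + 1, ]; fy <- ex_y[r2 + 1, ]    # right flanks
      flank_short <- if (b1 < b2) fx else fy
      coords <- sprintf("%d-%d:%d-%d", a1, bl, a1, bh)
      if (bh < flank_short[2]) {
        put(if (strand == "+") "A3" else "A5", coords, tx_s, tx_l)
      } else if ((if (b1 < b2) r == nrow(ix) else r2 == nrow(iy)) &&
                 (if (b1 < b2) r2 == nrow(iy) else r == nrow(ix))) {
        put(if (strand == "+") "AL" else "AF", coords, tx_l, tx_s)
      }
    }
  }
  if (!length(rows)) return(NULL)
  do.call(rbind, rows)
}

oracle_events <- function(annotation) {
  out <- list()
  for (gi in seq_len(nrow(annotation$genes))) {
    g <- annotation$genes[gi, ]
    tx <- annotation$transcripts$transcript_id[
      annotation$transcripts$gene_id == g$gene_id]
    chains <- lapply(tx, function(t) {
      e <- annotation$exons[annotation$exons$transcript_id == t, ]
      m <- as.matrix(e[order(e$start), c("start", "end")])
      storage.mode(m) <- "integer"; m
    })
    names(chains) <- tx
    if (length(tx) < 2) next
    recs <- list()
    for (i in seq_along(tx)) for (j in seq_along(tx)) {
      if (i == j) next
      r <- oracle_pair(g$gene_id, g$chrom, g$strand, tx[i], chains[[i]],
                       tx[j], chains[[j]])
      if (!is.null(r)) recs[[length(recs) + 1L]] <- r
    }
    if (!length(recs)) next
    recs <- do.call(rbind, recs)
    key <- paste(recs$type, recs$coords)
    for (kk in unique(key)) {
      sub <- recs[key == kk, ]
      incl <- sort(unique(sub$incl))
      total <- sort(unique(c(sub$incl, sub$excl)))
      out[[length(out) + 1L]] <- data.frame(
        event_id = paste0(g$gene_id, ";", sub$type[1], ":", g$chrom, ":",
                          sub$coords[1], ":", g$strand),
        event_type = sub$type[1], gene_id = g$gene_id,
        inclusion_transcripts = paste(incl, collapse = ","),
        total_transcripts = paste(total, collapse = ","))
    }
  }
  if (!length(out))
    return(data.frame(event_id = character(), event_type = character(),
                      gene_id = character(),
                      inclusion_transcripts = character(),
                      total_transcripts = character()))
  res <- unique(do.call(rbind, out))
  res[order(res$gene_id, res$event_id), ]
}

## ---- umbrella rank statistic oracle ---------------------------------------
# Direct-from-definition Mack-Wolfe umbrella statistic, maximized over
# circular peak placements, with explicit pair counting.

oracle_umbrella_stat <- function(x, g) {
  k <- max(g)
  sizes <- tabulate(g, k)
  # pairwise Mann-Whitney counts by explicit loops
  U <- matrix(0, k, k)
  for (i in 1:k) for (j in 1:k) {
    xi <- x[g == i]; xj <- x[g == j]
    for (a in xi) for (b in xj)
      U[i, j] <- U[i, j] + (a < b) + 0.5 * (a == b)
  }
  N <- sum(sizes)
  best <- -Inf
  for (p in 1:k) {
    o <- ((p - 1 + ceiling(k / 2) + 0:(k - 1)) %% k) + 1
    q <- floor(k / 2) + 1
    A <- 0
    for (m in 1:(k - 1)) for (m2 in (m + 1):k) {
      if (m2 <= q) A <- A + U[o[m], o[m2]]
      if (m >= q) A <- A + U[o[m2], o[m]]
    }
    n_o <- sizes[o]; N1 <- sum(n_o[1:q]); N2 <- sum(n_o[q:k]); np <- n_o[q]
    E <- (N1^2 + N2^2 - sum(sizes^2) - np^2) / 4
    V <- (2 * (N1^3 + N2^3) + 3 * (N1^2 + N2^2) -
            sum(sizes^2 * (2 * sizes + 3)) - np^2 * (2 * np + 3) +
            12 * np * N1 * N2 - 12 * np^2 * N) / 72
    best <- max(best, (A - E) / sqrt(max(V, 1e-12)))
  }
  best
}

# exhaustive permutation p-value by recursive enumeration of permutations
oracle_perms <- function(n) {
  if (n == 1) return(list(1L))
  res <- list()
  for (sub in oracle_perms(n - 1L)) for (pos in 0:(n - 1L))
    res[[length(res) + 1L]] <- append(sub, n, after = pos)
  res
}

oracle_umbrella_exact_p <- function(x, times, period) {
  ph <- round(times %% period, 9)
  g <- match(ph, sort(unique(ph)))
  obs <- oracle_umbrella_stat(x, g)
  stats <- vapply(oracle_perms(length(x)),
                  function(p) oracle_umbrella_stat(x[p], g), 0)
  mean(stats >= obs - 1e-9)
}

## ---- Mann-Whitney exact oracle --------------------------------------------
# Direct pair counting and enumeration over all label assignments.

oracle_mw_u <- function(x, y) {
  u <- 0
  for (a in x) for (b in y) u <- u + (a > b) + 0.5 * (a == b)
  u
}

oracle_mw_exact_p <- function(x, y) {
  n1 <- length(x); pooled <- c(x, y); N <- length(pooled)
  mu <- n1 * length(y) / 2
  obs <- abs(oracle_mw_u(x, y) - mu)
  sel <- utils::combn(N, n1)
  hits <- 0
  for (j in seq_len(ncol(sel))) {
    u <- oracle_mw_u(pooled[sel[, j]], pooled[-sel[, j]])
    if (abs(u - mu) >= obs - 1e-9) hits <- hits + 1
  }
  hits / ncol(sel)
}

## ---- TMM step-by-step oracle ----------------------------------------------
# Published trimmed-mean-of-M-values recipe: M/A over doubly-positive
# features, 30% / 5% two-sided rank trims, inverse asymptotic-variance
# weights, factors rescaled to geometric mean 1.

oracle_tmm <- function(counts, ref) {
  lib <- colSums(counts)
  f <- vapply(seq_len(ncol(counts)), function(k) {
    ok <- counts[, k] > 0 & counts[, ref] > 0
    yk <- counts[ok, k]; yr <- counts[ok, ref]
    M <- log2((yk / lib[k]) / (yr / lib[ref]))
    A <- 0.5 * log2((yk / lib[k]) * (yr / lib[ref]))
    w <- (lib[k] - yk) / (lib[k] * yk) + (lib[ref] - yr) / (lib[ref] * yr)
    n <- length(M)
    loM <- floor(n * 0.3) + 1; hiM <- n + 1 - loM
    loA <- floor(n * 0.05) + 1; hiA <- n + 1 - loA
    keep <- rank(M) >= loM & rank(M) <= hiM & rank(A) >= loA & rank(A) <= hiA
    fk <- 2^(sum(M[keep] / w[keep]) / sum(1 / w[keep]))
    if (!is.finite(fk) || fk == 0) fk <- 1
    fk
  }, 0)
  f <- f / exp(mean(log(f)))
  names(f) <- colnames(counts)
  f
}

## ---- grid/optimizer cosinor oracle ----------------------------------------
# Profile least squares: for a candidate acrophase the mesor/amplitude are
# fitted linearly; the acrophase minimizing RSS is found by grid + refine.

oracle_cosinor <- function(y, times, period = 24) {
  rss_at <- function(phi) {
    X <- cbind(1, cos(2 * pi * (times - phi) / period))
    b <- qr.solve(X, y)
    sum((y - X %*% b)^2)
  }
  grid <- seq(0, period, length.out = 481)[-481]
  phi0 <- grid[which.min(vapply(grid, rss_at, 0))]
  opt <- stats::optimize(rss_at, c(phi0 - period / 96, phi0 + period / 96),
                         tol = 1e-12)
  phi <- opt$minimum %% period
  X <- cbind(1, cos(2 * pi * (times - phi) / period))
  b <- qr.solve(X, y)
  if (b[2] < 0) { b[2] <- -b[2]; phi <- (phi + period / 2) %% period }
  list(mesor = b[1], amplitude = b[2], acrophase = phi)
}
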