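test_that("cosinor recovers a noiseless sinusoid exactly", {
  t <- seq(9, 54, by = 3)
  y <- 10 + 2 * cos(2 * pi * (t - 6) / 24)
  f <- cosinor_fit(y, t)
  expect_equal(f$mesor, 10, tolerance = 1e-9)
  expect_equal(f$amplitude, 2, tolerance = 1e-9)
  expect_equal(f$acrophase, 6, tolerance = 1e-9)
  expect_equal(f$ramp, 0.2, tolerance = 1e-9)
})

test_that("constant series give the amplitude-zero sentinel", {
  t <- seq(0, 21, by = 3)
  f <- cosinor_fit(rep(5, 8), t)
  expect_equal(f$mesor, 5)
  expect_equal(f$amplitude, 0)
  expect_equal(f$ramp, 0)
  expect_true(is.na(f$acrophase))
  expect_error(cosinor_fit(1:3, c(0, 8, 16)), "4 distinct")
})

test_that("cosinor agrees with the profile grid-search oracle on noisy data", {
  set.seed(11)
  t <- seq(9, 54, by = 3)
  for (i in 1:5) {
    phi <- runif(1, 0, 24)
    y <- 8 * (1 + 0.4 * cos(2 * pi * (t - phi) / 24)) + rnorm(16, 0, 0.8)
    f <- cosinor_fit(y, t)
    o <- oracle_cosinor(y, t)
    expect_equal(f$mesor, unname(o$mesor), tolerance = 1e-6)
    expect_equal(f$amplitude, unname(o$amplitude), tolerance = 1e-6)
    expect_equal(f$acrophase, o$acrophase, tolerance = 1e-6)
  }
})

test_that("phase is time-shift equivariant and scale leaves rAMP invariant", {
  set.seed(21)
  t <- seq(9, 54, by = 3)
  y <- 6 * (1 + 0.3 * cos(2 * pi * (t - 17) / 24)) * rlnorm(16, 0, 0.05)
  f0 <- cosinor_fit(y, t)
  for (delta in c(2.5, 7, 13)) {
    f1 <- cosinor_fit(y, t + delta)
    expect_equal(f1$acrophase, (f0$acrophase + delta) %% 24,
                 tolerance = 1e-9)
  }
  f2 <- cosinor_fit(3.7 * y, t)
  expect_equal(f2$mesor, 3.7 * f0$mesor, tolerance = 1e-9)
  expect_equal(f2$amplitude, 3.7 * f0$amplitude, tolerance = 1e-9)
  expect_equal(f2$ramp, f0$ramp, tolerance = 1e-9)
  # the rank-based p is invariant under strictly monotone transforms
  p0 <- rhythm_test(y, t, n_perm = 200, seed = 3, exact = "never")
  p1 <- rhythm_test(exp(y / 4), t, n_perm = 200, seed = 3, exact = "never")
  expect_equal(p0, p1)
})

test_that("umbrella permutation test hits the floor on a perfect sinusoid", {
  t <- seq(9, 54, by = 3)
  y <- 10 + 2 * cos(2 * pi * (t - 6) / 24)
  p <- rhythm_test(y, t, n_perm = 1000, seed = 1, exact = "never")
  expect_lte(p, 0.01)
  expect_equal(p, 1 / 1001)
  expect_equal(rhythm_test(rep(5, 16), t, n_perm = 200, seed = 1,
                           exact = "never"), 1)
})

test_that("small-series permutation p equals the exhaustive oracle", {
  t8 <- seq(0, 21, by = 3)
  cases <- list(c(3, 5, 8, 6, 4, 2, 1, 2),
                c(1, 2, 2, 3, 9, 4, 1, 1),
                c(5, 5, 5, 5, 5, 5, 5, 4))
  for (y in cases) {
    expect_equal(rhythm_test(y, t8),            # exact = "auto" enumerates
                 oracle_umbrella_exact_p(y, t8, 24))
  }
  # folding: 8 points over two cycles -> 4 phase groups of 2
  t2c <- seq(0, 42, by = 6)
  y <- c(8, 4, 1, 5, 7, 3, 2, 6)
  expect_equal(rhythm_test(y, t2c), oracle_umbrella_exact_p(y, t2c, 24))
  expect_error(rhythm_test(1:4, rep(c(0, 24), 2)), "2 phase groups")
})

test_that("detect_rhythmic applies BH and the rAMP gate per the invariants", {
  t <- seq(9, 54, by = 3)
  set.seed(8)
  strong <- 10 * (1 + 0.5 * cos(2 * pi * (t - 3) / 24)) * rlnorm(16, 0, 0.05)
  weak <- 10 * (1 + 0.05 * cos(2 * pi * (t - 3) / 24))  # rAMP below gate
  flat <- rep(7, 16)
  v <- rbind(strong = strong, weak = weak, flat = flat)
  x <- make_expr(v, t)
  fits <- detect_rhythmic(x, n_perm = 500, seed = 2, exact = "never")
  expect_true(fits$rhythmic[fits$feature_id == "strong"])
  wk <- fits[fits$feature_id == "weak", ]
  expect_lt(wk$q, 0.05)            # significant...
  expect_lt(wk$ramp, 0.1)          # ...but amplitude-gated
  expect_false(wk$rhythmic)
  # q monotone in p rank and >= p
  expect_true(all(fits$q >= fits$p))
  o <- order(fits$p)
  expect_true(all(diff(fits$q[o]) >= -1e-12))
  expect_error(detect_rhythmic(make_expr(v[0, , drop = FALSE], t)), "empty")
})

test_that("acrophase bins cover one period and sum to the rhythmic count", {
  fits <- data.frame(feature_id = letters[1:4],
                     acrophase = c(0, 23.9, 3, 11.99),
                     rhythmic = TRUE)
  b <- acrophase_bins(fits)
  expect_equal(sum(b), 4L)
  expect_equal(unname(b["[0,3)"]), 1L)
  expect_equal(unname(b["[21,24)"]), 1L)
  expect_equal(unname(b["[3,6)"]), 1L)
  expect_equal(unname(b["[9,12)"]), 1L)
  set.seed(12)
  phi <- runif(100, 0, 24)
  fits <- data.frame(feature_id = paste0("f", 1:100), acrophase = phi,
                     rhythmic = TRUE)
  got <- acrophase_bins(fits)
  want <- table(cut(phi, seq(0, 24, 3), right = FALSE))
  expect_equal(unname(as.integer(got)), unname(as.integer(want)))
})

test_that("discordance classes follow the gene/transcript flags", {
  t <- seq(9, 54, by = 3)
  # antiphase pair: rhythmic transcripts, exactly flat gene
  v <- rbind(t1 = 10 * (1 + 0.5 * cos(2 * pi * t / 24)),
             t2 = 10 * (1 + 0.5 * cos(2 * pi * (t - 12) / 24)),
             t3 = 12 * (1 + 0.4 * cos(2 * pi * (t - 6) / 24)))
  t2g <- data.frame(transcript_id = c("t1", "t2", "t3"),
                    gene_id = c("gA", "gA", "gB"))
  x <- make_expr(v, t)
  gx <- summarize_to_gene(x, t2g)
  tf <- detect_rhythmic(x, n_perm = 500, seed = 4, exact = "never")
  gf <- detect_rhythmic(gx, n_perm = 500, seed = 4, exact = "never")
  d <- gene_transcript_discordance(gf, tf, t2g)
  expect_equal(d$class[d$gene_id == "gA"], "transcripts_only")
  # a single rhythmic transcript sums to itself: both levels rhythmic
  expect_equal(d$class[d$gene_id == "gB"], "both_rhythmic")
  expect_error(gene_transcript_discordance(gf[gf$feature_id != "gA", ],
                                           tf, t2g), "absent")
})

test_that("discordance counts match a per-gene recomputation on simulation", {
  set.seed(31)
  t <- seq(9, 54, by = 3)
  n_gene <- 25
  rows <- list(); map <- list()
  for (g in seq_len(n_gene)) {
    k <- sample(1:3, 1)
    for (j in seq_len(k)) {
      id <- sprintf("g%02d.t%d", g, j)
      rhythmic <- runif(1) < 0.5
      amp <- if (rhythmic) 0.4 else 0
      rows[[id]] <- 10 * (1 + amp * cos(2 * pi * (t - runif(1, 0, 24)) / 24)) *
        rlnorm(16, 0, 0.05)
      map[[id]] <- data.frame(transcript_id = id, gene_id = sprintf("g%02d", g))
    }
  }
  v <- do.call(rbind, rows)
  t2g <- do.call(rbind, map)
  x <- make_expr(v, t); rownames(x$values) <- names(rows)
  gx <- summarize_to_gene(x, t2g)
  tf <- detect_rhythmic(x, n_perm = 300, seed = 5, exact = "never")
  gf <- detect_rhythmic(gx, n_perm = 300, seed = 5, exact = "never")
  d <- gene_transcript_discordance(gf, tf, t2g)
  for (i in seq_len(nrow(d))) {
    g <- d$gene_id[i]
    gr <- gf$rhythmic[gf$feature_id == g]
    tr <- tf$rhythmic[t2g$gene_id[match(tf$feature_id,
                                        t2g$transcript_id)] == g]
    want <- if (gr && any(tr)) "both_rhythmic" else if (gr) "gene_only"
            else if (any(tr)) "transcripts_only" else "neither"
    expect_equal(d$class[i], want)
  }
})
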