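test_that("TMM factors are 1 for identical or uniformly scaled libraries", {
  set.seed(1)
  y <- matrix(rpois(40, 100), 20, 2,
              dimnames = list(paste0("g", 1:20), c("a", "b")))
  y[, 2] <- y[, 1]
  x <- make_expr(y, times = c(0, 3), unit = "counts")
  f <- tmm_factors(x)$factors
  expect_equal(unname(f), c(1, 1), tolerance = 1e-12)
  y[, 2] <- 3 * y[, 1]   # pure depth change, composition unchanged
  x <- make_expr(y, times = c(0, 3), unit = "counts")
  f <- tmm_factors(x)$factors
  expect_equal(unname(f), c(1, 1), tolerance = 1e-12)
  expect_equal(exp(mean(log(f))), 1, tolerance = 1e-12)
})

test_that("TMM matches the step-by-step trim/weight oracle under bias", {
  # composition bias: one dominant feature inflated in sample b
  set.seed(42)
  y <- matrix(rpois(60, 200) + 1, 20, 3,
              dimnames = list(paste0("g", 1:20), c("a", "b", "c")))
  y["g1", "b"] <- 50000
  x <- make_expr(y, times = c(0, 3, 6), unit = "counts")
  nf <- tmm_factors(x, ref_sample = "a")
  expect_equal(unname(nf$factors), unname(oracle_tmm(y, ref = 1)),
               tolerance = 1e-10)
  expect_equal(exp(mean(log(nf$factors))), 1, tolerance = 1e-12)
  # the dominant feature makes the rest of b's composition look depleted,
  # so b's factor drops below 1
  expect_true(nf$factors["b"] < 1)
})

test_that("CPM follows the effective-library-size formula elementwise", {
  y <- matrix(c(500, 10, 0, 250), 2, 2,
              dimnames = list(c("g1", "g2"), c("a", "b")))
  y <- rbind(y, matrix(1e6 - colSums(y), 1, 2,
                       dimnames = list("filler", NULL)))
  x <- make_expr(y, times = c(0, 3), unit = "counts")
  cpm1 <- cpm_matrix(x)   # unit factors
  expect_equal(unname(cpm1$values["g1", "a"]), 500)
  expect_equal(unname(cpm1$values["g2", "b"]), 250)
  expect_equal(sum(cpm1$values[, 1]), 1e6)
  set.seed(2)
  y2 <- matrix(rpois(40, 50) + 1, 10, 4,
               dimnames = list(paste0("g", 1:10), paste0("s", 1:4)))
  x2 <- make_expr(y2, times = c(0, 3, 6, 9), unit = "counts")
  nf <- tmm_factors(x2)
  got <- cpm_matrix(x2, nf)$values
  want <- sweep(y2, 2, colSums(y2) * nf$factors, "/") * 1e6
  expect_equal(got, want, tolerance = 1e-12)
})

test_that("low-expression filter is inclusive at the threshold", {
  n_s <- 4
  lib <- 1e6
  # counts tuned so mean CPM is exactly 0.49 / 0.50 / high
  y <- rbind(low = rep(0.49, n_s), edge = rep(0.50, n_s),
             high = rep(1000, n_s),
             filler = rep(lib - 1000.99, n_s))
  x <- make_expr(y, times = c(0, 3, 6, 9), unit = "counts")
  cpm0 <- cpm_matrix(x)
  fl <- filter_low_expression(cpm0, x, threshold = 0.5)
  expect_setequal(fl$kept, c("edge", "high", "filler"))
  expect_identical(fl$dropped, "low")
})

test_that("filtering renormalizes on retained features and is idempotent", {
  set.seed(3)
  y <- matrix(rpois(400, 30) + 1, 100, 4,
              dimnames = list(paste0("g", 1:100), paste0("s", 1:4)))
  y[1:30, ] <- 0                               # 30 features below threshold
  x <- make_expr(y, times = c(0, 6, 12, 18), unit = "counts")
  cpm0 <- cpm_matrix(x, tmm_factors(x))
  fl <- filter_low_expression(cpm0, x, threshold = 0.5)
  expect_equal(length(fl$kept), 70)
  # CPM recomputed on the retained set only
  want <- cpm_matrix(fl$counts, tmm_factors(fl$counts))
  expect_equal(fl$cpm$values, want$values, tolerance = 1e-12)
  # a second pass with frozen factors removes nothing and changes nothing
  fl2 <- filter_low_expression(fl$cpm, fl$counts, threshold = 0.5,
                               refresh_factors = FALSE, factors = fl$factors)
  expect_identical(fl2$kept, fl$kept)
  fl3 <- filter_low_expression(fl$cpm, fl$counts, threshold = 0.5)
  expect_identical(fl3$kept, fl$kept)
  expect_error(filter_low_expression(cpm0, x, threshold = 1e9),
               "all features")
})

test_that("gene summarization sums transcripts exactly and conserves mass", {
  t2g <- data.frame(transcript_id = c("t1", "t2", "t3"),
                    gene_id = c("gA", "gA", "gB"))
  v <- matrix(c(3, 4.5, 2, 1, 0.5, 7), 3, 2,
              dimnames = list(c("t1", "t2", "t3"), c("s1", "s2")))
  x <- make_expr(v, times = c(0, 3), unit = "TPM")
  g <- summarize_to_gene(x, t2g)
  expect_equal(unname(g$values["gA", ]), unname(v["t1", ] + v["t2", ]))
  expect_equal(unname(g$values["gB", ]), unname(v["t3", ]))
  expect_equal(colSums(g$values), colSums(v))
  expect_error(summarize_to_gene(x, t2g[1:2, ]), "missing from tx2gene")
})

test_that("antiphase isoforms cancel into a constant gene series", {
  t <- seq(9, 54, by = 3)
  v <- rbind(t1 = 10 * (1 + 0.5 * cos(2 * pi * (t - 0) / 24)),
             t2 = 10 * (1 + 0.5 * cos(2 * pi * (t - 12) / 24)))
  x <- make_expr(v, times = t, unit = "TPM")
  g <- summarize_to_gene(x, data.frame(transcript_id = c("t1", "t2"),
                                       gene_id = "g"))
  expect_equal(unname(g$values["g", ]), rep(20, 16), tolerance = 1e-12)
})

test_that("expression matrices round-trip through TSV", {
  set.seed(4)
  v <- matrix(rpois(24, 40), 6, 4,
              dimnames = list(paste0("t", 1:6), paste0("s", 1:4)))
  x <- make_expr(v, times = c(0, 3, 6, 9), unit = "counts")
  path <- tempfile(fileext = ".tsv")
  write_expr_tsv(x, path)
  back <- read_expr_tsv(path, unit = "counts")
  expect_equal(back$values, x$values)
  expect_equal(back$samples, x$samples)
})
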