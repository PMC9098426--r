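se_fixture <- function() {
  ann <- generate_annotation("SE", 1, seed = 1)
  list(ann = ann, events = extract_events(ann))
}

test_that("PSI is the inclusion/total TPM ratio with NA where undefined", {
  fx <- se_fixture()
  t <- c(0, 3, 6, 9)
  v <- rbind(GSE001.T1 = c(9, 1, 5, 0),    # inclusion form
             GSE001.T2 = c(1, 9, 0, 0))
  x <- make_expr(v, t, unit = "TPM")
  pt <- psi_per_sample(fx$events, x)
  expect_equal(unname(pt$psi[1, ]), c(0.9, 0.1, 1.0, NA))
  expect_equal(pt$mean_psi, mean(c(0.9, 0.1, 1.0)))
  expect_equal(pt$defined_frac, 0.75)
  bad <- fx$events
  bad$total_transcripts <- paste0(bad$total_transcripts, ",GHOST")
  expect_error(psi_per_sample(bad, x), "absent from TPM")
  expect_error(psi_per_sample(fx$events,
                              make_expr(v, t, unit = "CPM")), "TPM")
})

test_that("PSI is scale-invariant and complementary forms sum to one", {
  fx <- se_fixture()
  t <- seq(0, 9, by = 3)
  set.seed(6)
  v <- matrix(rlnorm(8, log(5), 0.4), 2, 4,
              dimnames = list(c("GSE001.T1", "GSE001.T2"), NULL))
  x <- make_expr(v, t, unit = "TPM")
  p1 <- psi_per_sample(fx$events, x)
  scaled <- v * rep(c(2, 0.3, 10, 1), each = 2)   # per-sample rescaling
  x2 <- make_expr(scaled, t, unit = "TPM")
  p2 <- psi_per_sample(fx$events, x2)
  expect_equal(p1$psi, p2$psi, tolerance = 1e-12)
  # swap inclusion role: PSI + complementary PSI = 1
  flipped <- fx$events
  flipped$inclusion_transcripts <- "GSE001.T2"
  p3 <- psi_per_sample(flipped, x)
  expect_equal(unname(p1$psi + p3$psi), matrix(1, 1, 4), tolerance = 1e-12)
})

test_that("programmed inclusion fraction is recovered by mean PSI", {
  fx <- se_fixture()
  des <- simulation_design(seed = 13)
  specs <- signal_specs(c("GSE001.T1", "GSE001.T2"), mesor = c(3, 7),
                        rel_amplitude = 0, noise_cv = 0.05)
  sim <- simulate_timecourse(fx$ann, des, specs)
  pt <- psi_per_sample(fx$events, sim$tpm)
  expect_lt(abs(pt$mean_psi - 0.3), 0.02)
})

test_that("spliced flags use strict open-interval bounds", {
  pt <- structure(list(
    psi = matrix(0.5, 10, 4), mean_psi = c(0.10, 0.1000001, 0.5, 0.8999999,
                                           0.9, 0.0, 1.0, 0.3, NA, 0.7),
    defined_frac = c(rep(1, 8), 0, 1),
    events = data.frame(event_id = paste0("e", 1:10),
                        event_type = rep(c("SE", "RI"), 5),
                        gene_id = paste0("g", 1:10)),
    samples = make_sheet(c(0, 3, 6, 9)),
    spliced = rep(NA, 10)), class = "psi_table")
  pt <- flag_spliced(pt)
  expect_equal(pt$spliced,
               c(FALSE, TRUE, TRUE, TRUE, FALSE, FALSE, FALSE, TRUE, NA,
                 TRUE))
  gs <- spliced_genes(pt)
  expect_setequal(gs$spliced$SE, "g3")
  expect_setequal(gs$spliced$RI, c("g2", "g4", "g8", "g10"))
  # g9 is excluded from the universe: PSI undefined in every sample
  expect_false("g9" %in% gs$tested$SE)
})

test_that("gain/loss classification partitions the tested universe", {
  wt <- list(spliced = list(SE = c("g1", "g2"), AF = character()),
             tested = list(SE = c("g1", "g2", "g3"), AF = c("g4")))
  ko <- list(spliced = list(SE = c("g2", "g3"), AF = c("g4")),
             tested = list(SE = c("g1", "g2", "g3"), AF = c("g4")))
  ch <- classify_gain_loss(wt, ko)
  get <- function(g, ty) ch$status[ch$gene_id == g & ch$event_type == ty]
  expect_equal(get("g1", "SE"), "loss")
  expect_equal(get("g2", "SE"), "shared")
  expect_equal(get("g3", "SE"), "gain")
  expect_equal(get("g4", "AF"), "gain")
  # statuses partition the universe per event type
  expect_equal(nrow(ch), 4L)
  expect_error(classify_gain_loss(wt, ko[c("spliced")]), "tested")
  ko2 <- ko
  names(ko2$spliced) <- c("SE", "RI")
  expect_error(classify_gain_loss(wt, ko2), "keys differ")
})

test_that("Mann-Whitney exact p equals the enumeration oracle at n = 5 + 5", {
  set.seed(9)
  for (i in 1:4) {
    x <- round(rnorm(5, 0.4, 0.2), 2)
    y <- round(rnorm(5, 0.55, 0.2), 2)   # rounding induces occasional ties
    got <- mann_whitney_test(x, y)
    expect_equal(got$p, oracle_mw_exact_p(x, y))
    expect_equal(got$u, oracle_mw_u(x, y))
  }
  # identical vectors: U is central in every assignment, p = 1
  expect_equal(mann_whitney_test(rep(0.5, 5), rep(0.5, 5))$p, 1)
})

test_that("differential splicing flags separated PSI vectors, not identical", {
  fx <- se_fixture()
  t <- seq(9, 54, by = 3)
  base <- seq(0.3, 0.45, length.out = 16)
  v_wt <- rbind(GSE001.T1 = base * 10, GSE001.T2 = (1 - base) * 10)
  shift <- base + 0.4
  v_ko <- rbind(GSE001.T1 = shift * 10, GSE001.T2 = (1 - shift) * 10)
  pt_wt <- flag_spliced(psi_per_sample(fx$events,
                                       make_expr(v_wt, t, "WT", "TPM")))
  pt_ko <- flag_spliced(psi_per_sample(fx$events,
                                       make_expr(v_ko, t, "KO", "TPM")))
  ds <- differential_splicing(pt_wt, pt_ko)
  expect_lt(ds$p, 0.001)                   # full separation, n = 16 vs 16
  expect_true(ds$significant)
  expect_equal(ds$delta_psi, 0.4, tolerance = 1e-12)
  same <- differential_splicing(pt_wt, pt_wt)
  expect_equal(same$p, 1)
  expect_equal(same$delta_psi, 0)
  # insufficient defined samples -> untestable
  v_na <- v_wt; v_na[, 3:16] <- 0
  pt_na <- flag_spliced(psi_per_sample(fx$events,
                                       make_expr(v_na, t, "KO", "TPM")))
  ds2 <- differential_splicing(pt_wt, pt_na)
  expect_false(ds2$testable)
  expect_true(is.na(ds2$p))
})

test_that("large-sample approximation matches wilcox.test with ties", {
  set.seed(14)
  x <- round(rnorm(20, 0, 1), 1); y <- round(rnorm(25, 0.5, 1), 1)
  got <- mann_whitney_test(x, y)
  ref <- stats::wilcox.test(x, y, exact = FALSE, correct = FALSE)
  expect_equal(got$p, unname(ref$p.value), tolerance = 1e-12)
})
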