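test_that("per-gene tallies count mutations and distinct sites", {
  tr <- coding_transcript("G1", "T1", paste0(strrep("CTG", 12), "TAA"))
  empty <- tally_gene(selscape:::.empty_annotated(), tr)
  expect_equal(empty[c("N", "S", "S_N", "S_S")],
               list(N = 0L, S = 0L, S_N = 0L, S_S = 0L))
  expect_equal(sum(empty$z), 0)

  rec <- data.frame(
    sample_id = c("S1", "S2", "S3", "S1"),
    gene_id = "G1", transcript_id = "T1",
    cds_position = c(19L, 20L, 25L, 6L),
    codon_index = c(7L, 7L, 9L, 2L),
    ref = "C", alt = "T",
    consequence = c("missense", "missense", "missense", "synonymous"),
    context_class = NA_character_, stringsAsFactors = FALSE)
  counts <- tally_gene(rec, tr)
  expect_equal(counts$N, 3)
  expect_equal(counts$S, 1)
  expect_equal(counts$S_N, 2)       # codons 7 and 9
  expect_equal(counts$S_S, 1)
  expect_equal(counts$z[7], 2)
  expect_equal(counts$z[9], 1)
  expect_equal(sum(counts$z), counts$N)
})

test_that("CN/CS follows the rate-ratio definition", {
  expect_equal(as.numeric(compute_cncs(0, 5, 300, 100)), 0)
  expect_equal(as.numeric(compute_cncs(30, 10, 300, 100)), 1)
  # scale invariance in (L_N, L_S)
  expect_equal(as.numeric(compute_cncs(17, 5, 120, 40)),
               as.numeric(compute_cncs(17, 5, 12, 4)))
  s0 <- compute_cncs(10, 0, 300, 100)
  expect_true(attr(s0, "s_substituted"))
  expect_equal(as.numeric(s0), (10 / 300) / (0.5 / 100))
  expect_true(is.na(compute_cncs(0, 0, 300, 100)))
})

test_that("H matches hand-evaluated cases and is clamped to [0, 1]", {
  expect_equal(compute_H(c(0, 0, 0, 4)), 2 / 3)
  expect_equal(compute_H(c(0, 2, 1, 1)), 0)     # raw negative, clamped
  expect_equal(compute_H(c(5, 0, 0, 0, 0)), 0.75)
  expect_equal(compute_H(rep(3L, 10)), 0)       # equal counts -> no heterogeneity
  expect_true(is.na(compute_H(c(0L, 0L, 0L))))  # undefined at mean 0
  # one site absorbing everything: H -> 1 as gene length grows
  expect_gt(compute_H(c(100L, rep(0L, 999))), 0.98)
})

test_that("chi-square test against a null CN/CS ratio is Pearson on (N, S)", {
  t0 <- cncs_chisq_test(150, 50, 3, 1)
  expect_equal(t0$statistic, 0)
  expect_equal(t0$p.value, 1)

  t1 <- cncs_chisq_test(200, 50, 3, 1)
  expect_equal(t1$statistic, 10 / 3, tolerance = 1e-6)
  expect_equal(t1$p.value, 0.06788915, tolerance = 1e-5)

  # H = 0 makes the 1-H test identical to the test against 1
  expect_identical(cncs_chisq_test(80, 30, 3, 1, null_ratio = 1 - 0),
                   cncs_chisq_test(80, 30, 3, 1))

  # one-sided convention: deviation against the direction is never significant
  g <- cncs_chisq_test(200, 50, 3, 1, alternative = "greater")
  l <- cncs_chisq_test(200, 50, 3, 1, alternative = "less")
  expect_equal(g$p.value, t1$p.value / 2)
  expect_equal(l$p.value, 1 - t1$p.value / 2)
})

test_that("selection modes follow the CN/CS vs 1-H decision table", {
  expect_equal(selection_mode(12.4, 0.9, 1e-30, 1e-30), "dominant_positive")
  expect_equal(selection_mode(0.9, 0.4, 0.3, 0.01), "weak_positive")
  expect_equal(selection_mode(0.3, 0.4, 1e-4, 1e-6), "negative")
  expect_equal(selection_mode(1.0, 0.5, 1, 1), "neutral_or_undetermined")
  expect_equal(selection_mode(NA, NA, NA, NA), "neutral_or_undetermined")
})

test_that("compute_gene_stats assembles the per-gene table", {
  set.seed(81)
  cfg <- simulation_config(n_genes = 8, n_codons = 80, eta = 0.05, m0 = 0.4,
                           m1 = 6, alpha = 1.51, n_samples = 30, seed = 81)
  sim <- simulate_cohort(cfg)
  ann <- annotate_mutations(read_maf(sim$maf), sim$transcripts)
  gs <- compute_gene_stats(ann, sim$transcripts, uniform_spectrum())
  expect_equal(nrow(gs), 8)
  expect_true(all(gs$S_N <= gs$N))
  expect_true(all(gs$cncs >= 0, na.rm = TRUE))
  expect_true(all(gs$H >= 0 & gs$H <= 1, na.rm = TRUE))
  zs <- attr(gs, "z")
  expect_equal(vapply(zs, sum, 0)[gs$gene_id], setNames(gs$N, gs$gene_id))
})
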