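test_that("pyrimidine-centered collapse yields exactly 96 classes", {
  expect_equal(collapse_context("A", "C", "T", "G"), "A[C>T]G")
  # purine reference: reverse-complement triplet and substitution
  expect_equal(collapse_context("T", "G", "A", "C"), "G[C>T]A")
  expect_true(is.na(collapse_context(NA, "C", "T", "G")))

  grid <- expand.grid(f5 = c("A", "C", "G", "T"), ref = c("A", "C", "G", "T"),
                      alt = c("A", "C", "G", "T"), f3 = c("A", "C", "G", "T"),
                      stringsAsFactors = FALSE)
  grid <- grid[grid$ref != grid$alt, ]
  cls <- collapse_context(grid$f5, grid$ref, grid$alt, grid$f3)
  expect_false(any(is.na(cls)))
  expect_setequal(unique(cls), context_classes())
  expect_equal(length(context_classes()), 96)
  expect_equal(anyDuplicated(context_classes()), 0)
})

test_that("spectrum estimation is proportional to count/opportunity ratios", {
  set.seed(71)
  trs <- lapply(1:4, function(i) {
    coding_transcript(paste0("G", i), paste0("T", i), random_cds_helper(60))
  })
  names(trs) <- paste0("G", 1:4)
  opp <- selscape:::.syn_opportunities(trs)

  # counts exactly proportional to opportunities -> all rates 1 (pc = 0)
  records <- data.frame(
    consequence = "synonymous",
    context_class = rep(names(opp), opp),
    stringsAsFactors = FALSE)
  sp <- suppressWarnings(estimate_context_rates(records, trs, pseudocount = 0))
  # a few classes are never offered as synonymous changes; all offered
  # classes must share one rate (uniformity), zero-offered classes get 0
  offered <- sp[opp > 0]
  expect_lt(max(offered) - min(offered), 1e-12)
  expect_true(all(sp[opp == 0] == 0))

  # two observed classes with counts 30 and 10: rates scale with count/opp
  two <- names(which(opp >= 3))[1:2]
  rec2 <- data.frame(consequence = "synonymous",
                     context_class = rep(two, c(30, 10)),
                     stringsAsFactors = FALSE)
  sp2 <- suppressWarnings(estimate_context_rates(rec2, trs, pseudocount = 0))
  expect_equal(sp2[[two[1]]] / sp2[[two[2]]],
               (30 / opp[[two[1]]]) / (10 / opp[[two[2]]]), tolerance = 1e-12)

  # classes with zero observed events remain finite under the default pc
  sp3 <- suppressWarnings(estimate_context_rates(rec2, trs))
  expect_true(all(is.finite(sp3)) && all(sp3 >= 0))
  expect_equal(mean(sp3), 1, tolerance = 1e-12)
})

test_that("spectrum estimation recovers a known generating spectrum", {
  set.seed(72)
  trs <- lapply(1:20, function(i) {
    coding_transcript(paste0("G", i), paste0("T", i), random_cds_helper(200))
  })
  names(trs) <- paste0("G", 1:20)
  opp <- selscape:::.syn_opportunities(trs)
  truth <- context_spectrum(setNames(exp(rnorm(96, sd = 0.7)),
                                     context_classes()))
  prob <- as.numeric(truth) * opp
  draws <- sample(context_classes(), 50000, replace = TRUE,
                  prob = prob / sum(prob))
  records <- data.frame(consequence = "synonymous", context_class = draws,
                        stringsAsFactors = FALSE)
  est <- suppressWarnings(estimate_context_rates(records, trs))
  cosine <- sum(est * truth) / sqrt(sum(est^2) * sum(truth^2))
  expect_gt(cosine, 0.98)
})

test_that("expected sites reduce to potential-site counts under a uniform spectrum", {
  u <- uniform_spectrum()
  tr1 <- coding_transcript("G", "T", "TTTTAA")
  expect_equal(expected_sites(tr1, u), list(L_N = 8, L_S = 1))
  tr2 <- coding_transcript("G", "T", "ATGTTTTAA")
  expect_equal(expected_sites(tr2, u), list(L_N = 17, L_S = 1))
  # additivity over codons: per-codon change counts sum to the gene totals
  cc <- count_codon_changes("ATG") + count_codon_changes("TTT")
  expect_equal(expected_sites(tr2, u)$L_N, unname(cc["nonsyn"]))

  # scaling every rate and renormalizing leaves L_N and L_S unchanged
  set.seed(73)
  tr3 <- coding_transcript("G3", "T3", random_cds_helper(50))
  sp <- context_spectrum(setNames(runif(96, 0.2, 3), context_classes()))
  sp2 <- context_spectrum(sp * 2)
  expect_equal(expected_sites(tr3, sp), expected_sites(tr3, sp2))
})

test_that("spectrum serializes to TSV and back", {
  sp <- context_spectrum(setNames(runif(96, 0.5, 2), context_classes()))
  path <- tempfile(fileext = ".tsv")
  write_spectrum(sp, path)
  sp2 <- read_spectrum(path)
  expect_equal(as.numeric(sp2), as.numeric(sp), tolerance = 1e-12)
  expect_identical(names(sp2), names(sp))
})
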