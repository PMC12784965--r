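# Independent brute-force oracles: plain loops over the standard genetic
# code, written without the package's lookup tables or vectorized paths.

.GC <- as.character(Biostrings::GENETIC_CODE)
names(.GC) <- names(Biostrings::GENETIC_CODE)
.B4 <- c("A", "C", "G", "T")

oracle_consequence <- function(codon, pos, alt) {
  aa <- .GC[[codon]]
  mutated <- codon
  substr(mutated, pos, pos) <- alt
  aa2 <- .GC[[mutated]]
  if (aa == "*" || aa2 == "*") "other"
  else if (aa == aa2) "synonymous" else "missense"
}

# Classic potential-site counting over the sense codons of a CDS.
oracle_site_counts <- function(cds) {
  n <- nchar(cds) %/% 3L
  if (.GC[[substr(cds, nchar(cds) - 2L, nchar(cds))]] == "*") n <- n - 1L
  LN <- LS <- 0L
  for (i in seq_len(n)) {
    codon <- substr(cds, 3L * i - 2L, 3L * i)
    for (p in 1:3) {
      for (b in setdiff(.B4, substr(codon, p, p))) {
        cons <- oracle_consequence(codon, p, b)
        if (cons == "missense") LN <- LN + 1L
        else if (cons == "synonymous") LS <- LS + 1L
      }
    }
  }
  c(L_N = LN, L_S = LS)
}

sense_codons_helper <- function() names(.GC)[.GC != "*"]

random_cds_helper <- function(n_codons) {
  paste0(paste(sample(sense_codons_helper(), n_codons, replace = TRUE),
               collapse = ""), "TAA")
}

# Eq-8 analytic moments of the two-component site-count distribution.
analytic_moments <- function(eta, m0, m1, alpha) {
  zbar <- (1 - eta) * m0 + eta * m1
  v <- zbar + eta * (1 - eta) * (m1 - m0)^2 + eta * m1^2 / alpha
  c(mean = zbar, var = v)
}

write_toy_maf <- function(path, rows) {
  write.table(rows, path, sep = "\t", quote = FALSE, row.names = FALSE)
  path
}
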