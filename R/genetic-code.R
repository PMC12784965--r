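# Genetic-code utilities shared by annotation, opportunity counting and the
# simulator. All lookups are precomputed once per session.

.selscape <- new.env(parent = emptyenv())

.BASES <- c("A", "C", "G", "T")
.COMPLEMENT <- c(A = "T", C = "G", G = "C", T = "A")

.genetic_code <- function() {
  if (is.null(.selscape$gc)) {
    gc <- Biostrings::GENETIC_CODE
    .selscape$gc <- setNames(as.character(gc), names(gc))
  }
  .selscape$gc
}

.sense_codons <- function() {
  gc <- .genetic_code()
  names(gc)[gc != "*"]
}

# 576-entry lookup: "<codon><pos><alt>" -> consequence of the single-nucleotide
# change. Stop-gain and stop-loss both map to "other"; stop codons themselves
# are absent (mutation sites are restricted to sense codons).
.change_lookup <- function() {
  if (!is.null(.selscape$changes)) return(.selscape$changes)
  gc <- .genetic_code()
  codons <- names(gc)
  key <- character(64L * 9L)
  val <- character(64L * 9L)
  i <- 0L
  for (codon in codons) {
    aa <- gc[[codon]]
    for (pos in 1:3) {
      ref <- substr(codon, pos, pos)
      for (alt in setdiff(.BASES, ref)) {
        new_codon <- codon
        substr(new_codon, pos, pos) <- alt
        new_aa <- gc[[new_codon]]
        i <- i + 1L
        key[i] <- paste0(codon, pos, alt)
        val[i] <- if (aa == "*" || new_aa == "*") {
          "other"
        } else if (aa == new_aa) "synonymous" else "missense"
      }
    }
  }
  .selscape$changes <- setNames(val, key)
  .selscape$changes
}

#' Consequence of a single-nucleotide change within a codon
#'
#' Classifies the substitution of `alt` at codon position `pos` under the
#' standard genetic code. Changes creating or destroying a stop codon are
#' classified `"other"`; they enter neither the nonsynonymous nor the
#' synonymous tally.
#'
#' @param codon Character vector of 3-letter DNA codons (uppercase ACGT).
#' @param pos Integer vector in 1..3, position within the codon.
#' @param alt Character vector of replacement bases.
#' @return Character vector with values `"synonymous"`, `"missense"` or
#'   `"other"`. Mutations inside a stop codon return `NA`.
#' @examples
#' codon_consequence("ATG", 3, "A")  # Met -> Ile, missense
#' codon_consequence("CTG", 3, "A")  # Leu -> Leu, synonymous
#' @export
codon_consequence <- function(codon, pos, alt) {
  unname(.change_lookup()[paste0(codon, pos, alt)])
}

#' Partition the nine single-nucleotide changes of a sense codon
#'
#' @param codon A single sense codon (uppercase).
#' @return Named integer vector `c(nonsyn, syn, other)` summing to 9, where
#'   `other` counts stop-gain changes.
#' @examples
#' count_codon_changes("TTT")  # 8 missense, 1 synonymous
#' @export
count_codon_changes <- function(codon) {
  stopifnot(is.character(codon), length(codon) == 1L, nchar(codon) == 3L)
  gc <- .genetic_code()
  if (is.na(gc[codon]) || gc[[codon]] == "*") {
    stop("count_codon_changes() requires a sense codon, got ", codon)
  }
  cons <- codon_consequence(rep(codon, 9L), rep(1:3, each = 3L),
                            unlist(lapply(1:3, function(p)
                              setdiff(.BASES, substr(codon, p, p)))))
  c(nonsyn = sum(cons == "missense"),
    syn = sum(cons == "synonymous"),
    other = sum(cons == "other"))
}

# Split a CDS string into its codons.
.codons_of <- function(cds) {
  n <- nchar(cds) %/% 3L
  substring(cds, 3L * seq_len(n) - 2L, 3L * seq_len(n))
}

# Enumerate all 9 * n_codons single-nucleotide changes over the sense codons
# of a transcript. Flanking bases are taken from the full CDS (including a
# terminal stop codon when present); NA where no flank exists.
.enumerate_changes <- function(transcript) {
  cds <- transcript$cds_sequence
  n_cod <- transcript$n_codons
  L <- 3L * n_cod
  len <- nchar(cds)
  bases <- strsplit(cds, "", fixed = TRUE)[[1L]]
  site_ref <- bases[seq_len(L)]
  pos <- rep(seq_len(L), each = 3L)
  ref <- rep(site_ref, each = 3L)
  alt_of <- list(A = c("C", "G", "T"), C = c("A", "G", "T"),
                 G = c("A", "C", "T"), T = c("A", "C", "G"))
  alt <- unlist(alt_of[site_ref], use.names = FALSE)
  codon_index <- (pos - 1L) %/% 3L + 1L
  pos_in_codon <- (pos - 1L) %% 3L + 1L
  codons <- .codons_of(substr(cds, 1L, L))
  codon <- codons[codon_index]
  consequence <- unname(.change_lookup()[paste0(codon, pos_in_codon, alt)])
  flank5 <- ifelse(pos > 1L, bases[pmax(pos - 1L, 1L)], NA_character_)
  flank3 <- ifelse(pos < len, bases[pmin(pos + 1L, len)], NA_character_)
  data.frame(cds_position = pos, codon_index = codon_index,
             pos_in_codon = pos_in_codon, codon = codon,
             ref = ref, alt = alt, consequence = consequence,
             flank5 = flank5, flank3 = flank3,
             stringsAsFactors = FALSE)
}
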