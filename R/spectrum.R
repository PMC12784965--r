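# 96-class trinucleotide-context mutation spectrum and rate-weighted
# opportunity counts (L_N, L_S).

.SUBSTITUTIONS <- c("C>A", "C>G", "C>T", "T>A", "T>C", "T>G")

#' Canonical ordering of the 96 pyrimidine-centered context classes
#'
#' Classes are ordered substitution-major (C>A, C>G, C>T, T>A, T>C, T>G),
#' then by 5' flank, then by 3' flank, alphabetically.
#'
#' @return Character vector of 96 class labels such as `"A[C>T]G"`.
#' @export
context_classes <- function() {
  if (is.null(.selscape$classes)) {
    .selscape$classes <- as.vector(t(outer(
      .SUBSTITUTIONS,
      as.vector(t(outer(.BASES, .BASES, paste, sep = "."))),
      function(s, fl) {
        f <- strsplit(fl, ".", fixed = TRUE)
        mapply(function(sub, ff) paste0(ff[1], "[", sub, "]", ff[2]), s, f)
      })))
  }
  .selscape$classes
}

#' Collapse a stranded single-base substitution to its pyrimidine-centered class
#'
#' Substitutions with a purine reference base are reverse-complemented
#' (including the flanks) before classing, so every change maps to one of the
#' 96 classes with a C or T reference.
#'
#' @param flank5,flank3 Single bases 5' and 3' of the mutated base on the
#'   coding strand (`NA` allowed; yields `NA` class).
#' @param ref,alt Reference and alternate base; must differ.
#' @return Character vector of class labels; `NA` where any base is missing
#'   or ambiguous.
#' @examples
#' collapse_context("A", "C", "T", "G")  # "A[C>T]G"
#' collapse_context("T", "G", "A", "C")  # "G[C>T]A"
#' @export
collapse_context <- function(flank5, ref, alt, flank3) {
  n <- max(length(flank5), length(ref), length(alt), length(flank3))
  flank5 <- rep_len(as.character(flank5), n)
  flank3 <- rep_len(as.character(flank3), n)
  ref <- rep_len(as.character(ref), n)
  alt <- rep_len(as.character(alt), n)
  ok <- !is.na(flank5) & !is.na(flank3) & !is.na(ref) & !is.na(alt) &
    flank5 %in% .BASES & flank3 %in% .BASES &
    ref %in% .BASES & alt %in% .BASES & ref != alt
  out <- rep(NA_character_, n)
  if (!any(ok)) return(out)
  f5 <- flank5[ok]; f3 <- flank3[ok]; r <- ref[ok]; a <- alt[ok]
  pur <- r %in% c("A", "G")
  if (any(pur)) {
    nf5 <- unname(.COMPLEMENT[f3[pur]])
    nf3 <- unname(.COMPLEMENT[f5[pur]])
    nr <- unname(.COMPLEMENT[r[pur]])
    na_ <- unname(.COMPLEMENT[a[pur]])
    f5[pur] <- nf5; f3[pur] <- nf3; r[pur] <- nr; a[pur] <- na_
  }
  out[ok] <- paste0(f5, "[", r, ">", a, "]", f3)
  out
}

#' Construct a context spectrum
#'
#' @param rates Named numeric vector over all 96 classes of
#'   [context_classes()]; nonnegative and finite. Normalized to mean 1.
#' @return A `context_spectrum`: a named numeric vector of 96 relative rates
#'   with mean 1.
#' @export
context_spectrum <- function(rates) {
  cls <- context_classes()
  if (is.null(names(rates)) || !setequal(names(rates), cls)) {
    stop("rates must be named by the 96 context classes")
  }
  rates <- rates[cls]
  if (any(!is.finite(rates)) || any(rates < 0)) {
    stop("spectrum rates must be finite and nonnegative")
  }
  if (mean(rates) <= 0) stop("spectrum rates must not be all zero")
  out <- rates / mean(rates)
  class(out) <- c("context_spectrum", "numeric")
  out
}

#' Uniform (equal-rate) context spectrum
#' @return A `context_spectrum` with all 96 rates equal to 1.
#' @export
uniform_spectrum <- function() {
  context_spectrum(setNames(rep(1, 96), context_classes()))
}

# Per-class counts of possible synonymous changes across transcripts,
# excluding edge changes without a flank.
.syn_opportunities <- function(transcripts) {
  tot <- setNames(numeric(96), context_classes())
  for (tr in transcripts) {
    ec <- .enumerate_changes(tr)
    syn <- ec[ec$consequence == "synonymous", , drop = FALSE]
    cls <- collapse_context(syn$flank5, syn$ref, syn$alt, syn$flank3)
    tab <- table(cls[!is.na(cls)])
    tot[names(tab)] <- tot[names(tab)] + as.numeric(tab)
  }
  tot
}

#' Estimate the 96-class neutral mutation spectrum from synonymous mutations
#'
#' Relative rate of class c is proportional to
#' (observed synonymous mutations in c + pseudocount) /
#' (synonymous opportunities in c + pseudocount), normalized to mean 1.
#' Synonymous changes are taken as selectively neutral, so their
#' context-class composition relative to what the coding sequences offer
#' estimates the mutational process.
#'
#' @param records Annotated mutation data frame (see [annotate_mutations()]);
#'   only rows with `consequence == "synonymous"` and a non-`NA`
#'   `context_class` contribute.
#' @param transcripts List of `coding_transcript` objects providing the
#'   synonymous opportunities.
#' @param pseudocount Strength of shrinkage toward the cohort-average rate
#'   (default 0.5): each class receives `pseudocount` pseudo-opportunities
#'   carrying events at the cohort-average rate per opportunity. Classes
#'   never observed or never offered thus default to the average rate
#'   (relative rate 1) instead of being wildly inflated — counts are orders
#'   of magnitude sparser than opportunities, so adding the same raw
#'   pseudocount to both would give an empty class a raw ratio of 1 against
#'   a typical per-opportunity rate of ~1e-3.
#' @return A `context_spectrum`.
#' @export
estimate_context_rates <- function(records, transcripts, pseudocount = 0.5) {
  cls <- context_classes()
  syn <- records[records$consequence == "synonymous" &
                   !is.na(records$context_class), , drop = FALSE]
  if (nrow(syn) == 0L) {
    stop("no synonymous mutations with a context class; cannot fit spectrum")
  }
  counts <- setNames(numeric(96), cls)
  tab <- table(syn$context_class)
  counts[names(tab)] <- as.numeric(tab)
  opp <- .syn_opportunities(transcripts)
  if (any(opp == 0)) {
    warning(sum(opp == 0), " context classes have zero synonymous ",
            "opportunities; their rates rest on the pseudocount alone")
  }
  rate_bar <- sum(counts) / sum(opp)
  raw <- (counts + pseudocount * rate_bar) / (opp + pseudocount)
  raw[!is.finite(raw)] <- 0  # never offered, never observed, no pseudocount
  context_spectrum(raw)
}

#' Rate-weighted expected nonsynonymous and synonymous sites of a transcript
#'
#' Sums the spectrum rate of every possible nonsynonymous (`L_N`) or
#' synonymous (`L_S`) single-nucleotide change over the sense codons.
#' Stop-gain changes contribute to neither. Changes at CDS edges whose flank
#' is unknown use rate 1.
#'
#' @param transcript A `coding_transcript`.
#' @param spectrum A `context_spectrum`; defaults to [uniform_spectrum()],
#'   under which `L_N`/`L_S` reduces to classic potential-site counting.
#' @return List with `L_N`, `L_S`.
#' @export
expected_sites <- function(transcript, spectrum = uniform_spectrum()) {
  ec <- .enumerate_changes(transcript)
  cls <- collapse_context(ec$flank5, ec$ref, ec$alt, ec$flank3)
  rate <- ifelse(is.na(cls), 1, unname(spectrum[cls]))
  list(L_N = sum(rate[ec$consequence == "missense"]),
       L_S = sum(rate[ec$consequence == "synonymous"]))
}

#' Write / read a spectrum as a two-column TSV (class, rate)
#' @param spectrum A `context_spectrum`.
#' @param path File path.
#' @export
write_spectrum <- function(spectrum, path) {
  utils::write.table(
    data.frame(class = names(spectrum), rate = as.numeric(spectrum)),
    path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_spectrum
#' @export
read_spectrum <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  context_spectrum(setNames(df$rate, df$class))
}
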