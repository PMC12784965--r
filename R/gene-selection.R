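# Gene-level selection statistics: CN/CS, among-site heterogeneity H,
# chi-square tests against null ratios 1 and 1-H, and the selection mode.

#' Tally per-gene mutation counts
#'
#' @param records Annotated mutations of one gene (see [annotate_mutations()]).
#' @param transcript The gene's `coding_transcript`.
#' @return List of class `gene_counts`: `N` (missense mutations), `S`
#'   (synonymous mutations), `S_N` (distinct codons with >= 1 missense
#'   mutation), `S_S` (distinct CDS sites with >= 1 synonymous mutation) and
#'   `z`, the vector of missense counts per codon (length `n_codons`,
#'   zeros included). Mutations classified "other" (stop-gain etc.) enter
#'   none of the tallies.
#' @export
tally_gene <- function(records, transcript) {
  stopifnot(inherits(transcript, "coding_transcript"))
  if (nrow(records) > 0L &&
      !all(records$gene_id == transcript$gene_id)) {
    stop("records from a different gene than the transcript")
  }
  n_cod <- transcript$n_codons
  mis <- records[records$consequence == "missense", , drop = FALSE]
  syn <- records[records$consequence == "synonymous", , drop = FALSE]
  z <- integer(n_cod)
  if (nrow(mis) > 0L) {
    tab <- table(factor(mis$codon_index, levels = seq_len(n_cod)))
    z <- as.integer(tab)
  }
  structure(list(gene_id = transcript$gene_id,
                 N = nrow(mis), S = nrow(syn),
                 S_N = sum(z > 0L),
                 S_S = length(unique(syn$cds_position)),
                 z = z),
            class = "gene_counts")
}

#' Gene-level CN/CS ratio
#'
#' CN/CS = (N / L_N) / (S / L_S): the nonsynonymous mutation rate per
#' expected nonsynonymous site over the synonymous rate per expected
#' synonymous site. Values above 1 indicate positive selection.
#'
#' @param N,S Observed missense and synonymous mutation counts.
#' @param L_N,L_S Rate-weighted site opportunities from [expected_sites()].
#' @param s_pseudocount Substituted for `S` when `S == 0` (default 0.5); the
#'   result then carries attribute `s_substituted = TRUE`.
#' @return The ratio, or `NA` (with attribute `reason`) when `N + S == 0`.
#' @export
compute_cncs <- function(N, S, L_N, L_S, s_pseudocount = 0.5) {
  stopifnot(L_N > 0, L_S > 0)
  if (N + S == 0) {
    return(structure(NA_real_, reason = "no missense or synonymous mutations"))
  }
  s_sub <- S == 0
  if (s_sub) S <- s_pseudocount
  structure((N / L_N) / (S / L_S), s_substituted = s_sub)
}

#' Among-site heterogeneity H of missense mutation counts
#'
#' H = (var(z) - mean(z)) / (var(z) + mean(z) * (mean(z) - 1)), clamped to
#' [0, 1], with the population variance (divisor n). H estimates
#' 1 - E[lambda]^2 / E[lambda^2] of the latent per-site rates: 0 when all
#' sites mutate at the same rate, approaching 1 when a few sites absorb most
#' mutations. The band (1 - H, 1) of CN/CS flags weak positive selection at
#' individual sites masked by constraint elsewhere.
#'
#' @param z Integer vector of per-codon missense counts (zeros included),
#'   length >= 2.
#' @param variance `"population"` (default) or `"sample"`.
#' @return H in [0, 1], or `NA` when `mean(z) == 0`.
#' @export
compute_H <- function(z, variance = c("population", "sample")) {
  variance <- match.arg(variance)
  stopifnot(length(z) >= 2L)
  zb <- mean(z)
  if (zb == 0) return(NA_real_)
  v <- stats::var(z)
  if (variance == "population") v <- v * (length(z) - 1) / length(z)
  raw <- (v - zb) / (v + zb * (zb - 1))
  if (!is.finite(raw)) raw <- 0
  min(1, max(0, raw))
}

#' Chi-square test of CN/CS against a null ratio
#'
#' Two-cell Pearson goodness-of-fit on the counts (N, S): under null ratio
#' rho the expected fractions are (rho * L_N, L_S) / (rho * L_N + L_S),
#' df = 1. For a one-sided alternative the two-sided p is halved when the
#' observed deviation lies in the tested direction and reported as
#' 1 - p/2 otherwise (never significant against the direction).
#'
#' @param N,S Observed counts; `N + S >= 1`.
#' @param L_N,L_S Site opportunities.
#' @param null_ratio The CN/CS value under the null (default 1).
#' @param alternative `"two.sided"`, `"greater"` (CN/CS > null) or `"less"`.
#' @return List: `statistic`, `p.value`, `small_expected` (TRUE when an
#'   expected cell is below 1; the test is still computed).
#' @export
cncs_chisq_test <- function(N, S, L_N, L_S, null_ratio = 1,
                            alternative = c("two.sided", "greater", "less")) {
  alternative <- match.arg(alternative)
  stopifnot(N + S >= 1, null_ratio > 0)
  tot <- N + S
  pN <- null_ratio * L_N / (null_ratio * L_N + L_S)
  expected <- tot * c(pN, 1 - pN)
  x2 <- sum((c(N, S) - expected)^2 / expected)
  p2 <- stats::pchisq(x2, df = 1, lower.tail = FALSE)
  p <- switch(alternative,
    two.sided = p2,
    greater = if (N >= expected[1L]) p2 / 2 else 1 - p2 / 2,
    less = if (N <= expected[1L]) p2 / 2 else 1 - p2 / 2)
  list(statistic = x2, p.value = p, small_expected = any(expected < 1))
}

#' Selection-mode label from gene-level statistics
#'
#' @param cncs CN/CS ratio.
#' @param H Heterogeneity in [0, 1].
#' @param p_vs_1 Two-sided p against null ratio 1.
#' @param p_vs_1mH Two-sided p against null ratio 1 - H.
#' @param alpha_level Significance level (default 0.05).
#' @return One of `"dominant_positive"` (CN/CS > 1, significant vs 1),
#'   `"weak_positive"` (1 - H < CN/CS < 1, significant vs 1 - H),
#'   `"negative"` (CN/CS < 1 - H, significant vs 1 - H) or
#'   `"neutral_or_undetermined"`.
#' @export
selection_mode <- function(cncs, H, p_vs_1, p_vs_1mH, alpha_level = 0.05) {
  if (any(is.na(c(cncs, H, p_vs_1)))) return("neutral_or_undetermined")
  if (cncs > 1 && p_vs_1 < alpha_level) return("dominant_positive")
  if (!is.na(p_vs_1mH)) {
    if (cncs > 1 - H && cncs < 1 && p_vs_1mH < alpha_level) {
      return("weak_positive")
    }
    if (cncs < 1 - H && p_vs_1mH < alpha_level) return("negative")
  }
  "neutral_or_undetermined"
}

#' Per-gene selection statistics table
#'
#' Runs [tally_gene()], [expected_sites()], [compute_cncs()], [compute_H()],
#' the chi-square tests against null ratios 1 and 1 - H, and
#' [selection_mode()] for every gene with at least one usable mutation.
#'
#' @param records Annotated mutation data frame (post filtering).
#' @param transcripts Named list of `coding_transcript`s.
#' @param spectrum A `context_spectrum`.
#' @param alpha_level Significance level for the mode label.
#' @param s_pseudocount Pseudocount policy for `S == 0` genes.
#' @return Data frame: gene, N, S, S_N, S_S, n_codons, L_N, L_S, cncs, H,
#'   p_vs_1, p_vs_1mH, mode, flags; plus attribute `z` (named list of
#'   per-codon missense count vectors).
#' @export
compute_gene_stats <- function(records, transcripts, spectrum,
                               alpha_level = 0.05, s_pseudocount = 0.5) {
  genes <- intersect(names(transcripts), unique(records$gene_id))
  genes <- sort(genes)
  rows <- vector("list", length(genes))
  zs <- vector("list", length(genes))
  names(zs) <- genes
  for (i in seq_along(genes)) {
    g <- genes[i]
    tr <- transcripts[[g]]
    cnt <- tally_gene(records[records$gene_id == g, , drop = FALSE], tr)
    ls_ <- expected_sites(tr, spectrum)
    flags <- character(0)
    if (cnt$N + cnt$S == 0) {
      rows[[i]] <- data.frame(gene_id = g, N = 0L, S = 0L, S_N = 0L, S_S = 0L,
                              n_codons = tr$n_codons, L_N = ls_$L_N,
                              L_S = ls_$L_S, cncs = NA_real_, H = NA_real_,
                              p_vs_1 = NA_real_, p_vs_1mH = NA_real_,
                              mode = "neutral_or_undetermined",
                              flags = "no_mutations", stringsAsFactors = FALSE)
      zs[[i]] <- cnt$z
      next
    }
    cncs <- compute_cncs(cnt$N, cnt$S, ls_$L_N, ls_$L_S, s_pseudocount)
    if (isTRUE(attr(cncs, "s_substituted"))) flags <- c(flags, "S0")
    H <- compute_H(cnt$z)
    t1 <- cncs_chisq_test(cnt$N, cnt$S, ls_$L_N, ls_$L_S, null_ratio = 1)
    if (t1$small_expected) flags <- c(flags, "small_expected")
    p1mH <- NA_real_
    if (!is.na(H) && H < 1) {
      t2 <- cncs_chisq_test(cnt$N, cnt$S, ls_$L_N, ls_$L_S,
                            null_ratio = 1 - H)
      p1mH <- t2$p.value
    } else if (!is.na(H)) {
      flags <- c(flags, "H1")
    }
    mode <- selection_mode(as.numeric(cncs), H, t1$p.value, p1mH, alpha_level)
    rows[[i]] <- data.frame(gene_id = g, N = cnt$N, S = cnt$S, S_N = cnt$S_N,
                            S_S = cnt$S_S, n_codons = tr$n_codons,
                            L_N = ls_$L_N, L_S = ls_$L_S,
                            cncs = as.numeric(cncs), H = H,
                            p_vs_1 = t1$p.value, p_vs_1mH = p1mH,
                            mode = mode,
                            flags = paste(flags, collapse = ";"),
                            stringsAsFactors = FALSE)
    zs[[i]] <- cnt$z
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  attr(out, "z") <- zs
  out
}
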