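# End-to-end orchestration: ingest -> spectrum -> gene stats -> mixture ->
# omega -> classification.

#' Pipeline run configuration
#'
#' @param maf Path to a MAF-style TSV, or an already-read data frame.
#' @param cds Path to a CDS FASTA, or a named list of `coding_transcript`s.
#' @param cancer_types Optional path/data frame with `sample_id`,
#'   `cancer_type` for hypermutator stratification.
#' @param transcript_table Optional path/data frame with `gene_id`,
#'   `transcript_id` overriding longest-CDS transcript selection.
#' @param out_dir Optional output directory for result TSVs.
#' @param alpha_level Significance level used throughout (default 0.05,
#'   raw p-values).
#' @param pseudocount Zero-denominator substitution (default 0.5).
#' @param spectrum_pseudocount Pseudocount of the spectrum fit (default 0.5).
#' @param mom_method Per-gene (m1, eta) estimator: `"ml"` (default;
#'   maximum likelihood at the global alpha, moment-initialized),
#'   `"printed"` or `"exact"` moment inversion.
#' @param lrt_df `"boundary"` (half chi-square(1)) or `"chisq2"`.
#' @param lrt_null `"profiled"` (null Poisson at the gene's MLE rate,
#'   default) or `"m0"` (fixed at the passenger rate).
#' @param minidriver_rule `"joint"` or `"methods_only"`.
#' @param dubious_filter Apply the dubious-gene exclusion (default TRUE).
#' @param dubious_list Genes to exclude (default [dubious_gene_defaults()]).
#' @param alpha_fallback Gamma shape used when no gene supports the global
#'   fit (default 1.51).
#' @param seed RNG seed recorded in the manifest (the pipeline itself is
#'   deterministic given its inputs).
#' @return List of class `run_config`.
#' @export
run_config <- function(maf, cds, cancer_types = NULL,
                       transcript_table = NULL, out_dir = NULL,
                       alpha_level = 0.05, pseudocount = 0.5,
                       spectrum_pseudocount = 0.5,
                       mom_method = c("ml", "printed", "exact"),
                       lrt_df = c("boundary", "chisq2"),
                       lrt_null = c("profiled", "m0"),
                       minidriver_rule = c("joint", "methods_only"),
                       dubious_filter = TRUE,
                       dubious_list = dubious_gene_defaults(),
                       alpha_fallback = 1.51, seed = 1L) {
  structure(list(maf = maf, cds = cds, cancer_types = cancer_types,
                 transcript_table = transcript_table, out_dir = out_dir,
                 alpha_level = alpha_level, pseudocount = pseudocount,
                 spectrum_pseudocount = spectrum_pseudocount,
                 mom_method = match.arg(mom_method),
                 lrt_df = match.arg(lrt_df),
                 lrt_null = match.arg(lrt_null),
                 minidriver_rule = match.arg(minidriver_rule),
                 dubious_filter = dubious_filter,
                 dubious_list = dubious_list,
                 alpha_fallback = alpha_fallback,
                 seed = as.integer(seed)),
            class = "run_config")
}

.read_tsv_maybe <- function(x) {
  if (is.character(x)) utils::read.delim(x, stringsAsFactors = FALSE) else x
}

#' Run the full selection-landscape pipeline
#'
#' Stage order: read inputs, annotate mutations, exclude hypermutators,
#' estimate the 96-class spectrum from synonymous mutations, compute
#' gene-level statistics (CN/CS, H, tests, mode), fit the global gamma shape
#' on genes passing a positive-selection gate, fit the per-gene mixture and
#' LRT, decompose selection into Omega components for genes with a driver
#' fraction, and classify. Equivalent to calling the stage functions in
#' sequence with the same parameters.
#'
#' @param config A `run_config`.
#' @return List of class `selscape_result`: `gene_stats`, `mixture`, `omega`,
#'   `sites` (per-site posteriors for genes with eta > 0),
#'   `classifications`, `spectrum`, `alpha`, `excluded_samples`, `manifest`.
#'   When `config$out_dir` is set, tables are also written there.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "run_config"))
  maf <- if (is.data.frame(config$maf) && "gene_id" %in% names(config$maf)) {
    config$maf  # already standardized
  } else {
    read_maf(config$maf)
  }
  transcripts <- if (is.character(config$cds)) {
    read_cds_fasta(config$cds, .read_tsv_maybe(config$transcript_table))
  } else config$cds
  ann <- annotate_mutations(maf, transcripts)
  cohort <- filter_hypermutators(ann, .read_tsv_maybe(config$cancer_types))
  records <- cohort$records

  spectrum <- estimate_context_rates(records, transcripts,
                                     pseudocount = config$spectrum_pseudocount)
  gene_stats <- compute_gene_stats(records, transcripts, spectrum,
                                   alpha_level = config$alpha_level,
                                   s_pseudocount = config$pseudocount)
  zs <- attr(gene_stats, "z")

  a <- config$alpha_level
  gate <- with(gene_stats,
               (!is.na(cncs) & !is.na(p_vs_1) & cncs > 1 & p_vs_1 < a) |
                 (!is.na(cncs) & !is.na(H) & !is.na(p_vs_1mH) &
                    cncs > 1 - H & cncs < 1 & p_vs_1mH < a))
  gated <- gene_stats$gene_id[gate]

  cohort_syn_rate <- sum(gene_stats$S) / sum(gene_stats$L_S)
  m0_of <- function(i) {
    estimate_m0(gene_stats$S[i], gene_stats$L_N[i], gene_stats$L_S[i],
                gene_stats$n_codons[i],
                cohort_syn_rate = cohort_syn_rate)
  }

  alpha_hat <- config$alpha_fallback
  alpha_info <- list(boundary = FALSE, fallback = TRUE, n_genes = 0L)
  if (length(gated)) {
    idx <- match(gated, gene_stats$gene_id)
    # cohort-calibrated baseline per gene: stable against the noise of
    # individual synonymous counts, which otherwise biases the alpha fit
    m0_stable <- cohort_syn_rate * gene_stats$L_N[idx] /
      gene_stats$n_codons[idx]
    fit <- fit_alpha_global(zs[gated], m0_stable,
                            method = config$mom_method,
                            fallback = config$alpha_fallback)
    alpha_hat <- fit$alpha
    alpha_info <- fit[c("boundary", "fallback", "n_genes")]
  }

  mix_rows <- list()
  omega_rows <- list()
  site_rows <- list()
  fits <- list()
  omegas <- list()
  for (g in gated) {
    i <- match(g, gene_stats$gene_id)
    m0 <- m0_of(i)
    fit <- fit_mixture(zs[[g]], as.numeric(m0), alpha_hat,
                       method = config$mom_method, df = config$lrt_df,
                       null = config$lrt_null)
    fits[[g]] <- fit
    mix_rows[[g]] <- data.frame(
      gene_id = g, m0 = fit$m0, m1 = fit$m1, eta = fit$eta,
      alpha = fit$alpha, lrt_stat = fit$lrt_stat, lrt_p = fit$lrt_p,
      flags = paste(c(if (isTRUE(attr(m0, "s_fallback"))) "S0_fallback",
                      if (fit$truncated) "eta_truncated"), collapse = ";"),
      stringsAsFactors = FALSE)
    if (fit$eta > 0) {
      counts <- list(N = gene_stats$N[i], S = gene_stats$S[i],
                     S_N = gene_stats$S_N[i], S_S = gene_stats$S_S[i],
                     z = zs[[g]])
      om <- omega_decompose(counts, fit, gene_stats$L_N[i],
                            gene_stats$L_S[i],
                            s_pseudocount = config$pseudocount)
      omegas[[g]] <- om
      omega_rows[[g]] <- data.frame(
        gene_id = g, omega_pass = om$omega_pass, omega_dri = om$omega_dri,
        ns_star = om$ns_star, p_pass_lt1 = om$p_pass_lt1,
        floored = om$floored, stringsAsFactors = FALSE)
      st <- om$sites
      st$gene_id <- g
      site_rows[[g]] <- st[, c("gene_id", "codon_index", "z_k", "Q_k",
                               "omega_k")]
    }
  }

  cls_rows <- lapply(seq_len(nrow(gene_stats)), function(i) {
    g <- gene_stats$gene_id[i]
    cl <- classify_gene(gene_stats[i, ], fits[[g]], omegas[[g]],
                        alpha_level = config$alpha_level,
                        minidriver_rule = config$minidriver_rule)
    data.frame(gene_id = g, label = cl$label, reason = cl$reason,
               cncs = gene_stats$cncs[i], H = gene_stats$H[i],
               p_vs_1 = gene_stats$p_vs_1[i],
               p_vs_1mH = gene_stats$p_vs_1mH[i],
               eta = if (!is.null(fits[[g]])) fits[[g]]$eta else NA_real_,
               lrt_p = if (!is.null(fits[[g]])) fits[[g]]$lrt_p else NA_real_,
               omega_pass = if (!is.null(omegas[[g]]))
                 omegas[[g]]$omega_pass else NA_real_,
               p_pass_lt1 = if (!is.null(omegas[[g]]))
                 omegas[[g]]$p_pass_lt1 else NA_real_,
               stringsAsFactors = FALSE)
  })
  classifications <- do.call(rbind, cls_rows)
  classifications <- filter_dubious(
    classifications,
    if (config$dubious_filter) config$dubious_list else character(0))

  stopifnot(!any(classifications$label == "conserved_mini_driver" &
                   !(classifications$cncs < 1)))

  manifest <- list(
    package = "selscape",
    version = as.character(utils::packageVersion("selscape")),
    alpha_level = config$alpha_level, pseudocount = config$pseudocount,
    mom_method = config$mom_method, lrt_df = config$lrt_df,
    lrt_null = config$lrt_null,
    minidriver_rule = config$minidriver_rule,
    dubious_filter = config$dubious_filter,
    dubious_list = paste(config$dubious_list, collapse = ","),
    alpha_hat = alpha_hat, alpha_boundary = alpha_info$boundary,
    alpha_fallback_used = alpha_info$fallback,
    n_genes = nrow(gene_stats), n_gated = length(gated),
    n_samples_excluded = nrow(cohort$excluded_samples),
    seed = config$seed)

  result <- list(
    gene_stats = gene_stats,
    mixture = if (length(mix_rows)) do.call(rbind, mix_rows) else NULL,
    omega = if (length(omega_rows)) do.call(rbind, omega_rows) else NULL,
    sites = if (length(site_rows)) do.call(rbind, site_rows) else NULL,
    classifications = classifications,
    spectrum = spectrum, alpha = alpha_hat,
    excluded_samples = cohort$excluded_samples,
    manifest = manifest)
  class(result) <- "selscape_result"

  if (!is.null(config$out_dir)) {
    dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
    utils::write.table(gene_stats, file.path(config$out_dir,
                                             "gene_stats.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    for (nm in c("mixture", "omega", "sites")) {
      if (!is.null(result[[nm]])) {
        df <- result[[nm]]
        rownames(df) <- NULL
        utils::write.table(df, file.path(config$out_dir,
                                         paste0(nm, ".tsv")),
                           sep = "\t", quote = FALSE, row.names = FALSE)
      }
    }
    write_spectrum(spectrum, file.path(config$out_dir, "spectrum.tsv"))
    write_results(classifications, config$out_dir, manifest)
  }
  result
}
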