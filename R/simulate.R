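# Synthetic-cohort generator with known ground truth. Emits the same MAF and
# FASTA dialects the ingest module reads, so the whole pipeline is testable
# without external data.

#' Simulation configuration
#'
#' Defaults are the standard recovery scenario: 500 genes of 500 codons with
#' a 1% driver-site fraction, passenger rate 0.05 missense mutations per
#' codon, driver mean rate 5 and gamma shape 1.51 (the published pan-cancer
#' estimate).
#'
#' @param n_genes Number of genes.
#' @param n_codons Sense codons per gene (scalar or per-gene vector).
#' @param eta Driver-site fraction in [0, 1].
#' @param m0 Passenger per-codon missense rate.
#' @param m1 Mean driver rate (> m0 when eta > 0); the gamma scale is
#'   beta = alpha / (m1 - m0).
#' @param alpha Gamma shape of the among-driver-site rate distribution.
#' @param spectrum `context_spectrum` used to place mutations (default
#'   uniform).
#' @param n_samples Number of tumor samples mutations are assigned to.
#' @param seed Mandatory RNG seed.
#' @param gene_prefix Prefix of generated gene ids (default "G"); lets
#'   cohorts simulated under different parameters be merged without id
#'   clashes.
#' @return List of class `simulation_config`.
#' @export
simulation_config <- function(n_genes = 500, n_codons = 500, eta = 0.01,
                              m0 = 0.05, m1 = 5, alpha = 1.51,
                              spectrum = NULL, n_samples = 100, seed,
                              gene_prefix = "G") {
  problems <- character(0)
  if (missing(seed) || !is.numeric(seed)) problems <- c(problems, "seed")
  if (!is.numeric(eta) || eta < 0 || eta > 1) problems <- c(problems, "eta")
  if (!is.numeric(m0) || m0 < 0) problems <- c(problems, "m0")
  if (!is.numeric(alpha) || alpha <= 0) problems <- c(problems, "alpha")
  if (eta > 0 && (!is.numeric(m1) || m1 <= m0)) problems <- c(problems, "m1")
  if (any(n_codons < 2) || n_genes < 1) problems <- c(problems, "n_genes/n_codons")
  if (length(problems)) {
    stop("invalid simulation config field(s): ", paste(problems, collapse = ", "))
  }
  structure(list(n_genes = n_genes, n_codons = n_codons, eta = eta, m0 = m0,
                 m1 = m1, alpha = alpha,
                 spectrum = if (is.null(spectrum)) uniform_spectrum()
                            else spectrum,
                 n_samples = n_samples, seed = as.integer(seed),
                 gene_prefix = gene_prefix),
            class = "simulation_config")
}

#' Simulate per-codon missense counts under the two-component model
#'
#' Count-level generator (no sequences): each codon is independently a
#' driver site with probability `eta`; passenger counts are Poisson(m0),
#' driver counts Poisson(m0 + lambda) with lambda ~ Gamma(alpha,
#' rate = alpha / (m1 - m0)). Uses the current RNG state; callers seed.
#'
#' @param n_genes,n_codons Cohort dimensions (`n_codons` recycled per gene).
#' @param eta,m0,m1,alpha Model parameters.
#' @return List with elements `z`, `driver`, `lambda`: lists of per-gene
#'   vectors.
#' @export
simulate_site_counts <- function(n_genes, n_codons, eta, m0, m1, alpha) {
  n_codons <- rep_len(n_codons, n_genes)
  z <- driver <- lambda <- vector("list", n_genes)
  beta <- if (eta > 0) alpha / (m1 - m0) else NA_real_
  for (g in seq_len(n_genes)) {
    n <- n_codons[g]
    d <- stats::runif(n) < eta
    lam <- numeric(n)
    if (any(d)) lam[d] <- stats::rgamma(sum(d), shape = alpha, rate = beta)
    z[[g]] <- stats::rpois(n, m0 + lam)
    driver[[g]] <- d
    lambda[[g]] <- lam
  }
  list(z = z, driver = driver, lambda = lambda)
}

# Random CDS of n sense codons plus a terminal stop.
.random_cds <- function(n_codons) {
  paste0(paste(sample(.sense_codons(), n_codons, replace = TRUE),
               collapse = ""), "TAA")
}

#' Simulate a full synthetic cohort (MAF + CDS FASTA + ground truth)
#'
#' Coding sequences are random sense codons. Per-codon missense counts
#' follow [simulate_site_counts()]; each missense event is realized as a
#' specific single-nucleotide change of its codon, drawn with probability
#' proportional to the spectrum rate of the change's context class.
#' Synonymous mutations arrive with gene-level intensity
#' `m0 * n_codons * L_S / L_N` (so neutral genes have expected CN/CS = 1 by
#' construction) and are placed over the synonymous opportunities, spectrum-
#' weighted. Mutations are assigned to samples uniformly at random.
#'
#' @param config A `simulation_config`.
#' @param dir Optional directory; when given, `maf.tsv`, `cds.fa`,
#'   `truth_genes.tsv` and `truth_sites.tsv` are written there.
#' @return List: `maf` (data frame in the MC3 column dialect),
#'   `transcripts`, `truth_genes`, `truth_sites`, `spectrum`, `config`,
#'   and `paths` when `dir` was given.
#' @export
simulate_cohort <- function(config, dir = NULL) {
  stopifnot(inherits(config, "simulation_config"))
  set.seed(config$seed)
  n_codons <- rep_len(config$n_codons, config$n_genes)
  genes <- sprintf("%s%04d", config$gene_prefix, seq_len(config$n_genes))
  samples <- sprintf("S%04d", seq_len(config$n_samples))
  spectrum <- config$spectrum

  transcripts <- list()
  maf_rows <- vector("list", config$n_genes)
  truth_g <- vector("list", config$n_genes)
  truth_s <- vector("list", config$n_genes)
  counts <- simulate_site_counts(config$n_genes, n_codons, config$eta,
                                 config$m0, config$m1, config$alpha)
  for (g in seq_len(config$n_genes)) {
    gene <- genes[g]
    tr <- coding_transcript(gene, paste0(gene, ".t1"),
                            .random_cds(n_codons[g]))
    transcripts[[gene]] <- tr
    ec <- .enumerate_changes(tr)
    cls <- collapse_context(ec$flank5, ec$ref, ec$alt, ec$flank3)
    ec$rate <- ifelse(is.na(cls), 1, unname(spectrum[cls]))
    L_N <- sum(ec$rate[ec$consequence == "missense"])
    L_S <- sum(ec$rate[ec$consequence == "synonymous"])
    z <- counts$z[[g]]

    mis <- ec[ec$consequence == "missense", , drop = FALSE]
    picked <- integer(0)
    hot <- which(z > 0L)
    for (k in hot) {
      cand <- which(mis$codon_index == k)
      picked <- c(picked, if (length(cand) == 1L) rep(cand, z[k]) else
        sample(cand, z[k], replace = TRUE, prob = mis$rate[cand]))
    }
    mis_rows <- mis[picked, , drop = FALSE]

    syn <- ec[ec$consequence == "synonymous", , drop = FALSE]
    n_syn <- if (nrow(syn) > 0L && L_N > 0) {
      stats::rpois(1L, config$m0 * n_codons[g] * L_S / L_N)
    } else 0L
    syn_rows <- if (n_syn > 0L) {
      syn[sample(nrow(syn), n_syn, replace = TRUE, prob = syn$rate), ,
          drop = FALSE]
    } else syn[0L, , drop = FALSE]

    ev <- rbind(mis_rows, syn_rows)
    n_ev <- nrow(ev)
    maf_rows[[g]] <- data.frame(
      Tumor_Sample_Barcode = if (n_ev) sample(samples, n_ev, replace = TRUE)
                             else character(0),
      Hugo_Symbol = rep(gene, n_ev),
      Transcript_ID = rep(tr$transcript_id, n_ev),
      Variant_Classification = c(rep("Missense_Mutation", nrow(mis_rows)),
                                 rep("Silent", nrow(syn_rows))),
      CDS_position = ev$cds_position,
      Reference_Allele = ev$ref,
      Tumor_Seq_Allele2 = ev$alt,
      stringsAsFactors = FALSE)
    truth_g[[g]] <- data.frame(
      gene_id = gene, n_codons = n_codons[g], eta = config$eta,
      m0 = config$m0, m1 = config$m1, alpha = config$alpha,
      n_driver_sites = sum(counts$driver[[g]]), L_N = L_N, L_S = L_S,
      stringsAsFactors = FALSE)
    truth_s[[g]] <- data.frame(
      gene_id = gene, codon_index = seq_len(n_codons[g]),
      driver = counts$driver[[g]], lambda = counts$lambda[[g]], z = z,
      stringsAsFactors = FALSE)
  }
  maf <- do.call(rbind, maf_rows)
  rownames(maf) <- NULL
  out <- list(maf = maf, transcripts = transcripts,
              truth_genes = do.call(rbind, truth_g),
              truth_sites = do.call(rbind, truth_s),
              spectrum = spectrum, config = config)
  if (!is.null(dir)) {
    if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
    maf_path <- file.path(dir, "maf.tsv")
    utils::write.table(maf, maf_path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    fa <- Biostrings::DNAStringSet(vapply(out$transcripts, `[[`, "",
                                          "cds_sequence"))
    names(fa) <- vapply(out$transcripts, function(tr)
      paste0(tr$transcript_id, " cds gene:", tr$gene_id), "")
    fa_path <- file.path(dir, "cds.fa")
    Biostrings::writeXStringSet(fa, fa_path)
    tg_path <- file.path(dir, "truth_genes.tsv")
    ts_path <- file.path(dir, "truth_sites.tsv")
    utils::write.table(out$truth_genes, tg_path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    utils::write.table(out$truth_sites, ts_path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    out$paths <- c(maf = maf_path, cds = fa_path, truth_genes = tg_path,
                   truth_sites = ts_path)
  }
  out
}

#' Parameter-recovery report against simulation ground truth
#'
#' @param truth_genes Ground-truth table from [simulate_cohort()]; may carry
#'   a `label_true` column.
#' @param estimates Data frame with `gene_id` and any of `eta_hat`,
#'   `m1_hat`, `m0_hat`; optionally `label`.
#' @return List: `params` (per-parameter bias, RMSE and median relative
#'   error over genes where both truth and estimate are finite) and
#'   `confusion` (label table, or `NULL` when labels are absent).
#' @export
recovery_report <- function(truth_genes, estimates) {
  if (!setequal(truth_genes$gene_id, estimates$gene_id)) {
    stop("gene sets of truth and estimates differ")
  }
  m <- merge(truth_genes, estimates, by = "gene_id")
  params <- list()
  for (p in c("eta", "m0", "m1")) {
    hat <- paste0(p, "_hat")
    if (!hat %in% names(m) || !p %in% names(m)) next
    ok <- is.finite(m[[p]]) & is.finite(m[[hat]])
    if (!any(ok)) next
    err <- m[[hat]][ok] - m[[p]][ok]
    params[[p]] <- data.frame(
      parameter = p, n = sum(ok), bias = mean(err),
      rmse = sqrt(mean(err^2)),
      median_rel_error = stats::median(err / m[[p]][ok]),
      stringsAsFactors = FALSE)
  }
  confusion <- NULL
  if ("label_true" %in% names(m) && "label" %in% names(m)) {
    confusion <- table(truth = m$label_true, predicted = m$label)
  }
  list(params = do.call(rbind, params), confusion = confusion)
}
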