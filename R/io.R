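# Ingest: MAF-style mutation tables, CDS FASTA, mutation annotation and
# cohort-level sample filters.

#' Default MAF column mapping (TCGA MC3 dialect)
#'
#' @return Named list mapping logical fields to MAF column names. `position`
#'   may name a numeric CDS-position column; when absent from the file, the
#'   `hgvsc` column (e.g. `"c.215C>G"`) is parsed instead.
#' @export
maf_column_defaults <- function() {
  list(sample = "Tumor_Sample_Barcode",
       gene = "Hugo_Symbol",
       transcript = "Transcript_ID",
       classification = "Variant_Classification",
       ref = "Reference_Allele",
       alt = "Tumor_Seq_Allele2",
       position = "CDS_position",
       hgvsc = "HGVSc")
}

# MC3 Variant_Classification -> coarse consequence class
.classification_map <- c(
  Silent = "synonymous",
  Missense_Mutation = "missense"
)

#' Read a MAF-style tab-separated mutation file
#'
#' Only column resolution and coarse classification happen here; codon-level
#' annotation against the CDS is done by [annotate_mutations()].
#'
#' @param path Path to a tab-separated file with a header line, or an
#'   already-read data frame in the same column dialect.
#' @param column_map Named list as returned by [maf_column_defaults()].
#' @return Data frame with columns `sample_id`, `gene_id`, `transcript_id`,
#'   `maf_class` (the verbatim classification), `consequence` (mapped to
#'   synonymous/missense/other), `cds_position`, `ref`, `alt`. One row per
#'   input mutation line; a header-only file yields zero rows.
#' @export
read_maf <- function(path, column_map = maf_column_defaults()) {
  if (is.data.frame(path)) {
    raw <- path
  } else {
    if (!file.exists(path)) stop("MAF file not found: ", path)
    raw <- utils::read.delim(path, stringsAsFactors = FALSE,
                             check.names = FALSE, comment.char = "#")
  }
  required <- c("sample", "gene", "classification", "ref", "alt")
  for (field in required) {
    col <- column_map[[field]]
    if (is.null(col) || !col %in% names(raw)) {
      stop("required MAF column missing: ", field,
           " (expected column '", column_map[[field]], "')")
    }
  }
  pos_col <- column_map$position
  hgvsc_col <- column_map$hgvsc
  if ((is.null(pos_col) || !pos_col %in% names(raw)) &&
      (is.null(hgvsc_col) || !hgvsc_col %in% names(raw))) {
    stop("required MAF column missing: position ",
         "(neither '", pos_col, "' nor '", hgvsc_col, "' present)")
  }
  n <- nrow(raw)
  cds_position <- rep(NA_integer_, n)
  if (!is.null(pos_col) && pos_col %in% names(raw)) {
    cds_position <- suppressWarnings(as.integer(raw[[pos_col]]))
  } else if (n > 0L) {
    m <- regmatches(raw[[hgvsc_col]],
                    regexpr("c\\.([0-9]+)", raw[[hgvsc_col]]))
    got <- lengths(regmatches(raw[[hgvsc_col]],
                              gregexpr("c\\.[0-9]+", raw[[hgvsc_col]]))) > 0
    cds_position[got] <- as.integer(sub("c\\.", "", m))
  }
  maf_class <- as.character(raw[[column_map$classification]])
  consequence <- unname(.classification_map[maf_class])
  consequence[is.na(consequence)] <- "other"
  tr <- if (!is.null(column_map$transcript) &&
            column_map$transcript %in% names(raw)) {
    as.character(raw[[column_map$transcript]])
  } else rep(NA_character_, n)
  data.frame(sample_id = as.character(raw[[column_map$sample]]),
             gene_id = as.character(raw[[column_map$gene]]),
             transcript_id = tr,
             maf_class = maf_class,
             consequence = consequence,
             cds_position = cds_position,
             ref = toupper(as.character(raw[[column_map$ref]])),
             alt = toupper(as.character(raw[[column_map$alt]])),
             stringsAsFactors = FALSE)
}

#' Construct a coding transcript
#'
#' @param gene_id,transcript_id Identifiers.
#' @param cds_sequence CDS on the coding strand, uppercase ACGT, length
#'   divisible by 3. A terminal stop codon, when present, is excluded from
#'   `n_codons` (mutation-site accounting covers sense codons only).
#' @return A `coding_transcript` list.
#' @export
coding_transcript <- function(gene_id, transcript_id, cds_sequence) {
  cds_sequence <- toupper(cds_sequence)
  len <- nchar(cds_sequence)
  if (len %% 3L != 0L) stop("CDS length not divisible by 3: ", transcript_id)
  if (grepl("[^ACGT]", cds_sequence)) {
    stop("CDS contains non-ACGT characters: ", transcript_id)
  }
  n <- len %/% 3L
  last <- substr(cds_sequence, len - 2L, len)
  if (.genetic_code()[[last]] == "*") n <- n - 1L
  if (n < 1L) stop("CDS has no sense codon: ", transcript_id)
  structure(list(gene_id = gene_id, transcript_id = transcript_id,
                 cds_sequence = cds_sequence, n_codons = n),
            class = "coding_transcript")
}

#' Read CDS sequences from FASTA, selecting one transcript per gene
#'
#' Headers are parsed as `<transcript_id> [... gene:<gene_id> ...]` (Ensembl
#' CDS dialect); a `gene_symbol:` tag is preferred when present, and the
#' transcript id doubles as the gene id when no gene tag exists. Records
#' whose length is not a multiple of 3, or that contain ambiguous bases, are
#' skipped with a warning. Per gene, the transcript named in
#' `transcript_table` is kept when given; otherwise the longest CDS (ties
#' broken by lexicographically smallest transcript id).
#'
#' @param path FASTA file path.
#' @param transcript_table Optional data frame with columns `gene_id`,
#'   `transcript_id`.
#' @return Named list of `coding_transcript` objects, keyed by gene id.
#' @export
read_cds_fasta <- function(path, transcript_table = NULL) {
  seqs <- Biostrings::readDNAStringSet(path)
  if (length(seqs) == 0L) stop("no parseable FASTA record in ", path)
  headers <- names(seqs)
  transcript_id <- sub("\\s.*$", "", headers)
  tag_value <- function(h, tag) {
    pat <- paste0("(^|\\s)", tag, ":(\\S+)")
    m <- regexec(pat, h)
    vapply(regmatches(h, m), function(x)
      if (length(x)) x[3L] else NA_character_, "")
  }
  gene_id <- tag_value(headers, "gene_symbol")
  plain <- tag_value(headers, "gene")
  gene_id[is.na(gene_id)] <- plain[is.na(gene_id)]
  gene_id[is.na(gene_id)] <- transcript_id[is.na(gene_id)]
  seq_chr <- toupper(as.character(seqs))
  keep <- nchar(seq_chr) %% 3L == 0L & !grepl("[^ACGT]", seq_chr)
  if (any(!keep)) {
    warning(sum(!keep), " FASTA record(s) skipped ",
            "(length not divisible by 3 or ambiguous bases)")
  }
  df <- data.frame(gene_id = gene_id[keep], transcript_id = transcript_id[keep],
                   seq = seq_chr[keep], len = nchar(seq_chr[keep]),
                   stringsAsFactors = FALSE)
  if (nrow(df) == 0L) stop("no usable CDS record in ", path)
  out <- list()
  for (g in unique(df$gene_id)) {
    cand <- df[df$gene_id == g, , drop = FALSE]
    pick <- NULL
    if (!is.null(transcript_table)) {
      want <- transcript_table$transcript_id[transcript_table$gene_id == g]
      if (length(want) && any(cand$transcript_id %in% want)) {
        pick <- cand[cand$transcript_id %in% want, , drop = FALSE][1L, ]
      }
    }
    if (is.null(pick)) {
      cand <- cand[order(-cand$len, cand$transcript_id), , drop = FALSE]
      pick <- cand[1L, ]
    }
    out[[g]] <- coding_transcript(g, pick$transcript_id, pick$seq)
  }
  out
}

#' Annotate a single mutation against its transcript
#'
#' Recomputes the consequence from the standard genetic code by substituting
#' `alt` into the codon at `cds_position`, and derives the 96-class context
#' from the CDS (or from the supplied flanks at CDS edges).
#'
#' @param transcript A `coding_transcript`.
#' @param cds_position 1-based position within the CDS, at most
#'   `3 * n_codons`.
#' @param ref,alt Reference and alternate base on the coding strand.
#' @param flank5,flank3 Optional flanking bases used only when the position
#'   sits at a CDS edge.
#' @return One-row data frame (see [annotate_mutations()]), or `NULL` with a
#'   warning when `ref` does not match the CDS.
#' @export
annotate_mutation <- function(transcript, cds_position, ref, alt,
                              flank5 = NULL, flank3 = NULL) {
  stopifnot(inherits(transcript, "coding_transcript"))
  L <- 3L * transcript$n_codons
  if (cds_position < 1L || cds_position > L) {
    stop("cds_position out of range [1, ", L, "]: ", cds_position)
  }
  cds <- transcript$cds_sequence
  if (substr(cds, cds_position, cds_position) != ref) {
    warning("reference mismatch at ", transcript$gene_id, ":", cds_position,
            " (CDS has ", substr(cds, cds_position, cds_position),
            ", MAF says ", ref, "); record dropped")
    return(NULL)
  }
  codon_index <- (cds_position - 1L) %/% 3L + 1L
  pos_in_codon <- (cds_position - 1L) %% 3L + 1L
  codon <- substr(cds, 3L * codon_index - 2L, 3L * codon_index)
  cons <- codon_consequence(codon, pos_in_codon, alt)
  f5 <- if (cds_position > 1L) {
    substr(cds, cds_position - 1L, cds_position - 1L)
  } else if (!is.null(flank5)) flank5 else NA_character_
  f3 <- if (cds_position < nchar(cds)) {
    substr(cds, cds_position + 1L, cds_position + 1L)
  } else if (!is.null(flank3)) flank3 else NA_character_
  data.frame(sample_id = NA_character_, gene_id = transcript$gene_id,
             transcript_id = transcript$transcript_id,
             cds_position = as.integer(cds_position),
             codon_index = codon_index, ref = ref, alt = alt,
             consequence = cons,
             context_class = collapse_context(f5, ref, alt, f3),
             stringsAsFactors = FALSE)
}

#' Annotate a MAF table against selected transcripts
#'
#' Rows for genes without a transcript, with a CDS position outside the sense
#' codons, with missing/invalid alleles, or whose reference base disagrees
#' with the CDS are dropped; the counts are reported in one warning.
#'
#' @param maf Data frame from [read_maf()] (or the same columns).
#' @param transcripts Named list from [read_cds_fasta()].
#' @return Annotated mutation data frame with columns `sample_id`, `gene_id`,
#'   `transcript_id`, `cds_position`, `codon_index`, `ref`, `alt`,
#'   `consequence` (recomputed from the genetic code), `context_class`.
#' @export
annotate_mutations <- function(maf, transcripts) {
  gene_ok <- maf$gene_id %in% names(transcripts)
  base_ok <- maf$ref %in% .BASES & maf$alt %in% .BASES & maf$ref != maf$alt &
    !is.na(maf$cds_position)
  df <- maf[gene_ok & base_ok, , drop = FALSE]
  n_no_gene <- sum(!gene_ok)
  n_bad_allele <- sum(gene_ok & !base_ok)

  if (nrow(df) == 0L) {
    if (n_no_gene + n_bad_allele > 0L) {
      warning("dropped ", n_no_gene, " record(s) without a transcript and ",
              n_bad_allele, " with unusable alleles/positions")
    }
    return(.empty_annotated())
  }
  cds <- vapply(transcripts[df$gene_id], `[[`, "", "cds_sequence")
  tr_id <- vapply(transcripts[df$gene_id], `[[`, "", "transcript_id")
  n_cod <- vapply(transcripts[df$gene_id], `[[`, 1L, "n_codons")
  in_range <- df$cds_position >= 1L & df$cds_position <= 3L * n_cod
  ref_cds <- substr(cds, df$cds_position, df$cds_position)
  ref_match <- in_range & ref_cds == df$ref
  n_range <- sum(!in_range)
  n_mismatch <- sum(in_range & !ref_match)
  if (n_no_gene + n_bad_allele + n_range + n_mismatch > 0L) {
    warning("dropped ", n_no_gene, " record(s) without a transcript, ",
            n_bad_allele, " with unusable alleles/positions, ",
            n_range, " out of CDS range, ",
            n_mismatch, " with reference mismatches")
  }
  df <- df[ref_match, , drop = FALSE]
  cds <- cds[ref_match]
  tr_id <- tr_id[ref_match]
  if (nrow(df) == 0L) return(.empty_annotated())
  pos <- df$cds_position
  codon_index <- (pos - 1L) %/% 3L + 1L
  pos_in_codon <- (pos - 1L) %% 3L + 1L
  codon <- substr(cds, 3L * codon_index - 2L, 3L * codon_index)
  cons <- codon_consequence(codon, pos_in_codon, df$alt)
  f5 <- ifelse(pos > 1L, substr(cds, pos - 1L, pos - 1L), NA_character_)
  f3 <- ifelse(pos < nchar(cds), substr(cds, pos + 1L, pos + 1L),
               NA_character_)
  data.frame(sample_id = df$sample_id, gene_id = df$gene_id,
             transcript_id = tr_id,
             cds_position = as.integer(pos), codon_index = codon_index,
             ref = df$ref, alt = df$alt, consequence = cons,
             context_class = collapse_context(f5, df$ref, df$alt, f3),
             stringsAsFactors = FALSE, row.names = NULL)
}

.empty_annotated <- function() {
  data.frame(sample_id = character(), gene_id = character(),
             transcript_id = character(), cds_position = integer(),
             codon_index = integer(), ref = character(), alt = character(),
             consequence = character(), context_class = character(),
             stringsAsFactors = FALSE)
}

#' Exclude hypermutator samples by a per-cancer-type Tukey fence
#'
#' A sample is excluded if and only if its total mutation count exceeds
#' Q3 + 1.5 * IQR of the per-sample counts within its cancer type AND exceeds
#' `max_mutations` (default 1000); both conditions are required. Quartiles
#' use linear interpolation (type 7). Strata with fewer than 4 samples fall
#' back to the whole-cohort fence.
#'
#' @param records Mutation data frame with a `sample_id` column (annotated or
#'   raw).
#' @param cancer_types Optional data frame with columns `sample_id`,
#'   `cancer_type`; samples without a type form their own stratum.
#' @param max_mutations Absolute floor for exclusion (default 1000).
#' @return List of class `cohort_dataset`: `records` (retained rows),
#'   `samples` (per-sample count, cancer type, excluded flag),
#'   `excluded_samples` (sample, count, reason).
#' @export
filter_hypermutators <- function(records, cancer_types = NULL,
                                 max_mutations = 1000) {
  counts <- table(records$sample_id)
  samples <- data.frame(sample_id = names(counts),
                        n_mutations = as.integer(counts),
                        stringsAsFactors = FALSE)
  if (!is.null(cancer_types)) {
    samples$cancer_type <- cancer_types$cancer_type[
      match(samples$sample_id, cancer_types$sample_id)]
  } else {
    samples$cancer_type <- rep(NA_character_, nrow(samples))
  }
  samples$cancer_type[is.na(samples$cancer_type)] <- "(untyped)"
  fence_of <- function(x) {
    stats::quantile(x, 0.75, type = 7, names = FALSE) + 1.5 * stats::IQR(x, type = 7)
  }
  global_fence <- fence_of(samples$n_mutations)
  samples$fence <- NA_real_
  for (ct in unique(samples$cancer_type)) {
    idx <- samples$cancer_type == ct
    if (sum(idx) < 4L) {
      message("stratum '", ct, "' has <4 samples; using whole-cohort fence")
      samples$fence[idx] <- global_fence
    } else {
      samples$fence[idx] <- fence_of(samples$n_mutations[idx])
    }
  }
  samples$excluded <- samples$n_mutations > samples$fence &
    samples$n_mutations > max_mutations
  excluded <- samples[samples$excluded, c("sample_id", "n_mutations",
                                          "cancer_type", "fence")]
  excluded$reason <- sprintf("count %d > fence %.1f and > %d",
                             excluded$n_mutations, excluded$fence,
                             max_mutations)
  keep <- !(records$sample_id %in% excluded$sample_id)
  structure(list(records = records[keep, , drop = FALSE],
                 samples = samples,
                 excluded_samples = excluded),
            class = "cohort_dataset")
}

#' Write / read annotated mutation records as TSV
#'
#' Fixed column order; reading back reproduces the records exactly.
#'
#' @param records Annotated mutation data frame.
#' @param path File path.
#' @export
write_mutation_records <- function(records, path) {
  cols <- c("sample_id", "gene_id", "transcript_id", "cds_position",
            "codon_index", "ref", "alt", "consequence", "context_class")
  utils::write.table(records[, cols], path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' @rdname write_mutation_records
#' @export
read_mutation_records <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  df$cds_position <- as.integer(df$cds_position)
  df$codon_index <- as.integer(df$codon_index)
  df$context_class <- as.character(df$context_class)
  df$context_class[df$context_class == "NA"] <- NA_character_
  df
}
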