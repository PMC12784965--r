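# Three-way gene classification (driver / mini-driver / conserved
# mini-driver) and result writing.

#' Default list of recurrently false-positive ("dubious") genes
#'
#' Large or late-replicating genes that accumulate passenger mutations and
#' are nominated as drivers by many frequency-based methods.
#'
#' @return Character vector of gene symbols.
#' @export
dubious_gene_defaults <- function() {
  c("TTN", "FLG", "PCLO", "CSMD3", "CNTN5", "LRP1B")
}

#' Classify one gene from its three analysis layers
#'
#' Driver: positive selection at gene level (CN/CS > 1, chi-square p < alpha)
#' and at site level (eta > 0, LRT p < alpha). Mini-driver: weak positive
#' selection (1 - H < CN/CS < 1, chi-square vs 1 - H p < alpha) and, under
#' the default `"joint"` rule, also a significant driver component;
#' `"methods_only"` drops the mixture requirement. Conserved mini-driver: a
#' mini-driver whose passenger component is under significant negative
#' selection (Omega_pass < 1, one-sided p < alpha).
#'
#' @param stats List or one-row data frame with `cncs`, `H`, `p_vs_1`,
#'   `p_vs_1mH`.
#' @param fit `mixture_fit` (or list with `eta`, `lrt_p`); may be `NULL` when
#'   the gene failed both positive-selection gates.
#' @param omega `omega_decomposition` (or list with `omega_pass`,
#'   `p_pass_lt1`); may be `NULL`.
#' @param alpha_level Significance level (default 0.05).
#' @param minidriver_rule `"joint"` (default) or `"methods_only"`.
#' @return List: `label` in driver / mini_driver / conserved_mini_driver /
#'   unclassified, and `reason` for unclassified genes.
#' @export
classify_gene <- function(stats, fit = NULL, omega = NULL,
                          alpha_level = 0.05,
                          minidriver_rule = c("joint", "methods_only")) {
  minidriver_rule <- match.arg(minidriver_rule)
  cncs <- stats$cncs; H <- stats$H
  p1 <- stats$p_vs_1; p1mH <- stats$p_vs_1mH
  if (is.na(cncs)) return(list(label = "unclassified", reason = "no_cncs"))
  gene_pos <- !is.na(p1) && cncs > 1 && p1 < alpha_level
  weak_pos <- !is.na(H) && !is.na(p1mH) &&
    cncs > 1 - H && cncs < 1 && p1mH < alpha_level
  site_pos <- !is.null(fit) && !is.na(fit$eta) && fit$eta > 0 &&
    !is.na(fit$lrt_p) && fit$lrt_p < alpha_level
  if (gene_pos) {
    if (site_pos) return(list(label = "driver", reason = NA_character_))
    return(list(label = "unclassified",
                reason = if (is.null(fit)) "missing_mixture_layer"
                         else "no_significant_driver_component"))
  }
  if (weak_pos) {
    mini <- if (minidriver_rule == "joint") site_pos else TRUE
    if (mini && minidriver_rule == "joint" && is.null(fit)) {
      return(list(label = "unclassified", reason = "missing_mixture_layer"))
    }
    if (mini) {
      conserved <- !is.null(omega) && !is.na(omega$omega_pass) &&
        omega$omega_pass < 1 && !is.na(omega$p_pass_lt1) &&
        omega$p_pass_lt1 < alpha_level
      return(list(label = if (conserved) "conserved_mini_driver"
                          else "mini_driver",
                  reason = NA_character_))
    }
    return(list(label = "unclassified",
                reason = if (is.null(fit)) "missing_mixture_layer"
                         else "no_significant_driver_component"))
  }
  list(label = "unclassified", reason = "no_positive_selection")
}

#' Flag dubious genes and exclude them from the driver output
#'
#' @param classifications Data frame with `gene_id` and `label` columns.
#' @param gene_list Genes to flag (default [dubious_gene_defaults()]); an
#'   empty vector disables the filter.
#' @return The data frame with a `dubious_filtered` logical column.
#' @export
filter_dubious <- function(classifications,
                           gene_list = dubious_gene_defaults()) {
  classifications$dubious_filtered <-
    classifications$gene_id %in% gene_list
  classifications
}

#' Write classification result tables
#'
#' Emits deterministic, gene-sorted TSVs: `all_genes.tsv`, `drivers.tsv`,
#' `mini_drivers.tsv`, `conserved_mini_drivers.tsv` (conserved mini-drivers
#' also appear in the mini-driver table, whose criteria they satisfy), and a
#' flat `manifest.txt` of run parameters. Dubious-filtered genes are dropped
#' from the driver table but kept, flagged, in `all_genes.tsv`.
#'
#' @param classifications Data frame from the pipeline (must include
#'   `gene_id`, `label`, `dubious_filtered`).
#' @param dir Output directory (created if needed).
#' @param manifest Named list or vector of run parameters.
#' @return Invisibly, the paths written.
#' @export
write_results <- function(classifications, dir, manifest = list()) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  cl <- classifications[order(classifications$gene_id), , drop = FALSE]
  rownames(cl) <- NULL
  w <- function(df, name) {
    p <- file.path(dir, name)
    utils::write.table(df, p, sep = "\t", quote = FALSE, row.names = FALSE)
    p
  }
  paths <- c(
    w(cl, "all_genes.tsv"),
    w(cl[cl$label == "driver" & !cl$dubious_filtered, , drop = FALSE],
      "drivers.tsv"),
    w(cl[cl$label %in% c("mini_driver", "conserved_mini_driver") &
           !cl$dubious_filtered, , drop = FALSE], "mini_drivers.tsv"),
    w(cl[cl$label == "conserved_mini_driver" & !cl$dubious_filtered, ,
         drop = FALSE], "conserved_mini_drivers.tsv"))
  mpath <- file.path(dir, "manifest.txt")
  lines <- paste0(names(manifest), "=",
                  vapply(manifest, function(x) paste(x, collapse = ","), ""))
  writeLines(lines, mpath)
  invisible(c(paths, mpath))
}
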