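# End-to-end pipeline: read -> normalize -> copy numbers -> significance ->
# correction -> calls -> QC -> tables and heatmaps. Deterministic: no
# randomness anywhere in the analysis path.

#' Run the full copy-number calling pipeline
#'
#' @param target Path to the target cohort coverage TSV, or a raw coverage
#'   tibble.
#' @param reference Optional path to / tibble of a reference (normal)
#'   cohort with the same amplicon set.
#' @param gene_map Optional gene annotation: a path to a two-column TSV or a
#'   tibble (`amplicon`, `gene`). Default: parse gene names from amplicon
#'   ids at the first `"_"`.
#' @param mode `"gene_wise"` (combine amplicon evidence per gene; default)
#'   or `"amplicon_wise"`.
#' @param scope Multiplicity scope for correction: `"both"` (default),
#'   `"samples"`, `"genes"`, `"none"`. Uncorrected calling is supported but
#'   recommendable only as a search test, with candidates confirmed by an
#'   independent assay; the run log carries this caveat.
#' @param method `"bonferroni"` (FWER; default) or `"bh"` (FDR).
#' @param alpha Significance level (default 0.05).
#' @param support_count,support_fraction Optional supporting-amplicon filter
#'   (gene-wise mode), see [call_cnas()].
#' @param cluster_genes,cluster_samples Cluster heatmap axes (default TRUE).
#' @param out_dir Output directory, created if needed. `NULL` skips all file
#'   output and returns results only.
#' @param heatmaps Write PNG + PDF heatmaps (default `TRUE`; only applies
#'   when `out_dir` is set).
#' @return (Invisibly when writing) a list with the copy-number tables,
#'   significance tables, `calls`, `qc`, orderings, and the settings used.
#' @export
run_pipeline <- function(target, reference = NULL, gene_map = NULL,
                         mode = c("gene_wise", "amplicon_wise"),
                         scope = c("both", "samples", "genes", "none"),
                         method = c("bonferroni", "bh"), alpha = 0.05,
                         support_count = NULL, support_fraction = NULL,
                         cluster_genes = TRUE, cluster_samples = TRUE,
                         out_dir = NULL, heatmaps = TRUE) {
  mode <- match.arg(mode)
  scope <- match.arg(scope)
  method <- match.arg(method)
  check_alpha(alpha)

  cov <- if (is.character(target)) read_coverage_matrix(target) else target
  ref <- if (is.character(reference)) read_coverage_matrix(reference) else reference
  gm <- if (is.null(gene_map)) {
    parse_gene_map(cov$amplicon)
  } else if (is.character(gene_map)) {
    read_gene_map(gene_map, amplicon_ids = cov$amplicon)
  } else gene_map

  cn <- estimate_copy_numbers(normalize_samples(cov), reference = ref)
  nulls <- fit_null_models(cn)
  amp_p <- amplicon_pvalues(cn, nulls)
  amp_adj <- correct_pvalues(amp_p, scope = scope, method = method)
  amp_calls <- run_amplicon_wise(amp_adj, alpha = alpha)
  qc <- compute_igi(cn, gm, nulls = nulls)

  if (mode == "gene_wise") {
    gene_cn <- summarize_gene_cn(cn, gm)
    gene_p <- combine_fisher(amp_p, gm)
    gene_adj <- correct_pvalues(gene_p, scope = scope, method = method)
    calls <- call_cnas(gene_adj, gene_cn, amplicon_calls = amp_calls,
                       gene_map = gm, alpha = alpha,
                       support_count = support_count,
                       support_fraction = support_fraction)
    unit_cn <- gene_cn
    unit_adj <- gene_adj
  } else {
    calls <- amp_calls
    unit_cn <- cn
    unit_adj <- amp_adj
    gene_cn <- NULL
  }

  res <- list(coverage = cov, cn = cn, gene_cn = gene_cn, nulls = nulls,
              amplicon_table = amp_adj, unit_table = unit_adj,
              calls = calls, qc = qc,
              settings = list(mode = mode, scope = scope, method = method,
                              alpha = alpha, support_count = support_count,
                              support_fraction = support_fraction,
                              reference_used = !is.null(ref)))

  if (is.null(out_dir)) return(res)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  p <- function(f) file.path(out_dir, f)

  write_coverage_matrix(cn, p("cn_amplicons.tsv"))
  if (!is.null(gene_cn)) write_coverage_matrix(gene_cn, p("cn_genes.tsv"))
  write_pvalue_tables(unit_adj, out_dir)
  write_calls(calls, p("calls_matrix.tsv"), layout = "matrix")
  write_calls(calls, p("calls_gene_list.tsv"), layout = "gene_list")
  write_calls(calls, p("calls_sample_list.tsv"), layout = "sample_list", qc = qc)
  readr::write_tsv(qc, p("qc_igi.tsv"), progress = FALSE)

  if (heatmaps) {
    cn_for_plot <- if (!is.null(gene_cn)) gene_cn else cn
    hm_cn <- plot_cn_heatmap(cn_for_plot, cluster_rows = cluster_genes,
                             cluster_columns = cluster_samples)
    hm_calls <- plot_call_heatmap(calls, cluster_rows = cluster_genes,
                                  cluster_columns = cluster_samples)
    for (dev in c("png", "pdf")) {
      ggplot2::ggsave(p(paste0("heatmap_cn.", dev)), hm_cn,
                      width = 10, height = 7, dpi = 150)
      ggplot2::ggsave(p(paste0("heatmap_calls.", dev)), hm_calls,
                      width = 10, height = 7, dpi = 150)
    }
    if (cluster_genes && nrow(cn_for_plot) > 1) {
      write_ordering(hierarchical_order(cn_for_plot, "rows"),
                     p("ordering_rows.txt"))
    }
    if (cluster_samples && ncol(cn_for_plot) > 2) {
      write_ordering(hierarchical_order(cn_for_plot, "columns"),
                     p("ordering_samples.txt"))
    }
  }

  log_lines <- c(
    sprintf("mode: %s", mode),
    sprintf("correction: %s over %s", method, scope),
    sprintf("alpha: %g", alpha),
    sprintf("support: %s", if (!is.null(support_count)) {
      sprintf("count >= %d", support_count)
    } else if (!is.null(support_fraction)) {
      sprintf("fraction >= %g", support_fraction)
    } else "none"),
    sprintf("reference cohort: %s", if (!is.null(ref)) "yes" else "no"),
    sprintf("amplicons: %d, genes: %d, samples: %d", nrow(cov),
            length(unique(gm$gene)), ncol(cov) - 1L),
    sprintf("gains: %d, losses: %d", sum(calls$status == "gain"),
            sum(calls$status == "loss")),
    "analysis is deterministic: no random number generation on this path")
  if (scope == "none") {
    log_lines <- c(log_lines,
      paste0("WARNING: no multiple testing correction; recommendable only ",
             "as a search test with independent confirmation of candidates"))
  }
  writeLines(log_lines, p("run_log.txt"))
  invisible(res)
}

write_pvalue_tables <- function(tbl, out_dir) {
  unit <- if (identical(attr(tbl, "axis"), "gene")) "gene" else "amplicon"
  for (col in c("p_gain", "p_loss", "p_gain_adj", "p_loss_adj")) {
    wide <- tbl %>%
      dplyr::select(dplyr::all_of(c(unit, "sample", col))) %>%
      tidyr::pivot_wider(names_from = "sample", values_from = dplyr::all_of(col))
    readr::write_tsv(wide, file.path(out_dir, paste0("pvalues_", col, ".tsv")),
                     progress = FALSE)
  }
  invisible(NULL)
}
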