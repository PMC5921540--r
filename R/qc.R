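# Intra-gene inconsistency: a per-sample quality score summing, over the
# multi-amplicon genes, the standard deviation of that gene's amplicon copy
# numbers. Amplicons of one gene interrogate the same locus, so disagreement
# between them is technical noise, most often from poor DNA quality.

#' Compute the intra-gene inconsistency (IGI) per sample
#'
#' IGI(s) is the sum over genes g of the sample standard deviation
#' (denominator n(g) - 1) of the copy numbers CN(a, s) of the amplicons
#' interrogating g. Genes with a single amplicon carry no within-gene spread
#' (the n(g) - 1 denominator is undefined) and are excluded; they are listed
#' in `attr(, "excluded_genes")` rather than silently dropped. IGI is 0
#' exactly when, within every multi-amplicon gene, all amplicon copy numbers
#' agree.
#'
#' @param cn Copy-number tibble from [estimate_copy_numbers()].
#' @param gene_map Tibble with columns `amplicon`, `gene`.
#' @param nulls Optional null-model tibble from [fit_null_models()]; when
#'   given, its degenerate amplicons are recorded in
#'   `attr(, "degenerate_amplicons")` for the QC report.
#' @return Tibble with columns `sample`, `igi` (one row per sample, input
#'   sample order).
#' @export
compute_igi <- function(cn, gene_map, nulls = NULL) {
  check_stage(cn, "copy_number", "compute_igi")
  m <- coverage_matrix(cn)
  gm <- gene_map[gene_map$amplicon %in% rownames(m), ]
  sizes <- gene_sizes(gm)
  multi <- sizes$gene[sizes$n >= 2]
  excluded <- sizes$gene[sizes$n < 2]
  igi <- rep(0, ncol(m))
  for (g in multi) {
    sub <- m[gm$amplicon[gm$gene == g], , drop = FALSE]
    igi <- igi + apply(sub, 2, stats::sd)
  }
  out <- tibble::tibble(sample = colnames(m), igi = unname(igi))
  attr(out, "excluded_genes") <- excluded
  attr(out, "degenerate_amplicons") <-
    if (is.null(nulls)) character(0) else nulls$amplicon[nulls$degenerate]
  out
}
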