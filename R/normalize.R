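# Two-stage median normalization: per-sample depth scaling, then per-amplicon
# efficiency scaling against the target (or an external reference) cohort,
# times two for diploidy. All scaling is multiplicative on the linear scale.

#' Scale each sample by the median of its amplicon coverages
#'
#' Removes per-sample sequencing depth: every column is divided by its own
#' median, so each sample's median normalized coverage is 1.
#'
#' @param x Raw coverage tibble from [read_coverage_matrix()].
#' @return Coverage tibble at stage `"sample_normalized"`.
#' @export
normalize_samples <- function(x) {
  check_stage(x, "raw", "normalize_samples")
  validate_coverage_tbl(x)
  m <- coverage_matrix(x)
  med <- col_medians(m)
  dead <- colnames(m)[med <= 0]
  if (length(dead) > 0) {
    stop(sprintf(paste0("Sample(s) with median amplicon coverage 0 ",
                        "(likely failed libraries): %s"),
                 paste(dead, collapse = ", ")), call. = FALSE)
  }
  new_coverage_tbl(sweep(m, 2, med, "/"), stage = "sample_normalized")
}

#' Estimate copy numbers by per-amplicon median scaling
#'
#' Each amplicon is divided by its median normalized coverage — taken over a
#' reference cohort when one is supplied, otherwise over the target cohort
#' itself — and multiplied by two (two alleles) to put the values on the
#' copy-number scale. Without a reference, every amplicon's median copy
#' number across samples is exactly 2.
#'
#' @param x Sample-normalized coverage tibble (see [normalize_samples()]).
#' @param reference Optional reference cohort (normal tissue / blood) with
#'   the identical amplicon set; raw input is sample-normalized internally
#'   before its amplicon medians are taken. Amplicon order may differ; rows
#'   are aligned by id.
#' @return Copy-number tibble at stage `"copy_number"`, with
#'   `attr(, "reference_used")` recording whether a reference was supplied.
#' @export
estimate_copy_numbers <- function(x, reference = NULL) {
  check_stage(x, "sample_normalized", "estimate_copy_numbers")
  m <- coverage_matrix(x)
  if (is.null(reference)) {
    scaler <- row_medians(m)
    ref_used <- FALSE
  } else {
    if (cov_stage(reference) == "raw") reference <- normalize_samples(reference)
    check_stage(reference, "sample_normalized", "estimate_copy_numbers")
    rm_ <- coverage_matrix(reference)
    if (!setequal(rownames(rm_), rownames(m))) {
      stop("Reference amplicon set does not match the target amplicon set.",
           call. = FALSE)
    }
    rm_ <- rm_[rownames(m), , drop = FALSE]
    scaler <- row_medians(rm_)
    ref_used <- TRUE
  }
  zero <- rownames(m)[scaler <= 0]
  if (length(zero) > 0) {
    stop(sprintf("Amplicon(s) with zero scaling median: %s",
                 paste(zero, collapse = ", ")), call. = FALSE)
  }
  new_coverage_tbl(2 * sweep(m, 1, scaler, "/"), stage = "copy_number",
                   reference_used = ref_used)
}

#' Summarize amplicon copy numbers to gene level
#'
#' The gene copy number CN(g, s) is the unweighted mean of CN(a, s) over the
#' amplicons interrogating gene g.
#'
#' @param cn Copy-number tibble from [estimate_copy_numbers()].
#' @param gene_map Tibble with columns `amplicon`, `gene`.
#' @return Wide tibble (`gene` column plus one column per sample) at stage
#'   `"copy_number"`; gene order follows the gene map.
#' @export
summarize_gene_cn <- function(cn, gene_map) {
  check_stage(cn, "copy_number", "summarize_gene_cn")
  m <- coverage_matrix(cn)
  missing <- setdiff(gene_map$amplicon, rownames(m))
  if (length(missing) > 0) {
    stop(sprintf("Gene map amplicon(s) absent from the copy-number table: %s",
                 paste(missing, collapse = ", ")), call. = FALSE)
  }
  gm <- gene_map[gene_map$amplicon %in% rownames(m), ]
  grp <- factor(gm$gene, levels = unique(gm$gene))
  sums <- rowsum(m[gm$amplicon, , drop = FALSE], grp, reorder = FALSE)
  avg <- sums / as.vector(table(grp)[rownames(sums)])
  new_coverage_tbl(avg, stage = "copy_number", id_col = "gene",
                   reference_used = attr(cn, "reference_used") %||% FALSE)
}
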