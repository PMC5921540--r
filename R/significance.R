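# Outlier significance of copy-number deviations: a normal null centered at
# CN = 2 with a MAD-calibrated spread per amplicon, one-sided tail p-values
# for gain and loss, gene-level combination with Fisher's method, and
# multiple-testing control over four scopes.

#' Fit the per-amplicon null model of diploid copy number
#'
#' For each amplicon the null is Normal(2, sigma_a^2) with sigma_a the median
#' absolute deviation of that amplicon's copy numbers across samples, scaled
#' by 1.4826 for consistency with the normal standard deviation. The center
#' is fixed at 2 (diploid), not estimated: deviations of the typical sample
#' from 2 are themselves of interest.
#'
#' @param cn Copy-number tibble from [estimate_copy_numbers()].
#' @return Tibble with columns `amplicon`, `sigma`, `degenerate`. An amplicon
#'   is degenerate when its MAD is 0 (at least half the samples share one
#'   value); such amplicons are uncallable and flagged rather than fatal.
#' @export
fit_null_models <- function(cn) {
  check_stage(cn, "copy_number", "fit_null_models")
  m <- coverage_matrix(cn)
  sigma <- apply(m, 1, stats::mad)  # constant = 1.4826, center = median
  tibble::tibble(amplicon = rownames(m), sigma = unname(sigma),
                 degenerate = sigma == 0)
}

#' One-sided outlier p-values per amplicon and sample
#'
#' With z = (CN(a, s) - 2) / sigma_a, the gain p-value is the upper normal
#' tail at z and the loss p-value the lower tail, so that
#' `p_gain + p_loss = 1` for every non-degenerate cell. Degenerate amplicons
#' (MAD 0) receive p = 1 in both directions and are uncallable.
#'
#' @param cn Copy-number tibble.
#' @param nulls Null models from [fit_null_models()]; fitted on the same
#'   amplicon set (the default refits on `cn`).
#' @return Long tibble with columns `amplicon`, `sample`, `cn`, `p_gain`,
#'   `p_loss`, `degenerate`; `attr(, "axis") == "amplicon"`.
#' @export
amplicon_pvalues <- function(cn, nulls = fit_null_models(cn)) {
  check_stage(cn, "copy_number", "amplicon_pvalues")
  m <- coverage_matrix(cn)
  if (!setequal(nulls$amplicon, rownames(m))) {
    stop("Null models were fitted on a different amplicon set.", call. = FALSE)
  }
  nulls <- nulls[match(rownames(m), nulls$amplicon), ]
  sigma <- nulls$sigma
  z <- (m - 2) / ifelse(sigma > 0, sigma, NA_real_)
  p_gain <- stats::pnorm(z, lower.tail = FALSE)
  p_loss <- stats::pnorm(z, lower.tail = TRUE)
  p_gain[nulls$degenerate, ] <- 1
  p_loss[nulls$degenerate, ] <- 1
  out <- tibble::tibble(
    amplicon = rep(rownames(m), times = ncol(m)),
    sample = rep(colnames(m), each = nrow(m)),
    cn = as.vector(m),
    p_gain = as.vector(p_gain),
    p_loss = as.vector(p_loss),
    degenerate = rep(nulls$degenerate, times = ncol(m)))
  attr(out, "axis") <- "amplicon"
  out
}

#' Combine amplicon p-values per gene with Fisher's method
#'
#' Per direction (gain, loss) and per gene-sample cell, the statistic
#' X^2 = -2 * sum(log p) over the gene's non-degenerate amplicons follows a
#' chi-square distribution with 2k degrees of freedom under the null; the
#' combined p-value is its upper tail. Genes whose amplicons are all
#' degenerate get p = 1 in both directions. Input p-values of exactly 0 are
#' clamped to the smallest positive double before taking logs; the number of
#' clamped values is recorded in `attr(, "n_clamped")` with a warning.
#'
#' @param amp_table Amplicon-level table from [amplicon_pvalues()].
#' @param gene_map Tibble with columns `amplicon`, `gene`.
#' @return Long tibble with columns `gene`, `sample`, `p_gain`, `p_loss`,
#'   `n_amplicons` (amplicons combined), `degenerate`;
#'   `attr(, "axis") == "gene"`.
#' @export
combine_fisher <- function(amp_table, gene_map) {
  stopifnot(identical(attr(amp_table, "axis"), "amplicon"))
  missing <- setdiff(amp_table$amplicon, gene_map$amplicon)
  if (length(missing) > 0) {
    stop(sprintf("Amplicon(s) missing from the gene map: %s",
                 paste(missing, collapse = ", ")), call. = FALSE)
  }
  n_zero <- sum(amp_table$p_gain == 0) + sum(amp_table$p_loss == 0)
  if (n_zero > 0) {
    warning(sprintf("%d zero p-value(s) clamped to the smallest positive double before Fisher combination.",
                    n_zero))
  }
  clamp <- function(p) pmax(p, .Machine$double.xmin)
  gene_lv <- unique(gene_map$gene)
  out <- amp_table %>%
    dplyr::left_join(gene_map, by = "amplicon") %>%
    dplyr::group_by(gene = factor(.data$gene, levels = gene_lv), .data$sample) %>%
    dplyr::summarise(
      n_amplicons = sum(!.data$degenerate),
      p_gain = fisher_tail(clamp(.data$p_gain[!.data$degenerate])),
      p_loss = fisher_tail(clamp(.data$p_loss[!.data$degenerate])),
      .groups = "drop") %>%
    dplyr::mutate(gene = as.character(.data$gene),
                  degenerate = .data$n_amplicons == 0L) %>%
    dplyr::arrange(factor(.data$gene, levels = gene_lv), .data$sample) %>%
    dplyr::select(dplyr::all_of(c("gene", "sample", "p_gain", "p_loss",
                                  "n_amplicons", "degenerate")))
  attr(out, "axis") <- "gene"
  attr(out, "n_clamped") <- n_zero
  out
}

fisher_tail <- function(p) {
  k <- length(p)
  if (k == 0) return(1)
  stats::pchisq(-2 * sum(log(p)), df = 2 * k, lower.tail = FALSE)
}

#' Multiple-testing correction of a significance table
#'
#' Controls the family-wise error rate (Bonferroni) or the false discovery
#' rate (Benjamini-Hochberg) over a chosen multiplicity scope:
#' `"samples"` corrects each unit's p-values across samples, `"genes"`
#' corrects each sample's p-values across analysis units (genes, or
#' amplicons in amplicon-wise mode), `"both"` pools all unit-sample
#' p-values of a direction into one family, and `"none"` leaves the table
#' unchanged. Bonferroni multiplies by the family size (capped at 1); BH is
#' the step-up adjustment with monotonicity enforcement.
#'
#' @param table Significance table from [amplicon_pvalues()] or
#'   [combine_fisher()].
#' @param scope One of `"both"`, `"samples"`, `"genes"`, `"none"`.
#' @param method `"bonferroni"` (FWER) or `"bh"` (FDR).
#' @return The table with columns `p_gain_adj`, `p_loss_adj` added and the
#'   scope/method recorded in attributes.
#' @export
correct_pvalues <- function(table, scope = c("both", "samples", "genes", "none"),
                            method = c("bonferroni", "bh")) {
  scope <- match.arg(scope)
  method <- match.arg(method)
  unit <- if (identical(attr(table, "axis"), "gene")) "gene" else "amplicon"
  grouping <- switch(scope,
    none = NULL,
    both = character(0),          # one family
    samples = unit,               # across samples, per unit
    genes = "sample")             # across units, per sample
  adjust <- function(p) {
    if (method == "bonferroni") pmin(1, p * length(p))
    else stats::p.adjust(p, method = "BH")
  }
  if (is.null(grouping)) {
    out <- dplyr::mutate(table, p_gain_adj = .data$p_gain,
                         p_loss_adj = .data$p_loss)
  } else {
    out <- table %>%
      dplyr::group_by(dplyr::across(dplyr::all_of(grouping))) %>%
      dplyr::mutate(p_gain_adj = adjust(.data$p_gain),
                    p_loss_adj = adjust(.data$p_loss)) %>%
      dplyr::ungroup()
  }
  attr(out, "axis") <- attr(table, "axis")
  attr(out, "correction_scope") <- scope
  attr(out, "correction_method") <- method
  out
}
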