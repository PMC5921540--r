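# Calling gains and losses from corrected significance tables, with optional
# supporting-amplicon filters in gene-wise mode.

#' Call copy number alterations per gene and sample
#'
#' A cell (g, s) is called a gain when its corrected gain p-value is below
#' `alpha`, its gene copy number exceeds 2, and at least the required number
#' of the gene's amplicons are themselves called gains at amplicon
#' resolution under the same correction scope and method; losses
#' symmetrically with CN below 2. The gene copy number fixes the direction,
#' so at most one direction can be called per cell. Without a support filter
#' no support is required, but the supporting-amplicon count is still
#' reported.
#'
#' @param gene_table Corrected gene-level table
#'   ([combine_fisher()] then [correct_pvalues()]).
#' @param gene_cn Gene-level copy numbers from [summarize_gene_cn()].
#' @param amplicon_calls Amplicon-resolution call set from
#'   [run_amplicon_wise()] at the same scope/method/alpha; used to count
#'   supporting amplicons. May be `NULL` only when no support filter is
#'   requested (support counts are then `NA`).
#' @param gene_map Tibble with columns `amplicon`, `gene`.
#' @param alpha Significance level in (0, 1); default 0.05.
#' @param support_count If set, require at least this many supporting
#'   amplicon calls (e.g. 2).
#' @param support_fraction If set, require supporting calls from at least
#'   this fraction of the gene's amplicons (ceiling; 0.5 with 3 amplicons
#'   means 2). At most one of `support_count`/`support_fraction` may be set.
#' @return A `cna_calls` tibble with one row per gene-sample cell: `gene`,
#'   `sample`, `status` (gain/loss/none), `cn`, `p_gain_adj`, `p_loss_adj`,
#'   `p_adj` (the direction-matching corrected p), `support_count`,
#'   `support_required`. Settings travel in attributes.
#' @export
call_cnas <- function(gene_table, gene_cn, amplicon_calls = NULL, gene_map = NULL,
                      alpha = 0.05, support_count = NULL, support_fraction = NULL) {
  check_alpha(alpha)
  if (!is.null(support_count) && !is.null(support_fraction)) {
    stop("Set at most one of support_count and support_fraction.", call. = FALSE)
  }
  if (!all(c("p_gain_adj", "p_loss_adj") %in% names(gene_table))) {
    stop("gene_table has no corrected p-values; run correct_pvalues() first.",
         call. = FALSE)
  }
  cn_long <- tidyr::pivot_longer(gene_cn, -1, names_to = "sample",
                                 values_to = "cn")
  out <- dplyr::inner_join(gene_table, cn_long, by = c("gene", "sample"))
  if (nrow(out) != nrow(gene_table)) {
    stop("gene_table and gene_cn do not cover the same gene-sample cells.",
         call. = FALSE)
  }

  if (!is.null(amplicon_calls)) {
    if (is.null(gene_map)) stop("gene_map is required to count supporting amplicons.",
                                call. = FALSE)
    sup <- amplicon_calls %>%
      dplyr::inner_join(gene_map, by = "amplicon") %>%
      dplyr::group_by(.data$gene, .data$sample) %>%
      dplyr::summarise(sup_gain = sum(.data$status == "gain"),
                       sup_loss = sum(.data$status == "loss"),
                       .groups = "drop")
    out <- dplyr::left_join(out, sup, by = c("gene", "sample"))
  } else {
    if (!is.null(support_count) || !is.null(support_fraction)) {
      stop("A support filter needs amplicon_calls to count supporting amplicons.",
           call. = FALSE)
    }
    out$sup_gain <- NA_integer_
    out$sup_loss <- NA_integer_
  }

  if (!is.null(support_count)) {
    out$support_required <- as.integer(support_count)
  } else if (!is.null(support_fraction)) {
    stopifnot(support_fraction > 0, support_fraction <= 1)
    sizes <- gene_sizes(gene_map)
    out <- dplyr::left_join(out, sizes, by = "gene")
    out$support_required <- as.integer(ceiling(support_fraction * out$n))
    out$n <- NULL
  } else {
    out$support_required <- 0L
  }

  gain <- out$p_gain_adj < alpha & out$cn > 2 &
    (out$support_required == 0L | dplyr::coalesce(out$sup_gain, 0L) >= out$support_required)
  loss <- out$p_loss_adj < alpha & out$cn < 2 &
    (out$support_required == 0L | dplyr::coalesce(out$sup_loss, 0L) >= out$support_required)
  out$status <- dplyr::case_when(gain ~ "gain", loss ~ "loss", TRUE ~ "none")
  out$support_count <- dplyr::case_when(
    out$status == "loss" ~ out$sup_loss,
    out$status == "gain" ~ out$sup_gain,
    out$cn < 2 ~ out$sup_loss,
    TRUE ~ out$sup_gain)
  out$p_adj <- dplyr::if_else(out$cn < 2, out$p_loss_adj,
                              dplyr::if_else(out$cn > 2, out$p_gain_adj,
                                             pmin(out$p_gain_adj, out$p_loss_adj)))
  out <- out %>%
    dplyr::select(dplyr::all_of(c("gene", "sample", "status", "cn",
                                  "p_gain_adj", "p_loss_adj", "p_adj",
                                  "support_count", "support_required")))
  new_cna_calls(out, mode = "gene_wise", alpha = alpha,
                scope = attr(gene_table, "correction_scope"),
                method = attr(gene_table, "correction_method"))
}

#' Call alterations at amplicon resolution
#'
#' Skips Fisher combination and gene averaging: every amplicon is its own
#' analysis unit. An amplicon-sample cell is called a gain when its
#' corrected gain p-value passes `alpha` and its copy number exceeds 2;
#' losses symmetrically.
#'
#' @param amp_table Corrected amplicon-level table
#'   ([amplicon_pvalues()] then [correct_pvalues()]).
#' @param alpha Significance level in (0, 1).
#' @return A `cna_calls` tibble with columns `amplicon`, `sample`, `status`,
#'   `cn`, `p_gain_adj`, `p_loss_adj`, `p_adj`, `support_count` (1 for a
#'   called cell — the amplicon itself), `support_required` (0).
#' @export
run_amplicon_wise <- function(amp_table, alpha = 0.05) {
  check_alpha(alpha)
  if (!all(c("p_gain_adj", "p_loss_adj") %in% names(amp_table))) {
    stop("amp_table has no corrected p-values; run correct_pvalues() first.",
         call. = FALSE)
  }
  out <- amp_table
  gain <- out$p_gain_adj < alpha & out$cn > 2
  loss <- out$p_loss_adj < alpha & out$cn < 2
  out$status <- dplyr::case_when(gain ~ "gain", loss ~ "loss", TRUE ~ "none")
  out$p_adj <- dplyr::if_else(out$cn < 2, out$p_loss_adj,
                              dplyr::if_else(out$cn > 2, out$p_gain_adj,
                                             pmin(out$p_gain_adj, out$p_loss_adj)))
  out$support_count <- dplyr::if_else(out$status == "none", 0L, 1L)
  out$support_required <- 0L
  out <- out %>%
    dplyr::select(dplyr::all_of(c("amplicon", "sample", "status", "cn",
                                  "p_gain_adj", "p_loss_adj", "p_adj",
                                  "support_count", "support_required")))
  new_cna_calls(out, mode = "amplicon_wise", alpha = alpha,
                scope = attr(amp_table, "correction_scope"),
                method = attr(amp_table, "correction_method"))
}

new_cna_calls <- function(x, mode, alpha, scope, method) {
  attr(x, "mode") <- mode
  attr(x, "alpha") <- alpha
  attr(x, "correction_scope") <- scope %||% "none"
  attr(x, "correction_method") <- method %||% "bonferroni"
  class(x) <- c("cna_calls", class(x))
  x
}

check_alpha <- function(alpha) {
  if (!is.numeric(alpha) || length(alpha) != 1 || alpha <= 0 || alpha >= 1) {
    stop("alpha must be a single number in (0, 1).", call. = FALSE)
  }
}

#' @export
print.cna_calls <- function(x, ...) {
  g <- sum(x$status == "gain")
  l <- sum(x$status == "loss")
  cat(sprintf("<cna_calls> %s, %s/%s correction, alpha = %g: %d gains, %d losses over %d cells\n",
              attr(x, "mode"), attr(x, "correction_method"),
              attr(x, "correction_scope"), attr(x, "alpha"), g, l, nrow(x)))
  NextMethod()
}

#' Tidy a call set: one row per called alteration
#'
#' @param x A `cna_calls` object.
#' @param ... Unused.
#' @return Tibble of the called cells only, sorted by unit then sample.
#' @method tidy cna_calls
#' @export
tidy.cna_calls <- function(x, ...) {
  unit <- call_unit(x)
  out <- dplyr::filter(tibble::as_tibble(x), .data$status != "none")
  dplyr::arrange(out, .data[[unit]], .data$sample)
}

#' One-row summary of a call set
#'
#' @param x A `cna_calls` object.
#' @param ... Unused.
#' @return Tibble with unit/sample counts, gain and loss counts and their
#'   fractions of all cells, plus the calling settings.
#' @method glance cna_calls
#' @export
glance.cna_calls <- function(x, ...) {
  unit <- call_unit(x)
  n_cells <- nrow(x)
  n_gains <- sum(x$status == "gain")
  n_losses <- sum(x$status == "loss")
  tibble::tibble(
    n_units = dplyr::n_distinct(x[[unit]]),
    n_samples = dplyr::n_distinct(x$sample),
    n_gains = n_gains,
    n_losses = n_losses,
    frac_gains = n_gains / n_cells,
    frac_losses = n_losses / n_cells,
    mode = attr(x, "mode"),
    correction_scope = attr(x, "correction_scope"),
    correction_method = attr(x, "correction_method"),
    alpha = attr(x, "alpha"))
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance
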