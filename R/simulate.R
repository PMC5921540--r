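# Coverage cohort simulator with known copy-number truth. The generative
# model is multiplicative: coverage(a, s) = base_depth * depth(s) * eff(a) *
# bulk_cn(g(a), s) / 2 * noise(a, s), with lognormal per-sample depth and
# per-amplicon efficiency factors and lognormal cell-wise noise (positive
# support; at small sigma it approximates the normal null on the CN scale).
# Spiked clonal alterations are diluted by tumor purity:
# bulk = purity * clonal_cn + (1 - purity) * 2.

#' Simulate an amplicon coverage cohort with known truth
#'
#' @param n_genes Number of genes in the panel (default 48, the size of a
#'   typical mid-size cancer amplicon panel).
#' @param amplicons_per_gene Amplicons per gene: a single count or a
#'   two-element range sampled uniformly per gene (default 2).
#' @param n_samples Cohort size (default 100).
#' @param base_depth Median target depth in reads (default 1000).
#' @param depth_sdlog Lognormal sd of the per-sample depth factor
#'   (default 0.5).
#' @param efficiency_sdlog Lognormal sd of the per-amplicon efficiency
#'   factor (default 1): amplification efficiencies span orders of
#'   magnitude in real panels.
#' @param noise_sigma Lognormal sd of the multiplicative cell-wise noise
#'   (default 0.05, i.e. roughly 5% coefficient of variation, about 0.1 on
#'   the CN scale).
#' @param n_spiked_genes Number of genes to spike with clonal alterations
#'   (default 0).
#' @param spike_fraction Fraction of samples carrying the alteration in each
#'   spiked gene (default 0.05). Must stay below 0.5: median normalization
#'   absorbs an alteration present in half or more of the cohort.
#' @param spike_cn Clonal copy number of the spiked alterations (default 6;
#'   values below 2 spike losses).
#' @param spikes Optional explicit spike table (columns `gene`, `sample`,
#'   `clonal_cn`); overrides the three arguments above.
#' @param purity Tumor purity in (0, 1], a scalar or one value per sample;
#'   clonal alterations are diluted toward CN 2 as purity falls.
#' @param seed Optional integer seed for full reproducibility.
#' @return List with `coverage` (raw wide coverage tibble, amplicon ids
#'   `G01_1`, ...) and `truth`, a tibble per gene-sample cell: `gene`,
#'   `sample`, `clonal_cn`, `purity`, `bulk_cn`, `label`
#'   (gain/loss/none).
#' @examples
#' sim <- simulate_cohort(n_genes = 4, n_samples = 12, n_spiked_genes = 1,
#'                        spike_fraction = 0.25, seed = 1)
#' dplyr::count(sim$truth, label)
#' @export
simulate_cohort <- function(n_genes = 48, amplicons_per_gene = 2,
                            n_samples = 100, base_depth = 1000,
                            depth_sdlog = 0.5, efficiency_sdlog = 1,
                            noise_sigma = 0.05,
                            n_spiked_genes = 0, spike_fraction = 0.05,
                            spike_cn = 6, spikes = NULL,
                            purity = 1, seed = NULL) {
  stopifnot(n_genes >= 1, n_samples >= 1, base_depth > 0,
            depth_sdlog >= 0, efficiency_sdlog >= 0, noise_sigma >= 0,
            all(purity > 0), all(purity <= 1))
  if (!is.null(seed)) set.seed(seed)
  genes <- sprintf("G%02d", seq_len(n_genes))
  samples <- sprintf("S%03d", seq_len(n_samples))
  purity <- rep_len(purity, n_samples)

  if (length(amplicons_per_gene) == 1) {
    n_amp <- rep(as.integer(amplicons_per_gene), n_genes)
  } else {
    stopifnot(length(amplicons_per_gene) == 2)
    n_amp <- sample(amplicons_per_gene[1]:amplicons_per_gene[2], n_genes,
                    replace = TRUE)
  }
  stopifnot(all(n_amp >= 1))
  amp_gene <- rep(genes, times = n_amp)
  amplicons <- paste0(amp_gene, "_", unlist(lapply(n_amp, seq_len)))

  if (is.null(spikes)) {
    spikes <- make_spikes(genes, samples, n_spiked_genes, spike_fraction,
                          spike_cn)
  } else {
    stopifnot(all(c("gene", "sample", "clonal_cn") %in% names(spikes)),
              all(spikes$gene %in% genes), all(spikes$sample %in% samples),
              all(spikes$clonal_cn >= 0))
  }
  per_gene <- table(factor(spikes$gene, levels = genes))
  if (any(per_gene >= n_samples / 2)) {
    stop(paste0("A gene is spiked in >= 50% of samples; median normalization ",
                "would absorb the alteration. Spike fewer samples."),
         call. = FALSE)
  }

  truth <- tidyr::expand_grid(gene = genes, sample = samples) %>%
    dplyr::left_join(spikes, by = c("gene", "sample")) %>%
    dplyr::mutate(clonal_cn = dplyr::coalesce(.data$clonal_cn, 2),
                  purity = purity[match(.data$sample, samples)],
                  bulk_cn = .data$purity * .data$clonal_cn +
                    (1 - .data$purity) * 2,
                  label = dplyr::case_when(.data$bulk_cn > 2 ~ "gain",
                                           .data$bulk_cn < 2 ~ "loss",
                                           TRUE ~ "none"))

  depth <- stats::rlnorm(n_samples, meanlog = 0, sdlog = depth_sdlog)
  eff <- stats::rlnorm(length(amplicons), meanlog = 0, sdlog = efficiency_sdlog)
  bulk <- matrix(truth$bulk_cn, nrow = n_genes, ncol = n_samples,
                 byrow = TRUE, dimnames = list(genes, samples))
  noise <- matrix(stats::rlnorm(length(amplicons) * n_samples,
                                meanlog = -noise_sigma^2 / 2,
                                sdlog = noise_sigma),
                  nrow = length(amplicons))
  covm <- base_depth * outer(eff, depth) *
    (bulk[amp_gene, , drop = FALSE] / 2) * noise
  dimnames(covm) <- list(amplicons, samples)

  list(coverage = new_coverage_tbl(covm, stage = "raw"), truth = truth)
}

make_spikes <- function(genes, samples, n_spiked_genes, spike_fraction,
                        spike_cn) {
  if (n_spiked_genes == 0) {
    return(tibble::tibble(gene = character(0), sample = character(0),
                          clonal_cn = numeric(0)))
  }
  stopifnot(n_spiked_genes <= length(genes),
            spike_fraction > 0, spike_fraction < 0.5, spike_cn >= 0)
  n_carriers <- max(1L, round(spike_fraction * length(samples)))
  spiked <- sample(genes, n_spiked_genes)
  purrr::map_dfr(spiked, function(g) {
    tibble::tibble(gene = g, sample = sample(samples, n_carriers),
                   clonal_cn = spike_cn)
  })
}

#' Compare a call set against simulation truth
#'
#' @param calls A gene-wise `cna_calls` object.
#' @param truth Truth tibble from [simulate_cohort()].
#' @param by Optional character vector of truth columns (e.g. `"purity"`,
#'   `"bulk_cn"`) to stratify the metrics by.
#' @return Tibble with, per stratum: `n_true` (cells with a true
#'   alteration), `n_null` (truly diploid cells), `sensitivity` (fraction of
#'   true alterations called with the matching direction), `specificity`
#'   (fraction of diploid cells left uncalled), `n_false_calls` (calls on
#'   diploid cells plus direction mismatches), and `any_false_call`
#'   (family-wise error indicator for the replicate).
#' @export
evaluate_recovery <- function(calls, truth, by = NULL) {
  joined <- dplyr::inner_join(tibble::as_tibble(calls)[, c("gene", "sample", "status")],
                              truth, by = c("gene", "sample"))
  if (nrow(joined) != nrow(truth)) {
    stop("calls and truth do not cover the same gene-sample cells.",
         call. = FALSE)
  }
  joined %>%
    dplyr::group_by(dplyr::across(dplyr::all_of(by %||% character(0)))) %>%
    dplyr::summarise(
      n_true = sum(.data$label != "none"),
      n_null = sum(.data$label == "none"),
      sensitivity = dplyr::if_else(
        n_true > 0,
        sum(.data$status == .data$label & .data$label != "none") /
          pmax(n_true, 1L), NA_real_),
      specificity = dplyr::if_else(
        n_null > 0,
        sum(.data$status == "none" & .data$label == "none") /
          pmax(n_null, 1L), NA_real_),
      n_false_calls = sum(.data$status != "none" & .data$status != .data$label),
      any_false_call = n_false_calls > 0,
      .groups = "drop")
}
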