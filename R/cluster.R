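# Deterministic average-linkage ordering for heatmap display. Distances are
# Manhattan (L1); agglomeration is UPGMA (the distance between clusters is
# the unweighted mean over all cross-pairs). Ties are resolved by comparing
# cluster representative ids (the lexicographically smallest member id), for
# merge choice and for left/right placement alike, so the ordering is
# bit-reproducible and invariant to input row permutation up to relabeling.

#' Order one axis of a matrix by hierarchical clustering
#'
#' @param x Wide tibble (id column first, numeric columns after), e.g. a
#'   copy-number table.
#' @param axis `"rows"` to cluster the id rows, `"columns"` to cluster the
#'   sample columns.
#' @return An `axis_ordering` list: `ids` (leaf order left to right),
#'   `clustered` flag, and `merges`, a tibble of the agglomeration sequence
#'   (representative ids of the merged clusters and the linkage height, as
#'   computed — monotonicity of heights is recorded, not assumed). A single
#'   element on the axis yields the trivial ordering with
#'   `clustered = FALSE`.
#' @examples
#' cn <- tibble::tibble(gene = c("A", "B", "C"), s1 = c(0, 1, 5))
#' hierarchical_order(cn, axis = "rows")$ids
#' @export
hierarchical_order <- function(x, axis = c("rows", "columns")) {
  axis <- match.arg(axis)
  m <- coverage_matrix(x)
  if (axis == "columns") m <- t(m)
  ids <- rownames(m)
  if (!all(is.finite(m))) stop("Matrix entries must be finite.", call. = FALSE)
  if (length(ids) < 2) {
    return(structure(list(ids = ids, clustered = FALSE,
                          merges = tibble::tibble(left = character(0),
                                                  right = character(0),
                                                  height = numeric(0))),
                     class = "axis_ordering"))
  }
  d <- as.matrix(stats::dist(m, method = "manhattan"))

  # active clusters: member ids, leaf order, representative (min member id)
  cl <- lapply(ids, function(i) list(members = i, order = i, rep = i))
  sizes <- rep(1L, length(ids))
  active <- seq_along(ids)
  merges <- vector("list", length(ids) - 1L)
  for (step in seq_len(length(ids) - 1L)) {
    best <- NULL
    for (ii in seq_along(active)) {
      for (jj in seq_len(ii - 1L)) {
        a <- active[ii]; b <- active[jj]
        dd <- d[a, b]
        reps <- sort(c(cl[[a]]$rep, cl[[b]]$rep))
        cand <- list(a = a, b = b, d = dd, r1 = reps[1], r2 = reps[2])
        if (is.null(best) || dd < best$d ||
            (dd == best$d && (cand$r1 < best$r1 ||
                              (cand$r1 == best$r1 && cand$r2 < best$r2)))) {
          best <- cand
        }
      }
    }
    a <- best$a; b <- best$b
    # left subtree: lexicographically smaller representative
    if (cl[[a]]$rep > cl[[b]]$rep) { tmp <- a; a <- b; b <- tmp }
    merges[[step]] <- tibble::tibble(left = cl[[a]]$rep, right = cl[[b]]$rep,
                                     height = best$d)
    # UPGMA update: unweighted mean over all cross-pairs
    na <- sizes[a]; nb <- sizes[b]
    for (k in setdiff(active, c(a, b))) {
      dk <- (na * d[a, k] + nb * d[b, k]) / (na + nb)
      d[a, k] <- dk; d[k, a] <- dk
    }
    cl[[a]] <- list(members = c(cl[[a]]$members, cl[[b]]$members),
                    order = c(cl[[a]]$order, cl[[b]]$order),
                    rep = min(cl[[a]]$rep, cl[[b]]$rep))
    sizes[a] <- na + nb
    active <- setdiff(active, b)
  }
  structure(list(ids = cl[[active]]$order, clustered = TRUE,
                 merges = dplyr::bind_rows(merges)),
            class = "axis_ordering")
}

#' @export
print.axis_ordering <- function(x, ...) {
  cat(sprintf("<axis_ordering> %d ids%s\n", length(x$ids),
              if (x$clustered) ", clustered" else ""))
  utils::str(x$ids, give.head = FALSE)
  invisible(x)
}

#' Write an axis ordering as a plain-text id list
#'
#' @param ordering An `axis_ordering`.
#' @param path Output path (one id per line).
#' @return `path`, invisibly.
#' @export
write_ordering <- function(ordering, path) {
  writeLines(ordering$ids, path)
  invisible(path)
}

apply_ordering <- function(levels_in, ordering) {
  if (is.null(ordering)) levels_in else ordering$ids
}

#' Heatmap of copy-number levels
#'
#' Diverging color scale centered at the diploid value CN = 2. When
#' clustering is off the input order is preserved exactly, which is useful
#' for technical quality control and spotting batch effects.
#'
#' @param cn Wide copy-number tibble (gene- or amplicon-level).
#' @param cluster_rows,cluster_columns Cluster the corresponding axis with
#'   Manhattan distance and average linkage (default `TRUE`).
#' @return A ggplot object.
#' @export
plot_cn_heatmap <- function(cn, cluster_rows = TRUE, cluster_columns = TRUE) {
  unit <- names(cn)[1]
  ro <- if (cluster_rows && nrow(cn) > 1) hierarchical_order(cn, "rows") else NULL
  co <- if (cluster_columns && ncol(cn) > 2) hierarchical_order(cn, "columns") else NULL
  long <- tidyr::pivot_longer(cn, -1, names_to = "sample", values_to = "cn")
  long[[unit]] <- factor(long[[unit]], levels = rev(apply_ordering(unique(long[[unit]]), ro)))
  long$sample <- factor(long$sample, levels = apply_ordering(unique(long$sample), co))
  ggplot2::ggplot(long, ggplot2::aes(x = .data$sample, y = .data[[unit]],
                                     fill = .data$cn)) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_gradient2(low = "#2166AC", mid = "#F7F7F7",
                                  high = "#B2182B", midpoint = 2,
                                  name = "CN") +
    ggplot2::labs(x = "sample", y = unit) +
    heatmap_theme()
}

#' Heatmap of copy-number alteration calls
#'
#' Three-state categorical scale (gain / none / loss). Clustering, when
#' requested, runs on a numeric encoding of the calls (gain = 1, none = 0,
#' loss = -1).
#'
#' @param calls A `cna_calls` object.
#' @param cluster_rows,cluster_columns Cluster genes (or amplicons) and/or
#'   samples (default `TRUE`).
#' @return A ggplot object.
#' @export
plot_call_heatmap <- function(calls, cluster_rows = TRUE, cluster_columns = TRUE) {
  unit <- call_unit(calls)
  enc <- calls %>%
    tibble::as_tibble() %>%
    dplyr::mutate(code = dplyr::case_when(.data$status == "gain" ~ 1,
                                          .data$status == "loss" ~ -1,
                                          TRUE ~ 0)) %>%
    dplyr::select(dplyr::all_of(c(unit, "sample", "code"))) %>%
    tidyr::pivot_wider(names_from = "sample", values_from = "code")
  ro <- if (cluster_rows && nrow(enc) > 1) hierarchical_order(enc, "rows") else NULL
  co <- if (cluster_columns && ncol(enc) > 2) hierarchical_order(enc, "columns") else NULL
  long <- tibble::as_tibble(calls)
  long[[unit]] <- factor(long[[unit]], levels = rev(apply_ordering(unique(long[[unit]]), ro)))
  long$sample <- factor(long$sample, levels = apply_ordering(unique(long$sample), co))
  long$status <- factor(long$status, levels = c("gain", "none", "loss"))
  ggplot2::ggplot(long, ggplot2::aes(x = .data$sample, y = .data[[unit]],
                                     fill = .data$status)) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_manual(values = c(gain = "#B2182B", none = "#F7F7F7",
                                          loss = "#2166AC"),
                               drop = FALSE, name = "call") +
    ggplot2::labs(x = "sample", y = unit) +
    heatmap_theme()
}

#' @rdname plot_call_heatmap
#' @param object A `cna_calls` object.
#' @param ... Passed to [plot_call_heatmap()].
#' @method autoplot cna_calls
#' @export
autoplot.cna_calls <- function(object, ...) plot_call_heatmap(object, ...)

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

heatmap_theme <- function() {
  ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 90, vjust = 0.5,
                                                       size = 5),
                   axis.text.y = ggplot2::element_text(size = 6),
                   panel.grid = ggplot2::element_blank())
}
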