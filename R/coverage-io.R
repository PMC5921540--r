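# Reading and writing coverage matrices, gene annotations and call tables.
# Input dialect: strict TSV, UTF-8, header row of sample ids, first column
# amplicon ids, no quoting.

#' Read a tab-separated coverage matrix
#'
#' Reads one or several TSV files with amplicon identifiers in the first
#' column and one column of read coverages per sample. When several paths are
#' given, the files must carry an identical amplicon column (same ids, same
#' order) and disjoint sample ids; their sample columns are concatenated, as
#' when cohorts are uploaded as several files.
#'
#' @param path Character vector of one or more file paths.
#' @return A wide tibble (`amplicon` column plus one numeric column per
#'   sample) at stage `"raw"`, row and column order preserved from the file.
#' @details Duplicate amplicon or sample identifiers, non-numeric cells and
#'   ragged rows are rejected with errors naming the offending location.
#'   Amplicons with zero coverage in every sample are rejected, because they
#'   make median scaling degenerate and almost always indicate a failed
#'   amplicon that should be removed upstream.
#' @examples
#' tf <- tempfile(fileext = ".tsv")
#' writeLines(c("amplicon\tS1\tS2", "ERBB2_1\t100\t220", "ERBB2_2\t90\t250"), tf)
#' read_coverage_matrix(tf)
#' @export
read_coverage_matrix <- function(path) {
  stopifnot(is.character(path), length(path) >= 1)
  parts <- lapply(path, read_one_coverage)
  out <- parts[[1]]
  if (length(parts) > 1) {
    for (p in parts[-1]) {
      if (!identical(out$amplicon, p$amplicon)) {
        stop("Cannot column-concatenate: amplicon rows differ between files.",
             call. = FALSE)
      }
      out <- dplyr::bind_cols(out, p[, -1, drop = FALSE],
                              .name_repair = "minimal")
    }
    attr(out, "stage") <- "raw"
  }
  validate_coverage_tbl(out)
  m <- coverage_matrix(out)
  all_zero <- rownames(m)[rowSums(m) == 0]
  if (length(all_zero) > 0) {
    stop(sprintf(paste0("Amplicon(s) with zero coverage in every sample: %s. ",
                        "Remove them before analysis; their median scaling ",
                        "is undefined."),
                 paste(all_zero, collapse = ", ")), call. = FALSE)
  }
  out
}

read_one_coverage <- function(path) {
  if (!file.exists(path)) stop(sprintf("File not found: %s", path), call. = FALSE)
  raw <- readr::read_tsv(path, col_types = readr::cols(.default = readr::col_character()),
                         name_repair = "minimal", progress = FALSE,
                         quote = "", na = character())
  prob <- readr::problems(raw)
  if (nrow(prob) > 0) {
    p1 <- prob[1, ]
    stop(sprintf("Malformed TSV at %s row %d: %s", path, p1$row,
                 p1$expected), call. = FALSE)
  }
  if (ncol(raw) < 2) {
    stop(sprintf("%s: need an amplicon id column plus at least one sample column.",
                 path), call. = FALSE)
  }
  amp <- raw[[1]]
  check_unique(amp, "amplicon")
  check_unique(names(raw)[-1], "sample")
  vals <- matrix(NA_real_, nrow(raw), ncol(raw) - 1L,
                 dimnames = list(amp, names(raw)[-1]))
  for (j in 2:ncol(raw)) {
    v <- suppressWarnings(as.numeric(raw[[j]]))
    bad <- which(is.na(v))
    if (length(bad) > 0) {
      stop(sprintf("Non-numeric cell in %s: row %d (amplicon '%s'), column '%s' (value '%s').",
                   path, bad[1], amp[bad[1]], names(raw)[j], raw[[j]][bad[1]]),
           call. = FALSE)
    }
    vals[, j - 1L] <- v
  }
  if (any(vals < 0)) stop(sprintf("%s: negative coverage values.", path), call. = FALSE)
  new_coverage_tbl(vals, stage = "raw")
}

#' Write a coverage or copy-number table as TSV
#'
#' @param x Wide tibble as produced by [read_coverage_matrix()],
#'   [estimate_copy_numbers()] or [summarize_gene_cn()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_coverage_matrix <- function(x, path) {
  readr::write_tsv(x, path, progress = FALSE)
  invisible(path)
}

#' Derive the amplicon-to-gene map from amplicon identifiers
#'
#' Amplicon panels conventionally name amplicons `<GENE><delim><index>`;
#' the gene is everything before the first delimiter occurrence.
#'
#' @param amplicon_ids Character vector of unique amplicon identifiers.
#' @param delimiter Single string separating gene from amplicon index
#'   (default `"_"`). Gene names must not contain it.
#' @return A tibble with columns `amplicon` and `gene`; gene order follows
#'   first appearance.
#' @examples
#' parse_gene_map(c("ERBB2_1", "ERBB2_2", "FGFR1_1"))
#' @export
parse_gene_map <- function(amplicon_ids, delimiter = "_") {
  stopifnot(is.character(amplicon_ids), length(amplicon_ids) > 0,
            is.character(delimiter), nchar(delimiter) > 0)
  check_unique(amplicon_ids, "amplicon")
  missing_delim <- amplicon_ids[!grepl(delimiter, amplicon_ids, fixed = TRUE)]
  if (length(missing_delim) > 0) {
    stop(sprintf("Amplicon id(s) without delimiter '%s': %s",
                 delimiter, paste(missing_delim, collapse = ", ")),
         call. = FALSE)
  }
  genes <- vapply(strsplit(amplicon_ids, delimiter, fixed = TRUE),
                  function(p) p[[1]], character(1))
  tibble::tibble(amplicon = amplicon_ids, gene = genes)
}

#' Read an amplicon-to-gene annotation file
#'
#' Two-column TSV with header `amplicon<TAB>gene`, one row per amplicon.
#'
#' @param path File path.
#' @param amplicon_ids Optional character vector; when given, the annotation
#'   must cover every id exactly once (ids missing from the file raise an
#'   error listing them) and rows are returned in `amplicon_ids` order.
#' @return A tibble with columns `amplicon` and `gene`.
#' @export
read_gene_map <- function(path, amplicon_ids = NULL) {
  gm <- readr::read_tsv(path, col_types = "cc", progress = FALSE)
  if (!all(c("amplicon", "gene") %in% names(gm))) {
    stop("Gene annotation must have columns 'amplicon' and 'gene'.", call. = FALSE)
  }
  gm <- gm[, c("amplicon", "gene")]
  check_unique(gm$amplicon, "amplicon")
  if (!is.null(amplicon_ids)) {
    missing <- setdiff(amplicon_ids, gm$amplicon)
    if (length(missing) > 0) {
      stop(sprintf("Amplicon(s) missing from annotation: %s",
                   paste(missing, collapse = ", ")), call. = FALSE)
    }
    gm <- gm[match(amplicon_ids, gm$amplicon), ]
  }
  gm
}

#' Gene sizes n(g) of a gene map
#'
#' @param gene_map Tibble with columns `amplicon`, `gene`.
#' @return Tibble with columns `gene`, `n` in first-appearance gene order.
#' @export
gene_sizes <- function(gene_map) {
  gene_map %>%
    dplyr::count(gene = factor(.data$gene, levels = unique(.data$gene)),
                 name = "n") %>%
    dplyr::mutate(gene = as.character(.data$gene))
}

#' Write called copy number alterations
#'
#' Three layouts are supported, mirroring the downloadable tables of the
#' interactive original: a gene-by-sample status `matrix`
#' (gain/loss/none per cell), a `gene_list` with one row per called
#' alteration sorted by gene then sample, and a `sample_list` sorted by
#' sample with each sample's intra-gene inconsistency repeated on its rows.
#'
#' @param calls A call set from [call_cnas()] or [run_amplicon_wise()].
#' @param path Output path.
#' @param layout One of `"matrix"`, `"gene_list"`, `"sample_list"`.
#' @param qc QC tibble from [compute_igi()]; required for
#'   `layout = "sample_list"`.
#' @return `path`, invisibly.
#' @export
write_calls <- function(calls, path,
                        layout = c("matrix", "gene_list", "sample_list"),
                        qc = NULL) {
  layout <- match.arg(layout)
  unit <- call_unit(calls)
  if (layout == "matrix") {
    wide <- calls %>%
      dplyr::select(dplyr::all_of(c(unit, "sample", "status"))) %>%
      tidyr::pivot_wider(names_from = "sample", values_from = "status")
    readr::write_tsv(wide, path, progress = FALSE)
    return(invisible(path))
  }
  hits <- calls %>%
    dplyr::filter(.data$status != "none") %>%
    dplyr::select(dplyr::all_of(c(unit, "sample", "status", "cn", "p_adj",
                                  "support_count")))
  if (layout == "gene_list") {
    hits <- dplyr::arrange(hits, .data[[unit]], .data$sample)
  } else {
    if (is.null(qc)) {
      stop("layout = 'sample_list' needs the QC table from compute_igi().",
           call. = FALSE)
    }
    hits <- hits %>%
      dplyr::left_join(qc[, c("sample", "igi")], by = "sample") %>%
      dplyr::arrange(.data$sample, .data[[unit]])
  }
  readr::write_tsv(hits, path, progress = FALSE)
  invisible(path)
}

#' Read back a written call table
#'
#' Inverse of [write_calls()] for round-trip checks and downstream use.
#'
#' @param path File path.
#' @param layout Layout the file was written with.
#' @return For `"matrix"`, a long tibble of cellwise statuses; for the list
#'   layouts, the call records as written.
#' @export
read_calls <- function(path, layout = c("matrix", "gene_list", "sample_list")) {
  layout <- match.arg(layout)
  if (layout == "matrix") {
    wide <- readr::read_tsv(path, col_types = readr::cols(.default = readr::col_character()),
                            progress = FALSE)
    unit <- names(wide)[1]
    return(tidyr::pivot_longer(wide, -1, names_to = "sample",
                               values_to = "status"))
  }
  readr::read_tsv(path, col_types = readr::cols(
    sample = readr::col_character(), status = readr::col_character(),
    cn = readr::col_double(), p_adj = readr::col_double(),
    support_count = readr::col_integer(),
    .default = readr::col_guess()), progress = FALSE)
}

call_unit <- function(calls) {
  if ("gene" %in% names(calls)) "gene" else "amplicon"
}
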