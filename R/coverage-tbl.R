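#' @keywords internal
"_PACKAGE"

#' @importFrom rlang .data
#' @importFrom dplyr %>%
NULL

# A coverage table is a wide tibble: first column `amplicon` (character,
# unique), remaining columns one per sample (numeric). The processing stage
# travels in attr "stage": "raw" -> "sample_normalized" -> "copy_number".
# Gene-level tables use a first column `gene` instead.

STAGES <- c("raw", "sample_normalized", "copy_number")

new_coverage_tbl <- function(mat, stage, id_col = "amplicon",
                             reference_used = NULL) {
  out <- tibble::as_tibble(as.data.frame(mat, check.names = FALSE),
                           .name_repair = "minimal")
  out <- tibble::add_column(out, !!id_col := rownames(mat), .before = 1)
  attr(out, "stage") <- stage
  if (!is.null(reference_used)) attr(out, "reference_used") <- reference_used
  out
}

#' Extract the numeric matrix underlying a coverage table
#'
#' @param x A wide coverage or copy-number tibble (id column first).
#' @return A numeric matrix with the id column as rownames and sample
#'   identifiers as colnames.
#' @keywords internal
#' @noRd
coverage_matrix <- function(x) {
  stopifnot(is.data.frame(x), ncol(x) >= 2)
  ids <- as.character(x[[1]])
  m <- as.matrix(x[, -1, drop = FALSE])
  storage.mode(m) <- "double"
  rownames(m) <- ids
  m
}

cov_stage <- function(x) attr(x, "stage") %||% "raw"

`%||%` <- function(a, b) if (is.null(a)) b else a

check_stage <- function(x, expected, fun) {
  st <- cov_stage(x)
  if (!identical(st, expected)) {
    stop(sprintf("%s() expects a coverage table at stage '%s', got '%s'.",
                 fun, expected, st), call. = FALSE)
  }
  invisible(x)
}

check_unique <- function(ids, what) {
  dup <- unique(ids[duplicated(ids)])
  if (length(dup) > 0) {
    stop(sprintf("Duplicate %s identifier(s): %s", what,
                 paste(dup, collapse = ", ")), call. = FALSE)
  }
  invisible(ids)
}

validate_coverage_tbl <- function(x, id_col = "amplicon") {
  if (!is.data.frame(x) || ncol(x) < 2) {
    stop("A coverage table needs an id column plus at least one sample column.",
         call. = FALSE)
  }
  check_unique(as.character(x[[1]]), id_col)
  check_unique(names(x)[-1], "sample")
  m <- coverage_matrix(x)
  if (anyNA(m)) stop("Coverage table contains missing values.", call. = FALSE)
  if (cov_stage(x) != "copy_number" && any(m < 0)) {
    stop("Coverage values must be non-negative.", call. = FALSE)
  }
  invisible(x)
}

sample_ids <- function(x) names(x)[-1]

# median with the midpoint convention for even counts (stats::median default)
col_medians <- function(m) apply(m, 2, stats::median)
row_medians <- function(m) apply(m, 1, stats::median)
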