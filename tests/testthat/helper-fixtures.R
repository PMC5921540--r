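# Fixtures are built in code; nothing is stored on disk.

# wide coverage tibble from a matrix with dimnames
cov_tbl <- function(m, stage = "raw") {
  out <- tibble::as_tibble(as.data.frame(m, check.names = FALSE),
                           .name_repair = "minimal")
  out <- tibble::add_column(out, amplicon = rownames(m), .before = 1)
  attr(out, "stage") <- stage
  out
}

mat_of <- function(x) {
  m <- as.matrix(x[, -1, drop = FALSE])
  rownames(m) <- x[[1]]
  m
}

write_cov_tsv <- function(tbl, path = tempfile(fileext = ".tsv")) {
  readr::write_tsv(tbl, path, progress = FALSE)
  path
}

# small deterministic raw cohort: 3 genes x 2 amplicons, 6 samples
tiny_cohort <- function(seed = 11) {
  set.seed(seed)
  amps <- c("AKT1_1", "AKT1_2", "ERBB2_1", "ERBB2_2", "MYC_1", "MYC_2")
  m <- matrix(round(rlnorm(36, log(500), 0.2)), 6, 6,
              dimnames = list(amps, paste0("S", 1:6)))
  cov_tbl(m)
}

# independent step-up FDR adjustment, straight from the definition
bh_brute <- function(p) {
  n <- length(p)
  o <- order(p)
  adj <- numeric(n)
  running <- Inf
  for (i in n:1) {
    running <- min(running, n / i * p[o[i]])
    adj[o[i]] <- min(1, running)
  }
  adj
}

# closed-form chi-square survival for 4 degrees of freedom
chisq_sf_df4 <- function(x) exp(-x / 2) * (1 + x / 2)
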