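test_that("sample normalization divides each column by its own median", {
  m <- matrix(c(100, 200, 300), 3, 1, dimnames = list(paste0("G_", 1:3), "S1"))
  out <- normalize_samples(cov_tbl(m))
  expect_equal(out$S1, c(0.5, 1.0, 1.5))
  expect_identical(attr(out, "stage"), "sample_normalized")

  const <- matrix(7, 3, 1, dimnames = list(paste0("G_", 1:3), "S1"))
  expect_equal(normalize_samples(cov_tbl(const))$S1, c(1, 1, 1))

  # even count: midpoint-of-order-statistics median, checked independently
  even <- matrix(c(1, 2, 3, 4), 4, 1, dimnames = list(paste0("G_", 1:4), "S1"))
  expect_equal(normalize_samples(cov_tbl(even))$S1, c(1, 2, 3, 4) / 2.5)
  expect_equal(stats::median(c(1, 2, 3, 4)), 2.5)

  dead <- matrix(c(0, 0, 0, 1, 5, 9), 3, 2,
                 dimnames = list(paste0("G_", 1:3), c("bad", "ok")))
  expect_error(normalize_samples(cov_tbl(dead)), "median amplicon coverage 0.*bad")
})

test_that("every sample's median is 1 after sample normalization", {
  sim <- simulate_cohort(n_genes = 10, n_samples = 31, seed = 21)
  out <- normalize_samples(sim$coverage)
  meds <- apply(mat_of(out), 2, median)
  expect_equal(unname(meds), rep(1, 31))
})

test_that("copy numbers scale amplicons by their median and multiply by two", {
  m <- matrix(c(0.5, 1.0, 2.0), 1, 3,
              dimnames = list("G_1", paste0("S", 1:3)))
  cn <- estimate_copy_numbers(cov_tbl(m, stage = "sample_normalized"))
  expect_equal(unname(mat_of(cn))[1, ], c(1, 2, 4))
  expect_false(attr(cn, "reference_used"))

  # a sample sitting at its amplicon's cross-sample median gets CN exactly 2
  sim <- simulate_cohort(n_genes = 8, n_samples = 25, seed = 8)
  cn2 <- estimate_copy_numbers(normalize_samples(sim$coverage))
  cmat <- mat_of(cn2)
  expect_equal(unname(apply(cmat, 1, median)), rep(2, nrow(cmat)))
  expect_true(all(cmat >= 0))
})

test_that("a unit reference leaves copy numbers at twice the target values", {
  m <- matrix(c(0.8, 1.2, 1.0, 1.0), 2, 2,
              dimnames = list(c("A_1", "B_1"), c("S1", "S2")))
  ref <- matrix(1, 2, 3, dimnames = list(c("A_1", "B_1"), c("R1", "R2", "R3")))
  cn <- estimate_copy_numbers(cov_tbl(m, stage = "sample_normalized"),
                              reference = cov_tbl(ref, stage = "sample_normalized"))
  expect_equal(unname(mat_of(cn)), unname(2 * m))
  expect_true(attr(cn, "reference_used"))

  # reference rows may come in a different order; alignment is by id
  ref2 <- ref[2:1, , drop = FALSE]
  cn2 <- estimate_copy_numbers(cov_tbl(m, stage = "sample_normalized"),
                               reference = cov_tbl(ref2, stage = "sample_normalized"))
  expect_equal(mat_of(cn2), mat_of(cn))

  mism <- matrix(1, 2, 2, dimnames = list(c("A_1", "C_1"), c("R1", "R2")))
  expect_error(estimate_copy_numbers(cov_tbl(m, stage = "sample_normalized"),
                                     reference = cov_tbl(mism, stage = "sample_normalized")),
               "amplicon set")
})

test_that("a raw reference cohort is sample-normalized before its medians are used", {
  set.seed(4)
  ref_m <- matrix(rlnorm(40, log(300), 0.3), 4, 10,
                  dimnames = list(paste0("G_", 1:4), paste0("R", 1:10)))
  tgt_m <- matrix(rlnorm(20, log(300), 0.3), 4, 5,
                  dimnames = list(paste0("G_", 1:4), paste0("S", 1:5)))
  tgt <- normalize_samples(cov_tbl(tgt_m))
  via_raw <- estimate_copy_numbers(tgt, reference = cov_tbl(ref_m))
  via_norm <- estimate_copy_numbers(tgt, reference = normalize_samples(cov_tbl(ref_m)))
  expect_equal(mat_of(via_raw), mat_of(via_norm))
  # scaling the reference's depth must not leak into the copy-number scale
  via_scaled <- estimate_copy_numbers(tgt, reference = cov_tbl(ref_m * 37))
  expect_equal(mat_of(via_scaled), mat_of(via_raw))
})

test_that("copy numbers are invariant to per-sample depth rescaling", {
  sim <- simulate_cohort(n_genes = 6, n_samples = 11, seed = 13)
  cov <- sim$coverage
  cn1 <- estimate_copy_numbers(normalize_samples(cov))
  scaled <- cov
  scaled[[3]] <- scaled[[3]] * 1234.5   # one sample re-sequenced deeper
  attr(scaled, "stage") <- "raw"
  cn2 <- estimate_copy_numbers(normalize_samples(scaled))
  expect_equal(mat_of(cn1), mat_of(cn2))
})

test_that("sample reordering only permutes copy-number columns", {
  sim <- simulate_cohort(n_genes = 6, n_samples = 9, seed = 17)
  cov <- sim$coverage
  perm <- c(1, 1 + sample(9))
  cov_p <- cov[, perm]
  attr(cov_p, "stage") <- "raw"
  cn <- mat_of(estimate_copy_numbers(normalize_samples(cov)))
  cn_p <- mat_of(estimate_copy_numbers(normalize_samples(cov_p)))
  expect_equal(cn_p, cn[, colnames(cn_p)])
})

test_that("gene summaries are unweighted amplicon means", {
  m <- matrix(c(1.8, 2.2, 2, 2, 8, 3), 3, 2, byrow = TRUE,
              dimnames = list(c("A_1", "A_2", "B_1"), c("S1", "S2")))
  # A has CNs (1.8, 2) and (2.2, 2) per sample; B single amplicon
  cn <- cov_tbl(m, stage = "copy_number")
  gm <- parse_gene_map(rownames(m))
  g <- summarize_gene_cn(cn, gm)
  expect_equal(g$S1, c(mean(c(1.8, 2)), 8))
  expect_equal(g$S2, c(mean(c(2.2, 2)), 3))
  expect_error(summarize_gene_cn(cn, tibble::tibble(amplicon = "Z_1", gene = "Z")),
               "absent")
})

test_that("worked gene means match direct computation", {
  m <- matrix(c(1.8, 2.2, 2, 2, 8, 100), 6, 1,
              dimnames = list(c("A_1", "A_2", "B_1", "C_1", "C_2", "C_3"), "S1"))
  g <- summarize_gene_cn(cov_tbl(m, stage = "copy_number"),
                         parse_gene_map(rownames(m)))
  expect_equal(g$S1, c(2, 2, mean(c(2, 8, 100))))
})
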