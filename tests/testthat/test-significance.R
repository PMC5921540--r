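test_that("null spread is the normal-consistent scaled MAD per amplicon", {
  m <- matrix(c(1.8, 1.9, 2.0, 2.1, 2.2), 1, 5,
              dimnames = list("G_1", paste0("S", 1:5)))
  nulls <- fit_null_models(cov_tbl(m, stage = "copy_number"))
  expect_equal(nulls$sigma, 1.4826 * 0.1)
  expect_false(nulls$degenerate)

  const <- matrix(2, 1, 5, dimnames = list("G_1", paste0("S", 1:5)))
  expect_true(fit_null_models(cov_tbl(const, stage = "copy_number"))$degenerate)

  # a single outlier cannot rescue a zero MAD: the amplicon stays degenerate
  robust <- matrix(c(2, 2, 2, 10), 1, 4, dimnames = list("G_1", paste0("S", 1:4)))
  nr <- fit_null_models(cov_tbl(robust, stage = "copy_number"))
  expect_equal(nr$sigma, 0)
  expect_true(nr$degenerate)
})

test_that("outlier p-values are one-sided normal tails around CN = 2", {
  m <- matrix(c(2, 2.392, 1.608, 2.1), 1, 4,
              dimnames = list("G_1", paste0("S", 1:4)))
  nulls <- tibble::tibble(amplicon = "G_1", sigma = 0.2, degenerate = FALSE)
  tab <- amplicon_pvalues(cov_tbl(m, stage = "copy_number"), nulls)
  expect_equal(tab$p_gain[1], 0.5)
  expect_equal(tab$p_loss[1], 0.5)
  expect_equal(tab$p_gain[2], pnorm(1.96, lower.tail = FALSE))
  expect_equal(tab$p_gain[2], 0.0250, tolerance = 1e-3)
  # independent CDF route: complementary error function
  z <- (as.vector(m) - 2) / 0.2
  expect_equal(tab$p_gain, 0.5 * pracma::erfc(z / sqrt(2)), tolerance = 1e-12)
  expect_equal(tab$p_gain + tab$p_loss, rep(1, 4))

  expect_error(amplicon_pvalues(cov_tbl(m, stage = "copy_number"),
                                tibble::tibble(amplicon = "X_1", sigma = 1,
                                               degenerate = FALSE)),
               "different amplicon set")
})

test_that("degenerate amplicons are uncallable in both directions", {
  m <- matrix(c(2, 50, 2, 2), 2, 2,
              dimnames = list(c("A_1", "B_1"), c("S1", "S2")))
  nulls <- tibble::tibble(amplicon = c("A_1", "B_1"), sigma = c(0, 0.1),
                          degenerate = c(TRUE, FALSE))
  tab <- amplicon_pvalues(cov_tbl(m, stage = "copy_number"), nulls)
  degen <- tab[tab$amplicon == "A_1", ]
  expect_true(all(degen$p_gain == 1) && all(degen$p_loss == 1))
})

test_that("Fisher combination matches the closed form and is order-invariant", {
  mk_tab <- function(p_gain, amps) {
    out <- tibble::tibble(amplicon = amps, sample = "S1", cn = 3,
                          p_gain = p_gain, p_loss = 1 - p_gain,
                          degenerate = FALSE)
    attr(out, "axis") <- "amplicon"
    out
  }
  gm <- tibble::tibble(amplicon = c("G_1", "G_2"), gene = c("G", "G"))

  # single amplicon: combination is the identity
  one <- combine_fisher(mk_tab(0.03, "G_1"), gm[1, ])
  expect_equal(one$p_gain, 0.03)

  two <- combine_fisher(mk_tab(c(0.5, 0.5), c("G_1", "G_2")), gm)
  x2 <- -2 * (log(0.5) + log(0.5))
  expect_equal(x2, 2.77259, tolerance = 1e-5)
  expect_equal(two$p_gain, chisq_sf_df4(x2), tolerance = 1e-12)
  expect_equal(two$p_gain, 0.59657, tolerance = 1e-5)

  two2 <- combine_fisher(mk_tab(c(0.01, 0.04), c("G_1", "G_2")), gm)
  expect_equal(two2$p_gain, chisq_sf_df4(-2 * (log(0.01) + log(0.04))),
               tolerance = 1e-12)
  expect_equal(two2$p_gain, 0.00353, tolerance = 1e-3)

  # order of amplicons within the gene is irrelevant
  two3 <- combine_fisher(mk_tab(c(0.04, 0.01), c("G_1", "G_2")), gm)
  expect_equal(two3$p_gain, two2$p_gain)
})

test_that("Fisher combination skips degenerate amplicons and clamps zeros", {
  tab <- tibble::tibble(amplicon = c("G_1", "G_2"), sample = "S1", cn = 2,
                        p_gain = c(0.03, 1), p_loss = c(0.97, 1),
                        degenerate = c(FALSE, TRUE))
  attr(tab, "axis") <- "amplicon"
  gm <- tibble::tibble(amplicon = c("G_1", "G_2"), gene = c("G", "G"))
  out <- combine_fisher(tab, gm)
  expect_equal(out$p_gain, 0.03)  # only the live amplicon counts
  expect_equal(out$n_amplicons, 1L)

  all_deg <- dplyr::mutate(tab, degenerate = TRUE)
  attr(all_deg, "axis") <- "amplicon"
  out2 <- combine_fisher(all_deg, gm)
  expect_true(out2$degenerate)
  expect_equal(out2$p_gain, 1)

  zero <- dplyr::mutate(tab, p_gain = c(0, 0.5), degenerate = FALSE)
  attr(zero, "axis") <- "amplicon"
  expect_warning(outz <- combine_fisher(zero, gm), "clamped")
  expect_true(outz$p_gain > 0)
  expect_equal(attr(outz, "n_clamped"), 1L)
})

test_that("Bonferroni and BH corrections match brute force on small tables", {
  # all matrices up to 5x5, several random fills, both scopes and methods
  set.seed(99)
  for (nu in 1:5) for (ns in 1:5) {
    units <- paste0("g", seq_len(nu))
    samples <- paste0("s", seq_len(ns))
    tab <- tibble::tibble(
      gene = rep(units, each = ns), sample = rep(samples, nu),
      p_gain = runif(nu * ns), p_loss = runif(nu * ns))
    attr(tab, "axis") <- "gene"

    both_bonf <- correct_pvalues(tab, "both", "bonferroni")
    expect_equal(both_bonf$p_gain_adj, pmin(1, tab$p_gain * nu * ns),
                 tolerance = 1e-12)
    both_bh <- correct_pvalues(tab, "both", "bh")
    expect_equal(both_bh$p_gain_adj, bh_brute(tab$p_gain), tolerance = 1e-12)
    expect_equal(both_bh$p_loss_adj, bh_brute(tab$p_loss), tolerance = 1e-12)

    smp_bonf <- correct_pvalues(tab, "samples", "bonferroni")
    expect_equal(smp_bonf$p_gain_adj, pmin(1, tab$p_gain * ns), tolerance = 1e-12)
    gen_bonf <- correct_pvalues(tab, "genes", "bonferroni")
    expect_equal(gen_bonf$p_gain_adj, pmin(1, tab$p_gain * nu), tolerance = 1e-12)

    smp_bh <- correct_pvalues(tab, "samples", "bh")
    for (u in units) {
      expect_equal(smp_bh$p_gain_adj[smp_bh$gene == u],
                   bh_brute(tab$p_gain[tab$gene == u]), tolerance = 1e-12)
    }

    none <- correct_pvalues(tab, "none", "bh")
    expect_equal(none$p_gain_adj, tab$p_gain)
  }
})

test_that("corrected p-values never fall below raw ones", {
  sim <- simulate_cohort(n_genes = 7, n_samples = 15, n_spiked_genes = 2,
                         spike_fraction = 0.2, seed = 7)
  cn <- estimate_copy_numbers(normalize_samples(sim$coverage))
  tab <- amplicon_pvalues(cn)
  for (scope in c("both", "samples", "genes", "none")) {
    for (method in c("bonferroni", "bh")) {
      adj <- correct_pvalues(tab, scope, method)
      expect_true(all(adj$p_gain_adj >= adj$p_gain - 1e-15))
      expect_true(all(adj$p_loss_adj >= adj$p_loss - 1e-15))
      expect_true(all(adj$p_gain_adj <= 1 & adj$p_gain_adj >= 0))
    }
  }
})

test_that("a known spiked amplification is found with a tiny combined p-value", {
  sim <- simulate_cohort(n_genes = 10, n_samples = 40, n_spiked_genes = 1,
                         spike_fraction = 0.1, spike_cn = 8, seed = 31)
  cn <- estimate_copy_numbers(normalize_samples(sim$coverage))
  gm <- parse_gene_map(cn$amplicon)
  gtab <- combine_fisher(amplicon_pvalues(cn), gm)
  spiked <- sim$truth[sim$truth$label == "gain", ]
  hit <- dplyr::semi_join(gtab, spiked, by = c("gene", "sample"))
  expect_true(all(hit$p_gain < 1e-10))
})
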