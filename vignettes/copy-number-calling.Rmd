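---
title: "Copy-number calling from amplicon coverage: model, choices, limits"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Copy-number calling from amplicon coverage: model, choices, limits}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ampliconcna)
```

## The model

Targeted amplicon sequencing reads out, per amplicon $a$ and sample $s$, a
coverage that is approximately proportional to

$$\mathrm{cov}(a,s) \;\propto\; d_s \cdot e_a \cdot \frac{\mathrm{CN}(a,s)}{2}
\cdot \varepsilon_{a,s},$$

with a per-sample depth factor $d_s$, a per-amplicon amplification
efficiency $e_a$ (spanning orders of magnitude between primer pairs), the
local copy number relative to the diploid two alleles, and multiplicative
noise $\varepsilon$. Two median scalings remove the nuisance factors: each
sample is divided by the median of its amplicon coverages (depth), then
each amplicon by its median normalized coverage over a reference cohort
or, absent one, over the target cohort itself (efficiency), and the result
is doubled:

$$\mathrm{CN}(a,s) = 2\,\frac{x(a,s)}{\mathrm{med}_a}.$$

Medians rather than means make both scalings robust to the alterations the
method is trying to find — provided an alteration is present in **under
half the cohort** for that amplicon, otherwise the amplicon median absorbs
it and the estimate recenters on the altered state. The simulator enforces
this constraint (`spike_fraction < 0.5`) for the same reason.

Significance is a per-amplicon outlier test: a normal null centered at
$\mathrm{CN}=2$ with spread $\sigma_a = 1.4826 \cdot \mathrm{MAD}_s\,
\mathrm{CN}(a,s)$ (the constant makes the MAD consistent for the normal
standard deviation), one-sided upper and lower tail p-values per cell, so
$p_\text{gain} + p_\text{loss} = 1$. Keeping the two directions separate
gives each its own table and call set; the center is pinned at 2 rather
than estimated because systematic deviation of the typical sample from
diploid is exactly what the test should flag, not absorb. In gene-wise
mode the $n(g)$ amplicon p-values of a gene combine through Fisher's
statistic $X^2 = -2\sum \ln p \sim \chi^2_{2n(g)}$, and gene copy number
is the plain amplicon mean. Bonferroni or Benjamini–Hochberg correction is
applied over a selectable multiplicity scope — across samples, across
genes, across both (the default: one family of all gene–sample cells per
direction), or not at all; the uncorrected mode is deliberately flagged in
the run log as suitable only for candidate screening with independent
confirmation.

A gain is called where the corrected gain p-value is below $\alpha$ *and*
the gene copy number exceeds 2; symmetrically for losses. Because the gene
copy number fixes the direction, at most one direction can be called per
cell. Optionally a call must be *supported* by at least $k$ (or
$\lceil f \cdot n(g)\rceil$; the ceiling makes "50% of 3 amplicons" mean
2) of the gene's amplicons individually called at amplicon resolution
under the same correction scope, method and $\alpha$. Support counting at
the corrected (not raw) amplicon level was a genuinely open choice; the
corrected level was chosen because an amplicon "call" is only defined
after correction. Without a support filter, no support is required —
Fisher evidence alone can carry a gene call even when no single amplicon
passes its own corrected threshold, and filtering those out silently would
change the method's headline behaviour.

## Quality control and display

The intra-gene inconsistency

$$\mathrm{IGI}(s)=\sum_{g}\sqrt{\frac{1}{n(g)-1}
\sum_{a\in A(g)}\big[\mathrm{CN}(a,s)-\mathrm{CN}(g,s)\big]^2}$$

sums, over genes with at least two amplicons, the within-gene standard
deviation of a sample's amplicon copy numbers. Amplicons of one gene
interrogate the same locus, so disagreement is technical, typically from
degraded DNA. Single-amplicon genes are mathematically outside the formula
($n(g)-1 = 0$) and are excluded but reported. No exclusion threshold is
imposed: IGI is a ranking aid, not a gate.

Heatmaps of copy numbers (diverging scale centered at 2) and of calls
(three-state) can cluster either axis with Manhattan distance and
average linkage. The agglomeration is implemented in the package with two
deterministic conventions: among equal-distance merge candidates the pair
with the lexicographically smallest representative identifiers merges
first, and at each merge the subtree with the smaller representative is
placed left. This makes orderings bit-reproducible *and* invariant to the
row order of the input, which `stats::hclust` does not guarantee under
ties; on tie-free data the merge heights agree with
`hclust(method = "average")` exactly (this is tested). Leaving samples
unclustered preserves run order, useful for spotting batch effects.

## The simulator

`simulate_cohort()` draws from the generative model above: lognormal depth
factors (sdlog 0.5, the spread of library yields seen across a typical
run), lognormal amplicon efficiencies (sdlog 1 — coverages in real panels
span orders of magnitude), lognormal cell noise (sdlog 0.05, i.e. about a
5% coefficient of variation, roughly 0.1 on the copy-number scale — the
tight end of what passes panel QC), and clonal alterations diluted by
tumor purity, $\mathrm{CN}_\text{bulk} = \rho\,\mathrm{CN}_\text{clonal} +
(1-\rho)\cdot 2$. The default panel shape is 48 genes at 2 amplicons each
with 100 samples, a mid-size cancer panel and cohort. What it does *not*
model: GC or amplicon-length biases, batch structure, correlated
degradation (the things IGI exists to catch), subclonal mixtures, or
read-level sampling noise. Passing recovery tests on simulated cohorts
therefore demonstrates the statistical machinery, not robustness to every
real-world artifact.

At these conditions the pipeline's recovery of clonal CN-6 amplifications
at 5% prevalence is essentially perfect (sensitivity 1, specificity
≈ 0.9995 under Bonferroni-both at $\alpha = 0.05$; recomputed by
`scripts/acceptance.R`). Dilution keeps bulk CN well above the noise even
at purity 0.3 ($0.3 \cdot 6 + 0.7 \cdot 2 = 3.2$), so sensitivity stays
flat down to that purity for high-level amplifications; the purity
limitation bites for low-level gains, where bulk CN approaches the null
spread.

## What "FWER control" does and does not mean here

The Bonferroni mode controls family-wise error *under the fitted null*.
Two structural features make the realized null-cohort FWER substantially
higher than the nominal level, and both are visible in this package's
simulations (null-cohort FWER ≈ 0.8 at the default conditions, reported
honestly by `scripts/acceptance.R`):

1. **Shared normalization noise.** Dividing a sample by its median
   amplicon coverage injects that median's estimation error into every
   cell of the sample. With widely spread amplicon efficiencies the median
   is effectively carried by the few amplicons nearest it, so the error is
   not small, and it is common to all amplicons of the sample (within-gene
   z-score correlations of 0.15–0.35 in simulation). Fisher's method
   assumes independent p-values; positively correlated amplicons make
   joint extremes far more likely than the $\chi^2$ reference implies.
2. **Plug-in spread estimation.** The z-scores use a MAD estimated from
   ~100 samples. The resulting statistic has heavier-than-normal tails
   (akin to a t statistic), and Bonferroni thresholds sit at extreme
   quantiles ($z \approx 4$) where a few percent of spread underestimation
   inflates tail probabilities several-fold. Even with fully independent
   cells, simulation puts the realized FWER near 0.36 at these sizes.

Neither is an implementation artifact — an independent re-implementation
of the identical procedure (numpy/scipy) reproduces the same rates, and
the package's suite cross-checks every analytic component (normal tails,
Fisher closed forms, brute-force BH/Bonferroni) at tolerances of 1e-10 or
tighter. In practice the test is best read as a *ranked screening*
statistic whose corrected p-values overstate certainty near the threshold;
high-amplitude events (the clinically actionable amplifications) sit far
beyond it. On real cohorts the concern is partly self-limiting: genuine
biological spread inflates the MAD and makes calling more conservative,
while the support filter (≥ 2 amplicons) removes most single-amplicon
flukes.

## Numerical and degenerate-input choices

* Medians use the midpoint convention for even counts (`stats::median`).
* An amplicon whose MAD is zero (half or more samples identical) is
  **degenerate**: uncallable, $p = 1$ both directions, excluded from
  Fisher combination, listed in the QC attributes. A gene whose amplicons
  are all degenerate gets $p = 1$.
* $p = 0$ (normal-tail underflow for $|z| \gtrsim 39$) entering Fisher's
  logarithm is clamped to the smallest positive double, with a warning and
  a count; this only makes astronomically significant cells marginally
  less so.
* All-zero amplicons and zero-median samples are rejected with errors
  naming the offenders rather than silently dropped: both make median
  scaling degenerate and indicate assay failure.
* Analysis is fully deterministic — the only randomness in the package is
  the simulator's seeded generator.
* Problem sizes in the test suite (cohorts of 10–100 samples, panels of
  4–48 genes, 200 null replicates for the error-rate estimate) were chosen
  to estimate each property to usefully tight Monte-Carlo error while
  keeping the whole suite quick to run.

## Known limitations

* No segmentation, no allele-specific copy number, no purity estimation:
  the unit of inference is the gene (or amplicon), marginally per sample.
* Without a reference cohort the diploid center is defined by the cohort
  median, so a CNA recurrent in ≥ 50% of samples inverts: the altered
  state becomes the center and the normal samples become the outliers.
* Corrected p-values near the threshold are optimistic (see above); the
  FDR mode inherits the same correlation caveat through its pooled
  p-value family.
* Panels with many single-amplicon genes lose both the support filter and
  the IGI signal for those genes.
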