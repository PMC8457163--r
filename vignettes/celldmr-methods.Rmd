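---
title: "Methods: windowed DMR calling and promoter-resampling overlap tests"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: windowed DMR calling and promoter-resampling overlap tests}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(celldmr)
```

## The analysis problem

Postmortem brain studies of psychiatric disease increasingly profile DNA
methylation in *sorted* nuclei — NeuN-positive (neuronal) and NeuN-negative
(nonneuronal) fractions — because bulk-tissue signal averages over cell types
with very different methylomes. One common readout is a promoter tiling
array hybridised with MBD-captured (densely methylated) DNA: each of tens of
thousands of promoters is covered by a handful of probes, and each probe
yields a log2 methylation-enrichment value per sample.

`celldmr` implements the downstream analysis for a case-control design on
such data:

1. call differentially methylated regions (DMRs) per cell type;
2. summarise how DMR-associated genes are shared between neurons and
   nonneurons;
3. ask whether those genes are differentially expressed in matched
   expression data from the same subjects, after tissue-quality filtering;
4. test whether the DMRs are enriched in — or depleted from — GWAS loci, by
   promoter-based random sampling.

A synthetic-data generator with planted ground truth makes every step
testable: calibration on null data, recovery of planted effects, and power
of the locus-overlap test can all be measured against known truth.

## The DMR statistic

For probe $i$, a Welch (unequal-variance) $t$ statistic compares cases (SZ)
with controls (CT) on the log2 enrichment signal, with
Welch–Satterthwaite degrees of freedom; `mean_diff` $= \bar{x}_{SZ} -
\bar{x}_{CT}$, so positive values mean hypermethylation in cases. Within
each promoter, probes are ordered by position and every run of consecutive
probes whose adjacent gaps are at most `max_gap_bp` (default 300 bp) is
scanned with windows of `min_probes` consecutive probes (default 4). Each
window is scored by the Stouffer combination

$$ S = \frac{1}{\sqrt{m}} \sum_{i=1}^{m} t_i, $$

treating each $t_i$ as a $z$-score. Two null models give the window a
p-value:

* **analytic** — the two-sided normal tail $2\Phi(-|S|)$. Fast and exact
  when probes are independent and per-probe $t$ is close to normal (large
  groups), but anti-conservative when neighbouring probes are positively
  correlated, as methylation enrichment induces.
* **permutation** — group labels are permuted `n_perm` times (one global
  permutation set, recomputing every probe's Welch $t$ per permutation);
  the window's p-value is the add-one-corrected fraction of permutations
  whose *promoter-level maximum* $|S|$ reaches the observed $|S|$. Taking
  the per-promoter maximum makes the p-value a family-wise quantity over
  the promoter's windows, so "this promoter yields a DMR at $\alpha$" is
  calibrated regardless of probe correlation, which the permutations absorb
  automatically.

Windows with $p < $ `threshold_p` are merged when they overlap; the merged
DMR spans their union, keeps the best (smallest) window p-value and its
score, and is assigned the direction (`hyper`/`hypo`) of the mean
`mean_diff` over the merged span. Sets are conventionally built at a
relaxed threshold of $10^{-5}$ and a stringent one of $10^{-7}$; both are
plain arguments, and the stringent value is an explicit configuration choice
rather than a fixed claim. A Benjamini–Hochberg FDR column over all tested
windows is emitted for reference but never used to define the set, matching
the raw-threshold framing of this analysis style.

Degenerate inputs are handled deterministically: zero-variance probes get a
variance floor of $10^{-12}$ (so noise-free fixtures give $t = 0$ rather
than NaN), promoters with fewer than `min_probes` probes are skipped with a
logged count, groups with fewer than two samples are an error, and analytic
p-values are clamped away from exactly 0 so they stay in $(0, 1]$.

### Analytic vs permutation agreement

The permutation null conditions on the observed data; its spread for a
window includes empirical cross-probe covariance terms of order
$1/\sqrt{n}$ even when the true probe correlation is zero. At $n = 35$ per
group individual windows can therefore disagree with the analytic tail by
a factor approaching two in either direction, which is exactly why the
permutation option exists. The agreement property we assert in the test
suite — every single-window promoter within $|\Delta \log_{10} p| < 0.3$ —
is checked at $n = 100$ per group, where these conditional terms are small
and the two nulls coincide for independent noise.

## Cross-cell-type sharing

`dmr_genes()` maps a DMR set to the unique gene symbols of its promoters
(several DMRs in one promoter collapse to one gene; each promoter record
carries exactly one gene). `overlap_summary()` reports the exact
intersection with sharing percentages rounded **half-up** to one decimal —
the convention that reproduces printed percentages such as 59.4%/69.5% from
sets of 69 and 59 genes sharing 41. Empty sets report `NA` percentages
rather than 0, and gene comparison is case-sensitive exact match since all
symbols come from the one universe file. `direction_concordance()` compares
per-gene directions between cell types, flagging genes whose DMRs disagree
within one cell type as `"mixed"`.

## Expression integration

The expression stage mirrors standard postmortem-microarray practice. The
pipeline order is fixed: (1) `exclude_low_ph()` removes subjects with brain
pH below a cutoff (default 6.0, a conventional brain-bank quality bound; the
source protocol does not print its cutoff, so it is an explicit, logged
parameter) and subjects with missing pH; (2) `filter_reliable()` keeps
probes whose signal exceeds a detection floor in at least 80% of subjects in
*each* group — again an explicit operationalisation of a "reliable
expression" call, configurable because detection rules differ across
platforms; (3) `test_dmr_gene_expression()` runs a two-sided Welch test per
remaining probe of the DMR-associated genes and reports per-probe results
plus the distinct-gene count among significant probes, at a nominal
(uncorrected) $\alpha = 0.05$ — deliberately no multiple-testing correction
at this stage, matching the descriptive intent of the assessment. The two
filters commute when reliability is assessed on the post-pH subject set;
fixing the order makes the computation unambiguous.

## GWAS locus overlap by promoter resampling

The sampling unit is the promoter. The observed statistic is the number of
distinct DMR-bearing promoters that intersect ($\geq$ 1 bp, strand ignored)
at least one locus of the trait's interval set. The null resamples $k$
promoters (the number of DMR-bearing promoters) uniformly *without
replacement* from the full universe `B` times (default 10,000) and counts
the same statistic. Empirical p-values are add-one corrected,

$$ p_{\text{enrich}} = \frac{1 + \#\{b : X_b \ge X_{\text{obs}}\}}{B + 1},
\qquad
p_{\text{deplete}} = \frac{1 + \#\{b : X_b \le X_{\text{obs}}\}}{B + 1}, $$

reported separately for the two sides (both count ties, so they sum to at
least $1 + 1/(B+1)$). Under this design the exact null law is
hypergeometric — $k$ draws from $N$ promoters of which $m$ overlap a locus —
which the test suite uses as a closed-form oracle on enumerable fixtures.
Two design choices deserve note. Counting a promoter once no matter how
many DMRs it carries makes the observed statistic exchangeable with the
resampled one. And sampling is unmatched uniform: matching on promoter
length or CpG density is a documented extension point (a weight hook in the
regime-based locus generator exists), not the default, because the simplest
exchangeable frame is the most transparent null.

## What the generator emulates — and what it does not

`sim_config()` defaults define the simulated study conditions:

| parameter | default | meaning |
|---|---|---|
| `n_promoters` | 2,000 | scaled-down universe (structure of a 25,500-promoter array at test-friendly cost) |
| `probes_per_promoter` | 8 | evenly spaced 50-bp probes per 1,000-bp promoter |
| `n_case`, `n_control` | 35 / 35 | the emulated cohort sizes |
| `noise_sd` | 0.5 | marginal log2-signal noise sd |
| `probe_correlation` | 0.3 | exchangeable within-promoter noise correlation |
| `dmr_fraction` | 0.05 | promoters planted with a DMR, per cell type |
| `effect_delta` | 0.5 | planted log2 shift in cases (1.0 × noise sd) |
| `shared_fraction` | 0.6 | planted DMRs shared between the cell types, mirroring the ~59–70% gene-level sharing observed in sorted-nuclei studies |
| `pH_mean`, `pH_sd`, `low_pH_fraction` | 6.5, 0.25, 0.1 | brain pH Normal with an explicit low-pH tail; the distribution only needs to exercise the filter |
| `expr_log2fc`, `expr_noise_sd` | 1.5, 0.5 | planted expression changes on a subset (`de_fraction` = 0.2) of planted-DMR genes |
| `unreliable_fraction` | 0.1 | expression probes emitted at the noise floor |

The noise model is Gaussian on the log2 scale with exchangeable
within-promoter correlation — the simplest structure that captures probe
non-independence. Plants span a promoter's whole probe range, shared plants
keep one direction across cell types, and every planted signal is recorded
in the `TruthTable` (its `de_genes` table is filled by the expression
generator), so truth is exhaustive by construction. Effect sizes are
calibration choices, not estimates: no effect-size distribution for real
DMRs is available.

Deliberately *not* simulated: raw hybridisation intensities and
normalisation, dye and batch effects, hydroxymethylation cross-reactivity,
LD structure in GWAS loci (loci are placed promoter-wise under neutral,
enriched, or depleted regimes), bidirectional promoters (one gene per
promoter record), and realistic genome geography (promoters sit on a
10-kb pitch on synthetic chromosomes). Passing tests therefore demonstrate
calibration and recovery under the stated stochastic structure, not
performance on any real array.

Determinism is part of the contract: every generator and every stochastic
stage (permutation null, resampling null, locus placement) takes a seed,
runs under a save/restore of the caller's RNG state, and is byte-identical
across repeated calls.

## Problem sizes used in the checks

The test suite and `scripts/acceptance.R` choose sizes that make the
statistical assertions sharp while staying quick: null calibration uses the
full default universe (2,000 promoters × 8 probes, 35 + 35 samples, 1,000
permutations; the binomial 99% band around $\alpha$ is then ±1.3 points at
$\alpha = 0.05$); recovery uses 300 promoters with 10% planted at effect
1.0 × noise sd and 2,000 permutations (the smallest `n_perm` that can
resolve $p < 10^{-3}$ with the add-one correction), scored against a
plain-loop brute-force oracle run on the same data; locus-overlap power and
calibration use 500 promoters, 150 loci and 100 replicate locus draws at
$B = 1{,}000$; and the hypergeometric oracle fixture uses 10 promoters with
4 overlapped, where $P(X \ge 2) = 1/3$ exactly.

## Known limitations

* The per-probe statistic treats Welch $t$ as standard normal inside the
  Stouffer sum; at very small group sizes the analytic null is heavier in
  the tails than assumed — use the permutation null there.
* The permutation null shares one global permutation set across promoters.
  Marginal per-promoter calibration is unaffected, but promoter p-values
  are weakly dependent across the array, so genome-wide counts of null
  DMRs have slightly more variance than a binomial model suggests.
* With a permutation null the smallest attainable p-value is
  $1/(\texttt{n\_perm}+1)$; thresholds must respect this resolution.
* The resampling frame is the full universe; restricting it to
  QC-passing promoters is the caller's responsibility (the frame is an
  explicit input).
* One DMR annotates exactly one gene (its promoter's record); bidirectional
  promoter architectures need a richer annotation than this container
  carries.
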