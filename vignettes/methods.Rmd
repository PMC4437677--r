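---
title: "Annotation-informed GWAS enrichment: models, choices and limits"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Annotation-informed GWAS enrichment: models, choices and limits}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(gwasenrich)
```

## The statistical model

The pipeline operates entirely on GWAS summary statistics: per tag SNP a
signed z-score (or a two-tailed p-value, from which an unsigned z is
derived).  The working model is a two-group mixture per annotation
stratum: a SNP's z-score is standard normal with probability 1 − π₁
(null) and drawn from a symmetric non-null distribution with variance
1 + σ² with probability π₁.  Under this model

* `mean(z² − 1)` over a stratum estimates π₁σ², the variance in effect
  sizes attributable to non-null SNPs — the quantity reported per category
  by `enrichment_estimate()`;
* the empirical cdf of p within a stratum, F̂(p | C), exceeds the overall
  F̂(p) when the stratum is enriched, so the conservative estimates
  FDR(p) = p/F̂(p) and condFDR(p | C) = p/F̂(p | C) (π₀ fixed at 1) order
  SNPs so that enriched-stratum members reach significance earlier; and
* the stratified Q-Q curve's vertical deflection above the identity line
  equals −log10 of the stratum's empirical FDR, which is why Q-Q
  enrichment, condFDR gain and replication-rate separation are three views
  of the same phenomenon.

Annotation enters through LD: a tag SNP stands for its LD block, so
category affiliation is the *LD-weighted score* — the sum of r² (≥ 0.2,
within 1 Mb, self term included) with reference-panel SNPs positioned in
the category — rather than the tag SNP's own position.  Membership at
score ≥ 1 ("at least one fully linked category SNP") is deliberately not
exclusive across categories; only the *positional* assignment of panel
SNPs is exclusive, resolved by a fixed priority order (regulatory-RNA
categories first, then transcript anatomy from most to least specific,
then regulatory DNA elements).  The intergenic stratum is defined
negatively — all ten genic scores exactly zero and no LD partner within
100 kb of a protein-coding gene or inside an ncRNA/TFBS/miRNA-binding-site
interval — and doubles as the null reference for inflation control and the
baseline group of the enrichment test.

## Parameters that matter

| Parameter | Default | Units | Why |
|---|---|---|---|
| LD window | 1,000,000 | bp | LD beyond 1 Mb is rare and noisy in reference panels |
| r² threshold | 0.2 | — | below it r² estimates are dominated by sampling noise; values < 0.2 are treated as 0 everywhere (scores, TotLD, pruning) |
| membership threshold | 1.0 | score units | one fully linked category SNP equivalent |
| gene pad (intergenic rule) | 100,000 | bp | regulatory neighbourhood of protein-coding genes; applies to genes only, strict containment for ncRNA/TFBS/miRNA-BS |
| miRNA track extension | 10,000 | bp each way | captures the miRNAs' own regulatory regions; no other track is padded |
| λ_GC quantile | 0.5 | — | the median is robust to the polygenic tail; 0.95 available for phenotypes with degenerate medians |
| pruning replicas | 10 | — | variance of Q-Q curves and the proportion-test statistic across random LD-block representatives |
| top quantile (BPT) | 0.10 | — | "top decile", taken over the pooled pruned set so both groups face one cutoff (per-group available via `per_group = TRUE`) |
| FDR / condFDR threshold | 0.01 | — | locus discovery rule; compared against FDR < 0.01 and Bonferroni p < 5×10⁻⁸ |
| panel QC | MAF ≥ 0.01, SNP missingness ≤ 0.05, HWE p ≥ 10⁻⁶, individual missingness ≤ 0.10 | — | standard reference-panel QC; individuals filtered before SNPs |

## Numerical and procedural choices

* **r² definition.**  Squared Pearson correlation of unphased allele
  counts (composite LD), pairwise-complete over missing genotypes; fewer
  than two complete pairs or zero variance give r² = 0.  Haplotype-based
  estimators are out of scope.
* **HWE test.**  The classical 1-df chi-square against expected genotype
  frequencies at the observed allele frequency; monomorphic SNPs return
  p = 1.  The exact test would differ only at very small counts, below the
  panel sizes QC is meant for.
* **LD pruning.**  A greedy pass over a seeded random ordering retains a
  SNP iff it has r² ≤ 0.2 with every already-retained SNP within 1 Mb — a
  random maximal independent set of the LD graph.  Replicas differ only
  through the ordering.  For locus counting the ordering is by the
  significance value (smaller condFDR first, ties by position) instead of
  random, so the most significant SNP represents each locus.
* **Q-Q construction.**  1,000 equally spaced nominal −log10 p points from
  0 to the observed maximum; at nominal x the curve value is −log10 of the
  ⌈10⁻ˣ·n⌉-th smallest p in the stratum-by-replica set.  The band is mean
  ± 1.96 sd across replicas.  Strata with fewer than 10 pruned SNPs are
  suppressed.
* **Proportion test.**  Pooled-variance two-sample z per replica; the
  final statistic is the replica median and the p-value its one-sided
  upper tail — enrichment, not depletion, is the hypothesis.  A degenerate
  pooled proportion (0 or 1) yields statistic 0, p 0.5.
* **FDR monotonisation.**  The raw p/F̂ estimator is not monotone in p;
  a cumulative maximum in p order is applied (per stratum for condFDR) so
  that thresholding defines nested discovery sets.  Ties in p share the
  largest empirical cdf value (ties.method = "max"), which is
  conservative.  z = 0 in the regression is floored at z² = 10⁻¹² before
  the log.
* **Replication p-value orientation.**  p_R = 1 − Φ(sgn(Z_D)·Z_R), small
  for strong sign-consistent replication, so "replicates at p < 0.05"
  selects what it should; the complementary orientation is available via
  `printed_formula = TRUE`.  Z_D = 0 has no direction and returns 0.5.
  Group z-combination is mean × √(group size): with four sub-studies the
  multiplier is √4 = 2, keeping combined null scores standard normal.
* **Replication binning.**  Bins are lower bounds; per split, the rate is
  the replicating fraction among SNPs *above* the bound; bins with no SNPs
  in a split are skipped in that split's average.  Within one analysis all
  strata share a single grid spanning the global discovery range so curves
  are comparable bin by bin; the bin-0 value is then exactly the stratum's
  overall replication rate.
* **Unsigned input.**  When only p-values are supplied the derived z
  carries no sign; the replication analysis requires signed z-scores and
  such input cannot be used there.  SNPs absent from the reference panel
  are excluded from scoring with a logged count.

## What the generator emulates — and what it does not

`simulate_panel()` builds blocks of SNPs sharing a pair of latent alleles:
each observed allele copies the latent one with probability t^¼ (t the
target within-block r²), giving expected pairwise dosage r² = t inside a
block and 0 between.  Blocks are narrower than 1 Mb and separated by 2 Mb,
so all LD is within-block and the intergenic proximity rule is decidable
by geometry.  Tracks cover whole blocks (at most one genic category per
block; transcript-anatomy blocks also get a protein-coding-gene interval);
z-scores follow the mixture above with category-dependent π₁, a global
inflation multiplier √λ, and sub-studies share the non-null effect through
a latent per-SNP component with variance σ²·c/K (c the effect-sharing
fraction), so the combined all-K z-score reproduces the single-study
mixture variance.

Default scale is a desk-sized study: 500 individuals, 200 blocks × 25
SNPs, within-block r² 0.6, eight sub-studies, effect sharing 1.  The
default non-null fraction is π₁ = 0.2 with σ² = 9 for the miRNA category
and 0 elsewhere: a strongly enriched focal category over a null
background.  That choice makes the default simulation reproduce the
qualitative regime the method is designed for — clearly separated
replication-rate curves and a visible condFDR gain; at π₁ an order of
magnitude smaller the miRNA and intergenic strata are statistically
indistinguishable near the origin at this scale, which exercises nothing.
Tests that need other regimes (null calibration, the π₁ = 0.05 vs 0.01
condFDR gain) set their own mixture explicitly.

What the generator deliberately does **not** model: realistic MAF spectra
(block frequencies are uniform in 0.1–0.5), coalescent LD decay (LD is
block-constant), phenotype-level association noise (effects are placed
directly on z-scores, the level at which the pipeline's assumptions are
stated), cross-category overlap of annotations (each block carries one
category), population stratification beyond a scalar λ, and signal leakage
from a causal SNP into its LD neighbours' summary statistics.  Passing
tests therefore certify the statistical machinery under its stated
assumptions — not robustness to the many ways real GWAS data violate
them, e.g. annotation-correlated LD structure or widespread weak
polygenicity, where the intergenic stratum itself is partly non-null and
λ_GC absorbs true signal.

## Problem sizes used by the test suite

The suite runs the panel-based checks at 50–5,000 SNPs and the
distributional checks at 10⁴–10⁵ draws; calibration and conservativeness
statements average 100–1,000 repetitions.  These sizes give Monte-Carlo
standard errors comfortably inside the asserted tolerances while keeping
the whole suite in the tens of seconds.

## Known limitations

* condFDR here conditions on *binary* stratum membership; conditioning on
  the continuous score, local fdr, or two-phenotype pleiotropy
  conditioning are out of scope.
* π₀ = 1 makes all rates conservative; no π₀ estimation is attempted.
* Locus definition is pure r²-pruning; no distance-based merging of
  significant SNPs into regions.
* Intervals are strandless; no transcript-isoform resolution.
* The annotation regression is plain OLS on log z² with one-sided
  normal-theory p-values; robust or weighted variants are not provided.
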