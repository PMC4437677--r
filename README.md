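# gwasenrich

Annotation-informed enrichment analysis and conditional false discovery rate
(condFDR) discovery for GWAS summary statistics.

## The problem

Standard single-SNP GWAS analysis leaves most of the polygenic signal in
summary statistics untouched: thousands of SNPs carry effects too small to
clear the genome-wide threshold, and they are not spread uniformly over the
genome.  Functional categories — 5'UTRs, exons, and regulatory-RNA regions
such as microRNA (miRNA) transcripts and miRNA binding sites — can be
*enriched* of true associations relative to intergenic baseline SNPs.  This
package implements, as a tested and reusable pipeline, the statistical
machinery needed to measure that enrichment from summary statistics plus a
reference genotype panel, and to convert it into extra discoveries:

1. **LD-weighted annotation scoring.**  For tag SNP *i* and category *C*,

   `score(i, C) = Σ_j δ_j(C) · r²_ij`

   summing squared-correlation LD (r² ≥ 0.2, within 1 Mb, self term 1) with
   all reference-panel SNPs positioned in *C*; a tag SNP is an LD member of
   *C* when the score is ≥ 1.  The total LD `TotLD_i = Σ_j r²_ij` is kept as
   a covariate.
2. **Intergenic inflation control.**  λ_GC is the median squared z-score of
   intergenic SNPs (those with all genic scores 0 and no LD partner near a
   gene, ncRNA, TFBS or miRNA binding site) over the χ²(1) median; z-scores
   are divided by √λ_GC.
3. **Stratified Q-Q curves** per category with 95% bands across ten random
   LD-pruning replicas, and a **binomial proportion test**: per replica the
   proportions of category vs intergenic SNPs in the pooled top decile of
   −log10 p are compared by a pooled two-proportion z; the reported p-value
   is the upper tail of the median statistic.
4. **Enrichment quantification** via `mean(z² − 1)` per category (under a
   null/non-null mixture this estimates the non-null effect-size variance
   π₁σ²), normalised by the per-phenotype maximum, plus an OLS regression of
   `log z²` on the category scores, the intergenic flag and TotLD to control
   for cross-category correlation.
5. **FDR and condFDR.**  With π₀ fixed at 1, `FDR(p) = p / F̂(p)` from the
   empirical cdf; `condFDR(p | C) = p / F̂(p | C)` from the within-stratum
   cdf; both monotonised.  Significant loci at condFDR < 0.01 are counted
   after greedy LD pruning (r² ≤ 0.2), alongside FDR < 0.01 and Bonferroni
   p < 5×10⁻⁸ counts.
6. **Replication analysis.**  Eight sub-studies are split into discovery /
   replication halves in all 70 ways; group z-scores are mean × √(group
   size); cumulative replication-rate curves (fraction with replication
   p < 0.05 above each discovery −log10 p bound, averaged over splits) are
   compared with the stratified true discovery rate TDR = 1 − FDR.

A block-LD synthetic data generator (`sim_config()`, `simulate_panel()`,
`simulate_tracks()`, `simulate_summary_stats()`, `simulate_substudies()`)
produces all pipeline inputs with known truth, so every stage is testable
without external genotype or annotation resources.

## Worked example

```r
library(gwasenrich)

cfg    <- sim_config(n_individuals = 300, n_blocks = 60, seed = 11)
panel  <- simulate_panel(cfg)
tracks <- simulate_tracks(cfg, panel)
ss     <- simulate_summary_stats(cfg, panel, tracks)

fit <- gwas_enrichment(ss, panel, tracks, seed = 1)
fit
#> Annotation-informed GWAS enrichment analysis
#>   1500 tag SNPs (700 intergenic), lambda_GC = 0.9215
#>   Most enriched categories (binomial proportion test vs intergenic):
#>     miRNA      z =   0.98  p = 0.164  mean(z^2-1) = 2.216
#>     miRNA_BS   z =  -0.39  p = 0.652  mean(z^2-1) = -0.194
#>     ncRNA      z =  -0.39  p = 0.652  mean(z^2-1) = 0.001

fit$loci$miRNA$counts
#>    condfdr        fdr bonferroni
#>          4          3          3
```

The fitted object reports: 1,500 tag SNPs of which 700 form the likely-null
intergenic stratum; a genomic inflation factor of 0.92 estimated from them
(divided out of all z-scores); the binomial-proportion z and the raw
`mean(z² − 1)` enrichment per category — here the simulated miRNA
enrichment (non-null fraction 0.2, extra variance 9) tops the table, though
at this desk scale the pruned-SNP counts are far too small for the
proportion test to reach significance; and the LD-pruned locus counts for
the miRNA stratum, where conditioning on miRNA membership (condFDR < 0.01)
finds 4 loci against 3 for the unconditional FDR at the same threshold.
`summary(fit)`, `coef(fit)` (regression coefficients) and `plot(fit)`
(stratified Q-Q curves) expose the rest.

The same pipeline is available from a shell via `inst/scripts/gwasenrich`
with subcommands `simulate`, `annotate`, `enrich`, `condfdr`, `replicate`
(TSV stage files; `--seed` makes every stage byte-reproducible).

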