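Package: gwasenrich
Title: Annotation-Informed Enrichment and Conditional FDR for GWAS Summary Statistics
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Stratified enrichment analysis of genome-wide association study
    (GWAS) summary statistics using linkage-disequilibrium (LD) weighted
    genomic annotation scores. Provides intergenic genomic-control inflation
    estimation, stratified quantile-quantile curves with confidence bands from
    LD-pruning replicas, a binomial proportion enrichment test, mean(z^2 - 1)
    enrichment estimates, an annotation regression, conditional false
    discovery rate (condFDR) locus discovery, and sub-study discovery/
    replication analysis. Includes a block-LD synthetic data generator so the
    whole pipeline can be exercised without external genotype or annotation
    resources, and a command-line interface over the pipeline stages.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    graphics,
    grDevices,
    yaml,
    IRanges
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
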