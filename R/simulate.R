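#' Simulation configuration
#'
#' Study-condition defaults for the synthetic pipeline inputs: a desk-scale
#' reference panel of 500 individuals and 200 LD blocks of 25 SNPs (blocks
#' narrower than 1 Mb, separated by more than 1 Mb so LD is strictly
#' within-block), annotation tracks placed over whole blocks, a null /
#' non-null mixture on z-scores whose non-null weight depends on annotation
#' category, and eight sub-studies sharing non-null effects.
#'
#' @param n_individuals Panel individuals.
#' @param n_blocks Number of LD blocks.
#' @param snps_per_block SNPs per block.
#' @param within_block_r2 Target mean pairwise r-squared within a block.
#' @param snp_spacing Base pairs between adjacent SNPs in a block.
#' @param block_gap Base pairs between block starts (> 1 Mb + block width).
#' @param placement_rates Named per-category probability that a block is
#'   assigned that category (remainder left unannotated / intergenic).
#' @param pi1 Named per-category non-null fraction (categories absent from
#'   the name set, and unannotated blocks, get \code{pi1_default}).
#' @param pi1_default Non-null fraction outside the named categories.
#' @param sigma2_extra Extra variance of the non-null z component.
#' @param lambda_true Simulated genomic inflation (>= 1).
#' @param K Number of sub-studies.
#' @param effect_sharing Fraction in \[0, 1\] of non-null effect variance
#'   shared across sub-studies (1 = a common latent effect).
#' @param seed Integer seed.
#' @return List of class \code{sim_config}.
#' @export
sim_config <- function(n_individuals = 500, n_blocks = 200,
                       snps_per_block = 25, within_block_r2 = 0.6,
                       snp_spacing = 1000, block_gap = 2e6,
                       placement_rates = c(miRNA = 0.05, miRNA_BS = 0.05,
                                           UTR5 = 0.05, UTR3 = 0.05,
                                           exon = 0.08, intron = 0.15,
                                           enhancer = 0.05, silencer = 0.02,
                                           TFBS = 0.05, ncRNA = 0.05),
                       pi1 = c(miRNA = 0.2), pi1_default = 0,
                       sigma2_extra = 9, lambda_true = 1,
                       K = 8, effect_sharing = 1, seed = 42) {
  cfg <- list(n_individuals = n_individuals, n_blocks = n_blocks,
              snps_per_block = snps_per_block,
              within_block_r2 = within_block_r2, snp_spacing = snp_spacing,
              block_gap = block_gap, placement_rates = placement_rates,
              pi1 = pi1, pi1_default = pi1_default,
              sigma2_extra = sigma2_extra, lambda_true = lambda_true,
              K = K, effect_sharing = effect_sharing, seed = seed)
  stopifnot(within_block_r2 >= 0, within_block_r2 <= 1,
            all(placement_rates >= 0), sum(placement_rates) <= 1,
            all(pi1 >= 0 & pi1 <= 1), pi1_default >= 0, pi1_default <= 1,
            sigma2_extra >= 0, lambda_true >= 1,
            effect_sharing >= 0, effect_sharing <= 1, K >= 2,
              block_gap > snps_per_block * snp_spacing + 1e6)
  class(cfg) <- "sim_config"
  cfg
}

#' Simulate a block-LD genotype panel
#'
#' Within a block every SNP shares a pair of latent alleles: each observed
#' allele copies the latent allele with probability
#' \code{within_block_r2^(1/4)} and is otherwise drawn fresh at the block
#' allele frequency, giving expected pairwise dosage r-squared equal to the
#' target within blocks and 0 between.  Block allele frequencies are drawn
#' uniformly in (0.1, 0.5) so QC passes.
#'
#' @param config A [sim_config()].
#' @param seed Seed (defaults to \code{config$seed}).
#' @return A [genotype_panel()] with an integer attribute \code{block}
#'   (block index per SNP).
#' @export
simulate_panel <- function(config, seed = config$seed) {
  set.seed(seed)
  n <- config$n_individuals; m <- config$snps_per_block
  s <- config$within_block_r2^(1 / 4)
  counts <- matrix(0L, n, config$n_blocks * m)
  pos <- integer(config$n_blocks * m)
  for (b in seq_len(config$n_blocks)) {
    f <- stats::runif(1, 0.1, 0.5)
    A1 <- stats::rbinom(n, 1, f); A2 <- stats::rbinom(n, 1, f)
    copy1 <- matrix(stats::runif(n * m) < s, n, m)
    copy2 <- matrix(stats::runif(n * m) < s, n, m)
    fresh1 <- matrix(stats::rbinom(n * m, 1, f), n, m)
    fresh2 <- matrix(stats::rbinom(n * m, 1, f), n, m)
    g <- (copy1 * A1 + (1 - copy1) * fresh1) +
      (copy2 * A2 + (1 - copy2) * fresh2)
    cols <- (b - 1) * m + seq_len(m)
    counts[, cols] <- g
    pos[cols] <- (b - 1) * config$block_gap + seq_len(m) * config$snp_spacing
  }
  map <- data.frame(id = sprintf("snp%05d", seq_len(ncol(counts))),
                    chrom = "1", pos = pos, stringsAsFactors = FALSE)
  panel <- genotype_panel(map, counts)
  attr(panel, "block") <- rep(seq_len(config$n_blocks), each = m)
  panel
}

#' Simulate annotation interval tracks
#'
#' Each block is assigned at most one genic category at the configured
#' placement rates (the remainder stays unannotated); an assigned block gets
#' one interval spanning all its SNPs.  Blocks carrying transcript-anatomy
#' categories (UTRs, exon, intron) additionally get a protein-coding gene
#' interval over the same span, so the intergenic proximity rule has genes
#' to measure against.  Unannotated blocks lie more than 1 Mb + 100 kb from
#' every interval by construction, guaranteeing a non-empty intergenic set.
#'
#' @param config A [sim_config()].
#' @param panel Panel from [simulate_panel()] (needs the \code{block}
#'   attribute).
#' @param seed Seed (defaults to \code{config$seed + 1}).
#' @return Named list of [interval_track()]s over [TRACK_CATEGORIES] with a
#'   character attribute \code{block_category} ("none" for unannotated
#'   blocks).
#' @export
simulate_tracks <- function(config, panel, seed = config$seed + 1) {
  set.seed(seed)
  block <- attr(panel, "block")
  stopifnot(!is.null(block))
  rates <- config$placement_rates[intersect(names(config$placement_rates),
                                            GENIC_CATEGORIES)]
  block_cat <- sample(c(names(rates), "none"), config$n_blocks, replace = TRUE,
                      prob = c(rates, 1 - sum(rates)))
  tracks <- list()
  spans <- vapply(seq_len(config$n_blocks), function(b) {
    range(panel$map$pos[block == b])
  }, numeric(2))
  for (cg in TRACK_CATEGORIES) {
    if (cg == "protein_coding_gene")
      bs <- which(block_cat %in% c("UTR5", "UTR3", "exon", "intron"))
    else bs <- which(block_cat == cg)
    if (length(bs))
      tracks[[cg]] <- interval_track(chrom = "1",
                                     start = spans[1, bs] - 1,  # 0-based
                                     end = spans[2, bs],
                                     category = cg)
    else
      tracks[[cg]] <- interval_track(chrom = character(0), start = numeric(0),
                                     end = numeric(0), category = cg)
  }
  attr(tracks, "block_category") <- block_cat
  tracks
}

#' Simulate GWAS summary statistics from an annotation-dependent mixture
#'
#' Each tag SNP's z-score is drawn from N(0, 1 + sigma2_extra) with
#' probability pi1(category of its block) and from N(0, 1) otherwise; all
#' z-scores are then multiplied by sqrt(lambda_true) to emulate genomic
#' inflation.  Non-null status is recorded in a truth table attribute for
#' downstream evaluation.
#'
#' @param config A [sim_config()].
#' @param panel Panel from [simulate_panel()].
#' @param tracks Tracks from [simulate_tracks()] (for the block categories).
#' @param seed Seed (defaults to \code{config$seed + 2}).
#' @return A \code{summary_stats} table (tag SNPs = panel SNPs) with
#'   attribute \code{truth}: data.frame(snp_id, is_non_null, category).
#' @export
simulate_summary_stats <- function(config, panel, tracks,
                                   seed = config$seed + 2) {
  set.seed(seed)
  block <- attr(panel, "block")
  block_cat <- attr(tracks, "block_category")
  snp_cat <- block_cat[block]
  pi1 <- ifelse(snp_cat %in% names(config$pi1), config$pi1[snp_cat],
                config$pi1_default)
  non_null <- stats::runif(length(pi1)) < pi1
  sd_z <- sqrt(ifelse(non_null, 1 + config$sigma2_extra, 1))
  z <- stats::rnorm(length(pi1), 0, sd_z) * sqrt(config$lambda_true)
  ss <- summary_stats(panel$map$id, panel$map$chrom, panel$map$pos, z)
  attr(ss, "truth") <- data.frame(snp_id = panel$map$id,
                                  is_non_null = non_null,
                                  category = snp_cat,
                                  stringsAsFactors = FALSE)
  ss
}

#' Simulate correlated sub-study z-scores
#'
#' Sub-study z-scores share a latent per-SNP effect at non-null SNPs:
#' z_k = delta_shared + delta_k + noise, with Var(delta_shared) =
#' effect_sharing * sigma2_extra / K and Var(delta_k) = (1 - effect_sharing)
#' * sigma2_extra / K, so the combined all-K z-score has the same marginal
#' variance 1 + sigma2_extra as the single-study mixture.  Null SNPs are
#' independent standard normal.
#'
#' @param config A [sim_config()].
#' @param truth Truth table from [simulate_summary_stats()] (attribute
#'   \code{truth}).
#' @param seed Seed (defaults to \code{config$seed + 3}).
#' @return SNPs x K matrix of signed z-scores (rownames = SNP ids).
#' @export
simulate_substudies <- function(config, truth, seed = config$seed + 3) {
  set.seed(seed)
  n <- nrow(truth); K <- config$K
  v_shared <- config$effect_sharing * config$sigma2_extra / K
  v_indep <- (1 - config$effect_sharing) * config$sigma2_extra / K
  delta_shared <- stats::rnorm(n, 0, sqrt(v_shared)) * truth$is_non_null
  z <- matrix(stats::rnorm(n * K), n, K, dimnames = list(truth$snp_id, NULL))
  if (v_indep > 0)
    z <- z + matrix(stats::rnorm(n * K, 0, sqrt(v_indep)), n, K) *
      truth$is_non_null
  z <- z + delta_shared
  z * sqrt(config$lambda_true)
}
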