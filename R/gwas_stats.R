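#' Intergenic genomic inflation factor
#'
#' lambda_GC is the chosen quantile (default the median) of squared z-scores
#' over intergenic SNPs divided by the matching quantile of the chi-square
#' distribution with one degree of freedom.  Intergenic SNPs are used
#' because their depletion of true associations makes them a robust estimate
#' of the null, uncontaminated by polygenic signal (a 0.95 quantile is
#' useful for phenotypes whose intergenic median is degenerate, as with very
#' sparse summary statistics).
#'
#' @param z Numeric z-score vector, named by SNP id if \code{intergenic_ids}
#'   is given.
#' @param intergenic_ids Optional ids of the intergenic stratum; default uses
#'   all of \code{z}.
#' @param quantile Quantile in (0, 1) at which to match chi-square(1).
#' @return The scalar inflation factor lambda_GC.
#' @export
estimate_lambda_gc <- function(z, intergenic_ids = NULL, quantile = 0.5) {
  stopifnot(quantile > 0, quantile < 1)
  if (!is.null(intergenic_ids)) z <- z[as.character(intergenic_ids)]
  z <- z[!is.na(z)]
  if (!length(z)) stop("no intergenic SNPs available for inflation control")
  if (length(z) < 100)
    warning("lambda_GC estimated from only ", length(z), " intergenic SNPs")
  as.numeric(stats::quantile(z^2, quantile, names = FALSE) /
               stats::qchisq(quantile, df = 1))
}

#' Apply genomic inflation control
#'
#' Divides z-scores by sqrt(lambda_GC) (equivalently z-squared by lambda_GC)
#' and recomputes two-tailed p-values.  Sign and rank order of |z| are
#' preserved.
#'
#' @param z Numeric (optionally named) z-score vector.
#' @param lambda_gc Positive inflation factor.
#' @return Data frame with columns \code{z_raw}, \code{z_adj}, \code{p_adj}.
#' @export
apply_inflation_control <- function(z, lambda_gc) {
  stopifnot(lambda_gc > 0)
  z_adj <- z / sqrt(lambda_gc)
  data.frame(z_raw = z, z_adj = z_adj, p_adj = 2 * stats::pnorm(-abs(z_adj)),
             row.names = names(z), stringsAsFactors = FALSE)
}

# empirical -log10 p quantile curve of a p-value vector on a nominal
# -log10(p) grid: at nominal x the expected upper-tail fraction is 10^-x and
# the curve value is -log10 of the matching order statistic
qq_empirical_curve <- function(p, grid) {
  p <- sort(p)
  n <- length(p)
  k <- pmax(1L, ceiling(10^(-grid) * n))
  -log10(p[k])
}

#' Stratified Q-Q curves with pruning-replica confidence bands
#'
#' For each stratum and each LD-pruning replica, computes the empirical
#' -log10(p) quantile function on a common grid of nominal -log10(p) values,
#' then the mean and a 95\% band (mean +/- 1.96 sd) across replicas.
#' Enrichment of a stratum appears as deflection of its curve above the
#' identity line; the vertical gap equals -log10 of the stratum's empirical
#' FDR at that point.
#'
#' @param p Named vector of (inflation-adjusted) p-values.
#' @param strata Named list of SNP-id sets (categories, intergenic, all).
#' @param prune_replicas List of pruned id sets from [ld_prune_replicas()].
#' @param n_bins Number of nominal grid points.
#' @return Object of class \code{qq_curves}: \code{grid} (nominal
#'   -log10 p) and per-stratum data frames (nominal, mean, lower, upper);
#'   strata with fewer than 10 pruned SNPs in some replica are suppressed
#'   with a warning.
#' @export
stratified_qq <- function(p, strata, prune_replicas, n_bins = 1000) {
  pruned_p <- unlist(lapply(prune_replicas, function(ids) p[ids]),
                     use.names = FALSE)
  grid <- seq(0, max(-log10(pruned_p)), length.out = n_bins)
  curves <- list()
  for (st in names(strata)) {
    mats <- lapply(prune_replicas, function(ids) {
      keep <- intersect(ids, strata[[st]])
      if (length(keep) < 10) return(NULL)
      qq_empirical_curve(p[keep], grid)
    })
    if (any(vapply(mats, is.null, logical(1)))) {
      warning("stratum '", st, "' has fewer than 10 pruned SNPs; curve suppressed")
      next
    }
    m <- do.call(cbind, mats)
    mu <- rowMeans(m)
    sdv <- apply(m, 1, stats::sd)
    curves[[st]] <- data.frame(nominal = grid, mean = mu,
                               lower = mu - 1.96 * sdv,
                               upper = mu + 1.96 * sdv)
  }
  structure(list(grid = grid, curves = curves, n_replicas = length(prune_replicas)),
            class = "qq_curves")
}

#' Two-sample proportion z-statistic with pooled variance
#'
#' @param x1,n1 Successes and size in group 1.
#' @param x2,n2 Successes and size in group 2.
#' @return The z-statistic; 0 when the pooled proportion is degenerate
#'   (0 or 1).
#' @export
two_proportion_z <- function(x1, n1, x2, n2) {
  pp <- (x1 + x2) / (n1 + n2)
  if (pp <= 0 || pp >= 1) return(0)
  (x1 / n1 - x2 / n2) / sqrt(pp * (1 - pp) * (1 / n1 + 1 / n2))
}

#' Binomial proportion enrichment test
#'
#' Per pruning replica, the cutoff is the (1 - top_quantile) quantile of
#' -log10(p) over all pruned SNPs (the pooled "top decile" at the default);
#' the proportion of category SNPs above the cutoff is compared with the
#' proportion of intergenic SNPs above it by the two-sample proportion
#' z-statistic with pooled variance.  The reported statistic is the median
#' over replicas and the p-value is the one-sided upper-tail normal
#' probability of that median (enrichment, not depletion, being the
#' hypothesis).
#'
#' @param category_ids,intergenic_ids SNP-id sets for the two groups.
#' @param p Named vector of (adjusted) p-values.
#' @param prune_replicas List of pruned id sets.
#' @param top_quantile Upper tail fraction defining the cutoff (0.10 = top
#'   decile).
#' @param per_group If TRUE, the cutoff is taken within each group's own
#'   -log10(p) distribution instead of the pooled one.
#' @return List with \code{statistic} (median z), \code{p.value}, and
#'   \code{replica_z}.
#' @export
binomial_proportion_test <- function(category_ids, intergenic_ids, p,
                                     prune_replicas, top_quantile = 0.10,
                                     per_group = FALSE) {
  zs <- vapply(prune_replicas, function(ids) {
    g1 <- intersect(ids, category_ids)
    g2 <- intersect(ids, intergenic_ids)
    if (length(g1) < 2 || length(g2) < 2)
      stop("fewer than 2 pruned SNPs in a group")
    l1 <- -log10(p[g1]); l2 <- -log10(p[g2])
    if (per_group) {
      x1 <- sum(l1 > stats::quantile(l1, 1 - top_quantile, names = FALSE))
      x2 <- sum(l2 > stats::quantile(l2, 1 - top_quantile, names = FALSE))
    } else {
      cutoff <- stats::quantile(-log10(p[ids]), 1 - top_quantile, names = FALSE)
      x1 <- sum(l1 > cutoff)
      x2 <- sum(l2 > cutoff)
    }
    two_proportion_z(x1, length(l1), x2, length(l2))
  }, numeric(1))
  med <- stats::median(zs)
  list(statistic = med,
       p.value = stats::pnorm(med, lower.tail = FALSE),
       replica_z = zs)
}

#' Categorical enrichment estimate mean(z^2 - 1)
#'
#' Under a mixture of a standard normal null and a symmetric non-null
#' component, the sample mean of z-squared over a category estimates the
#' total variance; subtracting one leaves a conservative estimate of the
#' variance in effect sizes attributable to non-null SNPs (pi1 *
#' sigma2_extra for the variance-inflation mixture).
#'
#' @param z Named vector of (adjusted) z-scores.
#' @param ids Optional SNP ids of the category; default all.
#' @return Scalar estimate, or NA for an empty category.
#' @export
enrichment_estimate <- function(z, ids = NULL) {
  if (!is.null(ids)) z <- z[as.character(ids)]
  z <- z[!is.na(z)]
  if (!length(z)) return(NA_real_)
  mean(z^2) - 1
}

#' Normalise enrichment estimates by the per-phenotype maximum
#'
#' @param estimates Named numeric vector of per-category estimates.
#' @return The estimates divided by their maximum (skipped with a warning if
#'   the maximum is not positive).
#' @export
normalize_estimates <- function(estimates) {
  m <- max(estimates, na.rm = TRUE)
  if (!is.finite(m) || m <= 0) {
    warning("maximum enrichment estimate is not positive; normalisation skipped")
    return(estimates)
  }
  estimates / m
}

#' Regression of log z-squared on annotation scores
#'
#' Ordinary least squares of log(z_adj^2) on the LD-weighted scores of the
#' most relevant genic categories (miRNA, miRNA-BS, 3'UTR, 5'UTR, exon,
#' intron), the intergenic flag and total LD.  Total LD accounts for the
#' very different LD-block sizes different categories encompass; the
#' direction of effect is discarded (squared z), so the test of interest is
#' one-sided for positive coefficients.  Collinear columns are dropped with
#' a warning; z = 0 is floored at \code{eps} before the log.
#'
#' @param z_adj Numeric vector of adjusted z-scores (one per row of
#'   \code{scores}).
#' @param scores Annotated table from [annotate_tags()].
#' @param eps Floor for z-squared before taking the log.
#' @return Data frame: term, estimate, se, t, p_one_sided.
#' @export
annotation_regression <- function(z_adj, scores, eps = 1e-12) {
  stopifnot(length(z_adj) == nrow(scores))
  design <- data.frame(scores[, c("miRNA", "miRNA_BS", "UTR3", "UTR5",
                                  "exon", "intron")],
                       intergenic = as.numeric(scores$intergenic),
                       total_ld = scores$total_ld)
  y <- log(pmax(z_adj^2, eps))
  fit <- stats::lm(y ~ ., data = design)
  cf <- coef(fit)
  if (anyNA(cf)) {
    warning("collinear design column(s) dropped: ",
            paste(names(cf)[is.na(cf)], collapse = ", "))
  }
  sm <- summary(fit)$coefficients
  data.frame(term = rownames(sm), estimate = sm[, 1], se = sm[, 2],
             t = sm[, 3],
             p_one_sided = stats::pt(sm[, 3], df = fit$df.residual,
                                     lower.tail = FALSE),
             row.names = NULL, stringsAsFactors = FALSE)
}
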