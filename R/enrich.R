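#' Annotation-informed GWAS enrichment analysis
#'
#' The package's main entry point: runs the full enrichment pipeline on a
#' summary-statistics table, a reference genotype panel and a set of
#' annotation interval tracks, and returns a single fitted object.
#'
#' Stages: (1) panel quality control and windowed LD computation; (2)
#' LD-weighted annotation scoring, category membership and intergenic
#' identification; (3) intergenic genomic-control inflation estimation and
#' z-score adjustment; (4) LD-pruning replicas, stratified Q-Q curves and
#' the binomial proportion enrichment test per category against the
#' intergenic stratum; (5) mean(z^2 - 1) enrichment estimates with
#' per-phenotype normalisation and the annotation regression; (6) FDR /
#' condFDR estimation and LD-pruned locus counting per stratum.
#'
#' @param sumstats A \code{summary_stats} table (see
#'   [read_summary_stats()]).
#' @param panel A [genotype_panel()] (raw; QC is applied here unless
#'   \code{qc = FALSE}).
#' @param tracks Named list of [interval_track()]s (miRNA track unextended;
#'   the 10 kb extension is applied internally).
#' @param qc Apply [qc_filter()] to the panel.
#' @param window,r2_min LD window (bp) and r-squared threshold.
#' @param score_threshold LD membership threshold on annotation scores.
#' @param gene_pad Protein-coding gene proximity pad (bp) for the intergenic
#'   rule.
#' @param lambda_quantile Quantile for [estimate_lambda_gc()].
#' @param n_replicas Number of LD-pruning replicas.
#' @param top_quantile Upper-tail fraction for the binomial proportion
#'   test.
#' @param fdr_threshold condFDR / FDR locus significance threshold.
#' @param n_bins Q-Q grid size.
#' @param seed Seed for the pruning replicas.
#' @return An object of class \code{gwas_enrichment}; see
#'   \code{\link{print.gwas_enrichment}}, \code{summary}, \code{coef} and
#'   \code{plot} methods.
#' @export
gwas_enrichment <- function(sumstats, panel, tracks, qc = TRUE,
                            window = 1e6, r2_min = 0.2,
                            score_threshold = 1.0, gene_pad = 1e5,
                            lambda_quantile = 0.5, n_replicas = 10,
                            top_quantile = 0.10, fdr_threshold = 0.01,
                            n_bins = 1000, seed = 1) {
  cl <- match.call()
  if (qc) panel <- qc_filter(panel)
  neighbors <- build_ld_neighbors(panel, window = window, r2_min = r2_min)
  scores <- annotate_tags(sumstats, panel, tracks, neighbors,
                          score_threshold = score_threshold,
                          gene_pad = gene_pad)
  stats_used <- sumstats[match(scores$snp_id, sumstats$snp_id), , drop = FALSE]
  z <- stats::setNames(stats_used$z, stats_used$snp_id)
  strata <- annotation_strata(scores)

  lambda_gc <- estimate_lambda_gc(z, strata$intergenic,
                                  quantile = lambda_quantile)
  adj <- apply_inflation_control(z, lambda_gc)
  p_adj <- stats::setNames(adj$p_adj, names(z))
  z_adj <- stats::setNames(adj$z_adj, names(z))

  replicas <- ld_prune_replicas(scores$snp_id, neighbors,
                                n_replicas = n_replicas, seed = seed,
                                r2_max = r2_min)
  qq <- stratified_qq(p_adj, strata, replicas, n_bins = n_bins)

  enr <- data.frame(category = GENIC_CATEGORIES, n_members = NA_integer_,
                    bpt_z = NA_real_, bpt_p = NA_real_,
                    mean_z2_minus_1 = NA_real_, stringsAsFactors = FALSE)
  for (k in seq_along(GENIC_CATEGORIES)) {
    cg <- GENIC_CATEGORIES[k]
    enr$n_members[k] <- length(strata[[cg]])
    enr$mean_z2_minus_1[k] <- if (length(strata[[cg]]))
      enrichment_estimate(z_adj, strata[[cg]]) else NA_real_
    ok <- all(vapply(replicas, function(r)
      length(intersect(r, strata[[cg]])) >= 2, logical(1)))
    if (ok && length(strata$intergenic)) {
      bpt <- binomial_proportion_test(strata[[cg]], strata$intergenic, p_adj,
                                      replicas, top_quantile = top_quantile)
      enr$bpt_z[k] <- bpt$statistic
      enr$bpt_p[k] <- bpt$p.value
    }
  }
  enr$normalized <- as.numeric(normalize_estimates(enr$mean_z2_minus_1))

  regression <- annotation_regression(adj$z_adj, scores)

  fdr_strata <- strata[c(GENIC_CATEGORIES, "intergenic")]
  fdr_strata <- fdr_strata[lengths(fdr_strata) > 0]
  ftab <- fdr_table(p_adj, fdr_strata)
  ftab <- cbind(ftab[, "snp_id", drop = FALSE],
                chrom = scores$chrom, pos = scores$pos,
                ftab[, -1, drop = FALSE])
  loci <- lapply(names(fdr_strata), function(st)
    significant_loci(ftab, st, neighbors, threshold = fdr_threshold,
                     prune_r2 = r2_min))
  names(loci) <- names(fdr_strata)

  structure(list(call = cl, lambda_gc = lambda_gc, panel = panel,
                 neighbors = neighbors, scores = scores, strata = strata,
                 stats = cbind(stats_used, z_adj = adj$z_adj,
                               p_adj = adj$p_adj),
                 replicas = replicas, qq = qq, enrichment = enr,
                 regression = regression, fdr = ftab, loci = loci,
                 params = list(window = window, r2_min = r2_min,
                               score_threshold = score_threshold,
                               gene_pad = gene_pad,
                               lambda_quantile = lambda_quantile,
                               n_replicas = n_replicas,
                               top_quantile = top_quantile,
                               fdr_threshold = fdr_threshold,
                               n_bins = n_bins, seed = seed)),
            class = "gwas_enrichment")
}

#' @export
print.gwas_enrichment <- function(x, ...) {
  cat("Annotation-informed GWAS enrichment analysis\n")
  cat(sprintf("  %d tag SNPs (%d intergenic), lambda_GC = %.4f\n",
              nrow(x$stats), length(x$strata$intergenic), x$lambda_gc))
  top <- x$enrichment[order(x$enrichment$bpt_p), ]
  cat("  Most enriched categories (binomial proportion test vs intergenic):\n")
  shown <- utils::head(top[!is.na(top$bpt_p), ], 3)
  for (i in seq_len(nrow(shown)))
    cat(sprintf("    %-10s z = %6.2f  p = %.3g  mean(z^2-1) = %.3f\n",
                shown$category[i], shown$bpt_z[i], shown$bpt_p[i],
                shown$mean_z2_minus_1[i]))
  invisible(x)
}

#' @export
summary.gwas_enrichment <- function(object, ...) {
  out <- list(lambda_gc = object$lambda_gc,
              n_snps = nrow(object$stats),
              n_intergenic = length(object$strata$intergenic),
              enrichment = object$enrichment,
              regression = object$regression,
              loci = t(vapply(object$loci, function(l) l$counts,
                              numeric(3))))
  class(out) <- "summary.gwas_enrichment"
  out
}

#' @export
print.summary.gwas_enrichment <- function(x, ...) {
  cat(sprintf("lambda_GC = %.4f over %d intergenic of %d tag SNPs\n\n",
              x$lambda_gc, x$n_intergenic, x$n_snps))
  cat("Enrichment by category:\n")
  print(x$enrichment, digits = 3, row.names = FALSE)
  cat("\nRegression of log z^2 on annotation scores:\n")
  print(x$regression, digits = 3, row.names = FALSE)
  cat("\nSignificant LD-independent loci (condFDR / FDR / Bonferroni):\n")
  print(x$loci)
  invisible(x)
}

#' @export
coef.gwas_enrichment <- function(object, ...) {
  stats::setNames(object$regression$estimate, object$regression$term)
}

#' Stratified Q-Q plot of a fitted enrichment analysis
#'
#' Draws the replica-averaged empirical -log10(p) quantile curves against
#' nominal -log10(p) with 95\% bands for the selected strata; the identity
#' line is the global null.  Deflection above the line indicates
#' enrichment, and the vertical gap is -log10 of the stratum's empirical
#' FDR.
#'
#' @param x A \code{gwas_enrichment} object.
#' @param strata Strata to draw (default miRNA, intergenic, all).
#' @param ... Passed to \code{matplot}.
#' @export
plot.gwas_enrichment <- function(x, strata = c("miRNA", "intergenic", "all"),
                                 ...) {
  plot_qq_curves(x$qq, strata = strata, ...)
}

#' @rdname plot.gwas_enrichment
#' @param qq A \code{qq_curves} object.
#' @export
plot_qq_curves <- function(qq, strata = names(qq$curves), ...) {
  strata <- intersect(strata, names(qq$curves))
  if (!length(strata)) stop("no curves to plot")
  ylim <- range(unlist(lapply(qq$curves[strata], function(d) d$mean)))
  cols <- grDevices::hcl.colors(max(3, length(strata)), "Dark 3")
  graphics::plot(NA, xlim = range(qq$grid), ylim = c(0, max(ylim)),
                 xlab = expression(Nominal ~ -log[10](p)),
                 ylab = expression(Empirical ~ -log[10](p)), ...)
  graphics::abline(0, 1, col = "grey50", lty = 2)
  for (i in seq_along(strata)) {
    d <- qq$curves[[strata[i]]]
    graphics::polygon(c(d$nominal, rev(d$nominal)),
                      c(pmax(d$lower, 0), rev(d$upper)),
                      col = grDevices::adjustcolor(cols[i], 0.2), border = NA)
    graphics::lines(d$nominal, d$mean, col = cols[i], lwd = 2)
  }
  graphics::legend("topleft", legend = strata, col = cols[seq_along(strata)],
                   lwd = 2, bty = "n")
  invisible(qq)
}

#' Replication-rate plot
#'
#' @param x A \code{replication_analysis} object.
#' @param ... Passed to \code{plot}.
#' @export
plot.replication_analysis <- function(x, ...) {
  cols <- grDevices::hcl.colors(max(3, length(x$curves)), "Dark 3")
  xr <- range(unlist(lapply(x$curves, function(cv) cv$bins)))
  graphics::plot(NA, xlim = xr, ylim = c(0, 1),
                 xlab = expression(Discovery ~ -log[10](p)),
                 ylab = "Cumulative replication rate", ...)
  for (i in seq_along(x$curves))
    graphics::lines(x$curves[[i]]$bins, x$curves[[i]]$rate, col = cols[i],
                    lwd = 2)
  graphics::legend("bottomright", legend = names(x$curves),
                   col = cols[seq_along(x$curves)], lwd = 2, bty = "n")
  invisible(x)
}
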