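#' Hardy-Weinberg equilibrium goodness-of-fit test
#'
#' Classical 1-df chi-square test of observed genotype counts against the
#' expectation under Hardy-Weinberg proportions at the observed allele
#' frequency.  Monomorphic SNPs return p = 1 by convention.
#'
#' @param n_hom_ref,n_het,n_hom_alt Non-negative genotype counts.
#' @return The chi-square p-value.
#' @export
hwe_test <- function(n_hom_ref, n_het, n_hom_alt) {
  n <- n_hom_ref + n_het + n_hom_alt
  stopifnot(n > 0, n_hom_ref >= 0, n_het >= 0, n_hom_alt >= 0)
  f <- (2 * n_hom_ref + n_het) / (2 * n)  # reference allele frequency
  if (f <= 0 || f >= 1) return(1)
  expected <- n * c(f^2, 2 * f * (1 - f), (1 - f)^2)
  chi2 <- sum((c(n_hom_ref, n_het, n_hom_alt) - expected)^2 / expected)
  stats::pchisq(chi2, df = 1, lower.tail = FALSE)
}

#' Quality-control filter for a genotype panel
#'
#' Individuals missing more than \code{ind_miss_max} of their genotypes are
#' removed first; SNP filters (missingness, minor allele frequency,
#' Hardy-Weinberg equilibrium) are then applied on the retained individuals.
#'
#' @param panel A [genotype_panel()].
#' @param maf_min Minimum minor allele frequency (SNPs below are removed).
#' @param snp_miss_max Maximum per-SNP missingness.
#' @param hwe_p_min Minimum Hardy-Weinberg p-value.
#' @param ind_miss_max Maximum per-individual missingness.
#' @return The filtered \code{genotype_panel}.
#' @export
qc_filter <- function(panel, maf_min = 0.01, snp_miss_max = 0.05,
                      hwe_p_min = 1e-6, ind_miss_max = 0.10) {
  stopifnot(inherits(panel, "genotype_panel"))
  ind_miss <- rowMeans(is.na(panel$counts))
  keep_ind <- ind_miss <= ind_miss_max
  counts <- panel$counts[keep_ind, , drop = FALSE]

  snp_miss <- colMeans(is.na(counts))
  f <- colMeans(counts, na.rm = TRUE) / 2
  maf <- pmin(f, 1 - f)
  hwe_p <- vapply(seq_len(ncol(counts)), function(j) {
    g <- counts[, j]
    hwe_test(sum(g == 0L, na.rm = TRUE), sum(g == 1L, na.rm = TRUE),
             sum(g == 2L, na.rm = TRUE))
  }, numeric(1))
  fail_miss <- snp_miss > snp_miss_max
  fail_maf <- is.na(maf) | maf < maf_min
  fail_hwe <- hwe_p < hwe_p_min
  keep_snp <- !(fail_miss | fail_maf | fail_hwe)
  log_msg("qc_filter: removed %d/%d individuals (missingness > %.2f); removed %d/%d SNPs (%d missingness, %d MAF, %d HWE)",
          sum(!keep_ind), length(keep_ind), ind_miss_max,
          sum(!keep_snp), length(keep_snp), sum(fail_miss),
          sum(fail_maf & !fail_miss), sum(fail_hwe & !fail_miss & !fail_maf))
  if (!any(keep_snp)) stop("qc_filter removed all SNPs")
  genotype_panel(panel$map[keep_snp, , drop = FALSE],
                 counts[, keep_snp, drop = FALSE])
}

#' Pairwise LD as squared Pearson correlation of allele counts
#'
#' Composite LD from unphased allele counts: the squared Pearson correlation
#' over individuals with both genotypes present.  Undefined values (fewer
#' than two complete pairs, or zero variance) are returned as 0.
#'
#' @param panel A [genotype_panel()].
#' @param i,j SNP indices or ids.
#' @return r-squared in \[0, 1\].
#' @export
pairwise_r2 <- function(panel, i, j) {
  if (is.character(i)) i <- match(i, panel$map$id)
  if (is.character(j)) j <- match(j, panel$map$id)
  r <- suppressWarnings(stats::cor(panel$counts[, i], panel$counts[, j],
                                   use = "pairwise.complete.obs"))
  if (is.na(r)) 0 else min(r^2, 1)
}

#' Build the windowed LD neighbour store
#'
#' Evaluates r-squared for every pair of panel SNPs on the same chromosome
#' within \code{window} base pairs, stores pairs with r-squared at or above
#' \code{r2_min} (values below the threshold are treated as zero throughout
#' the pipeline) and always includes the self pair with r-squared 1.
#'
#' @param panel A QC-passed [genotype_panel()].
#' @param window Maximum pair distance in base pairs.
#' @param r2_min Minimum stored r-squared.
#' @return An object of class \code{ld_neighbors}: ids/chrom/pos vectors and,
#'   per SNP, the integer indices (\code{nbr_idx}, self included) and
#'   r-squared values (\code{nbr_r2}) of its stored neighbours.
#' @export
build_ld_neighbors <- function(panel, window = 1e6, r2_min = 0.2) {
  stopifnot(inherits(panel, "genotype_panel"))
  n <- ncol(panel$counts)
  ii <- vector("list", n); rr <- vector("list", n)
  for (chr in unique(panel$map$chrom)) {
    idx <- which(panel$map$chrom == chr)
    idx <- idx[order(panel$map$pos[idx])]
    pos <- panel$map$pos[idx]
    m <- length(idx)
    for (a in seq_len(m)) {
      if (a == m) break
      b <- which(pos[(a + 1):m] - pos[a] <= window) + a
      if (!length(b)) next
      r <- suppressWarnings(stats::cor(panel$counts[, idx[a]],
                                       panel$counts[, idx[b], drop = FALSE],
                                       use = "pairwise.complete.obs"))
      r2 <- pmin(as.numeric(r)^2, 1)
      r2[is.na(r2)] <- 0
      keep <- r2 >= r2_min
      if (any(keep)) {
        ia <- idx[a]; jb <- idx[b][keep]; v <- r2[keep]
        ii[[ia]] <- c(ii[[ia]], jb); rr[[ia]] <- c(rr[[ia]], v)
        for (k in seq_along(jb)) {
          ii[[jb[k]]] <- c(ii[[jb[k]]], ia)
          rr[[jb[k]]] <- c(rr[[jb[k]]], v[k])
        }
      }
    }
  }
  for (s in seq_len(n)) {  # self term, then sort by index for determinism
    ii[[s]] <- c(ii[[s]], s); rr[[s]] <- c(rr[[s]], 1)
    o <- order(ii[[s]])
    ii[[s]] <- ii[[s]][o]; rr[[s]] <- rr[[s]][o]
  }
  structure(list(ids = panel$map$id, chrom = panel$map$chrom,
                 pos = panel$map$pos, nbr_idx = ii, nbr_r2 = rr,
                 window = window, r2_min = r2_min),
            class = "ld_neighbors")
}

#' @export
print.ld_neighbors <- function(x, ...) {
  cat("LD neighbour store:", length(x$ids), "SNPs, window", x$window,
      "bp, r2 >=", x$r2_min, "\n")
  cat("  mean neighbours per SNP (self included):",
      round(mean(lengths(x$nbr_idx)), 2), "\n")
  invisible(x)
}

#' Export the neighbour store as a pair table
#'
#' @param neighbors An \code{ld_neighbors} object.
#' @return Data frame (snp_i, snp_j, r2) with each unordered pair once
#'   (i < j); self pairs omitted.
#' @export
neighbors_to_pairs <- function(neighbors) {
  i <- rep.int(seq_along(neighbors$ids), lengths(neighbors$nbr_idx))
  j <- unlist(neighbors$nbr_idx, use.names = FALSE)
  r2 <- unlist(neighbors$nbr_r2, use.names = FALSE)
  keep <- i < j
  data.frame(snp_i = neighbors$ids[i[keep]], snp_j = neighbors$ids[j[keep]],
             r2 = r2[keep], stringsAsFactors = FALSE)
}

#' Rebuild a neighbour store from a pair table
#'
#' @param pairs Data frame (snp_i, snp_j, r2), each unordered pair once.
#' @param map Data frame (id, chrom, pos) for all SNPs in the store.
#' @param window,r2_min Parameters the pairs were built with.
#' @return An \code{ld_neighbors} object.
#' @export
neighbors_from_pairs <- function(pairs, map, window = 1e6, r2_min = 0.2) {
  n <- nrow(map)
  ii <- vector("list", n); rr <- vector("list", n)
  ai <- match(pairs$snp_i, map$id); bj <- match(pairs$snp_j, map$id)
  if (anyNA(ai) || anyNA(bj)) stop("pair table contains ids absent from map")
  for (k in seq_len(nrow(pairs))) {
    ii[[ai[k]]] <- c(ii[[ai[k]]], bj[k]); rr[[ai[k]]] <- c(rr[[ai[k]]], pairs$r2[k])
    ii[[bj[k]]] <- c(ii[[bj[k]]], ai[k]); rr[[bj[k]]] <- c(rr[[bj[k]]], pairs$r2[k])
  }
  for (s in seq_len(n)) {
    ii[[s]] <- c(ii[[s]], s); rr[[s]] <- c(rr[[s]], 1)
    o <- order(ii[[s]])
    ii[[s]] <- ii[[s]][o]; rr[[s]] <- rr[[s]][o]
  }
  structure(list(ids = as.character(map$id), chrom = as.character(map$chrom),
                 pos = as.integer(map$pos), nbr_idx = ii, nbr_r2 = rr,
                 window = window, r2_min = r2_min),
            class = "ld_neighbors")
}

#' Total LD of a SNP
#'
#' Sum of stored r-squared values (at or above the store threshold) between a
#' SNP and all panel SNPs within the store window, self term included, so
#' TotLD >= 1.
#'
#' @param neighbors An \code{ld_neighbors} object.
#' @param i SNP index or id; defaults to all SNPs.
#' @return Numeric vector of TotLD values.
#' @export
total_ld <- function(neighbors, i = seq_along(neighbors$ids)) {
  if (is.character(i)) i <- match(i, neighbors$ids)
  vapply(neighbors$nbr_r2[i], sum, numeric(1))
}

#' Random LD-pruning replicas
#'
#' Each replica is a maximal subset of the tag SNPs in which no retained pair
#' within the store window has r-squared above \code{r2_max}, obtained by a
#' greedy pass over a seeded random ordering (a random maximal independent
#' set of the LD graph).  Replicas differ only through the random ordering.
#'
#' @param snps Character vector of tag SNP ids (must be in the store).
#' @param neighbors An \code{ld_neighbors} object.
#' @param n_replicas Number of replicas.
#' @param seed Integer seed.
#' @param r2_max Retained pairs must have r-squared <= this value.
#' @return List of \code{n_replicas} character vectors of retained ids,
#'   each sorted in store (position) order.
#' @export
ld_prune_replicas <- function(snps, neighbors, n_replicas = 10, seed = 1,
                              r2_max = 0.2) {
  idx <- match(snps, neighbors$ids)
  if (anyNA(idx)) stop("some tag SNPs are absent from the LD store")
  in_set <- logical(length(neighbors$ids)); in_set[idx] <- TRUE
  set.seed(seed)
  replicate(n_replicas, {
    ord <- sample(idx)
    retained <- logical(length(neighbors$ids))
    for (s in ord) {
      nb <- neighbors$nbr_idx[[s]]
      conflict <- any(retained[nb] & nb != s & neighbors$nbr_r2[[s]] > r2_max)
      if (!conflict) retained[s] <- TRUE
    }
    neighbors$ids[which(retained)]
  }, simplify = FALSE)
}
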