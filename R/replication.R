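#' Enumerate discovery/replication splits
#'
#' All unordered choices of \code{group_size} sub-studies out of \code{K} as
#' the discovery group; the complement is the replication group (8 choose 4
#' = 70 splits for the default design).
#'
#' @param K Number of sub-studies.
#' @param group_size Discovery group size (0 < group_size < K).
#' @return List of \code{choose(K, group_size)} elements, each
#'   \code{list(discovery =, replication =)} of sub-study indices.
#' @export
enumerate_splits <- function(K = 8, group_size = 4) {
  stopifnot(group_size > 0, group_size < K)
  cmb <- utils::combn(K, group_size)
  lapply(seq_len(ncol(cmb)), function(k)
    list(discovery = cmb[, k], replication = setdiff(seq_len(K), cmb[, k])))
}

#' Combined z-score of a sub-study group
#'
#' The equal-weight mean of the member z-scores multiplied by the square
#' root of the group size, so that independent standard-normal member
#' scores combine to a standard-normal score.  SNPs missing in any member
#' are excluded (NA) with a logged count.
#'
#' @param substudies Numeric matrix, SNPs x sub-studies (rownames = SNP
#'   ids).
#' @param group_ids Column indices of the group.
#' @return Named numeric vector of combined z-scores (NA where excluded).
#' @export
combine_group_z <- function(substudies, group_ids) {
  stopifnot(length(group_ids) >= 1)
  zz <- substudies[, group_ids, drop = FALSE]
  miss <- rowSums(is.na(zz)) > 0
  if (any(miss))
    log_msg("combine_group_z: %d SNP(s) missing in a group member excluded",
            sum(miss))
  out <- rowMeans(zz) * sqrt(length(group_ids))
  out[miss] <- NA_real_
  out
}

#' Two-tailed discovery p-value
#'
#' @param Z_D Combined discovery z-scores.
#' @return p_D = 2 * pnorm(-|Z_D|).
#' @export
discovery_p <- function(Z_D) 2 * stats::pnorm(-abs(Z_D))

#' One-tailed replication p-value preserving the discovery sign
#'
#' Small when the replication z-score is large in the direction of the
#' discovery z-score: p_R = 1 - pnorm(sgn(Z_D) * Z_R).  With
#' \code{printed_formula = TRUE} the complementary form
#' pnorm(sgn(Z_D) * Z_R) is returned instead.  Z_D = 0 gives p_R = 0.5 by
#' convention.
#'
#' @param Z_D,Z_R Discovery and replication z-scores.
#' @param printed_formula Use the complementary orientation.
#' @return Vector of replication p-values.
#' @export
replication_p <- function(Z_D, Z_R, printed_formula = FALSE) {
  s <- sign(Z_D)
  s[s == 0] <- NA  # undefined direction -> 0.5 below
  v <- stats::pnorm(s * Z_R)
  v[is.na(v) & !is.na(Z_R)] <- 0.5
  if (printed_formula) v else 1 - v
}

#' Cumulative replication-rate curve
#'
#' For each of \code{n_bins} equally spaced bin lower bounds spanning the
#' observed discovery -log10(p) range and each split, the fraction of
#' stratum SNPs with discovery -log10(p) above the bound whose replication
#' p-value is below \code{alpha}; averaged across splits (bins empty in a
#' split are skipped in that split's average).  The bin-0 value is the
#' stratum's overall replication rate.
#'
#' @param p_D,p_R Matrices (SNPs x splits) of discovery and replication
#'   p-values, rownames = SNP ids; vectors are treated as one split.
#' @param stratum_ids SNP ids of the stratum.
#' @param n_bins Number of bins.
#' @param alpha Replication significance level.
#' @param bins Optional explicit bin lower bounds (a common grid lets
#'   strata be compared bin by bin); default spans the stratum's observed
#'   range.
#' @return Object of class \code{replication_curve}: \code{bins} (lower
#'   bounds), \code{rate} (split-averaged), \code{n_splits},
#'   \code{overall_rate}.
#' @export
cumulative_replication_rate <- function(p_D, p_R, stratum_ids, n_bins = 1000,
                                        alpha = 0.05, bins = NULL) {
  if (is.null(dim(p_D))) p_D <- as.matrix(p_D)
  if (is.null(dim(p_R))) p_R <- as.matrix(p_R)
  stratum_ids <- as.character(stratum_ids)
  if (!length(stratum_ids)) stop("empty stratum")
  lpd <- -log10(p_D[stratum_ids, , drop = FALSE])
  rep_ok <- p_R[stratum_ids, , drop = FALSE] < alpha
  n_splits <- ncol(lpd)
  if (is.null(bins))
    bins <- seq(0, max(lpd, na.rm = TRUE), length.out = n_bins)
  rate_mat <- matrix(NA_real_, n_bins, n_splits)
  overall <- numeric(n_splits)
  for (s in seq_len(n_splits)) {
    ok <- !is.na(lpd[, s]) & !is.na(rep_ok[, s])
    x <- lpd[ok, s]; r <- rep_ok[ok, s]
    overall[s] <- mean(r)
    o <- order(x, decreasing = TRUE)
    cs <- cumsum(r[o])
    xs <- sort(x)                       # ascending for findInterval
    n_above <- length(x) - findInterval(bins, xs)  # strictly > bound
    pos <- n_above > 0
    rate_mat[pos, s] <- cs[n_above[pos]] / n_above[pos]
  }
  structure(list(bins = bins, rate = rowMeans(rate_mat, na.rm = TRUE),
                 per_split = rate_mat, n_splits = n_splits,
                 overall_rate = mean(overall)),
            class = "replication_curve")
}

#' Full sub-study replication analysis
#'
#' Adjusts each sub-study independently by intergenic inflation control,
#' enumerates all discovery/replication splits, combines group z-scores,
#' converts to discovery and replication p-values and computes the
#' cumulative replication-rate curve per stratum.
#'
#' @param substudies SNPs x K matrix of signed sub-study z-scores (rownames
#'   = SNP ids).
#' @param strata Named list of stratum id sets (e.g. miRNA, intergenic,
#'   all).
#' @param intergenic_ids Ids of the intergenic stratum used for per-study
#'   inflation control (NULL skips adjustment).
#' @param group_size Discovery group size.
#' @param n_bins,alpha Passed to [cumulative_replication_rate()].
#' @return List of class \code{replication_analysis}: per-stratum
#'   \code{replication_curve}s, the split list, and the per-study lambda
#'   values.
#' @export
replication_analysis <- function(substudies, strata, intergenic_ids = NULL,
                                 group_size = ncol(substudies) / 2,
                                 n_bins = 1000, alpha = 0.05) {
  K <- ncol(substudies)
  lambdas <- rep(1, K)
  if (!is.null(intergenic_ids)) {
    for (k in seq_len(K)) {
      zk <- substudies[, k]
      lambdas[k] <- estimate_lambda_gc(zk, intergenic_ids)
      substudies[, k] <- zk / sqrt(lambdas[k])
    }
  }
  splits <- enumerate_splits(K, group_size)
  n <- nrow(substudies)
  p_D <- matrix(NA_real_, n, length(splits),
                dimnames = list(rownames(substudies), NULL))
  p_R <- p_D
  for (s in seq_along(splits)) {
    ZD <- combine_group_z(substudies, splits[[s]]$discovery)
    ZR <- combine_group_z(substudies, splits[[s]]$replication)
    p_D[, s] <- discovery_p(ZD)
    p_R[, s] <- replication_p(ZD, ZR)
  }
  empty <- lengths(strata) == 0
  if (any(empty)) {
    log_msg("replication_analysis: empty stratum curve(s) omitted: %s",
            paste(names(strata)[empty], collapse = ", "))
    strata <- strata[!empty]
  }
  bins <- seq(0, max(-log10(p_D), na.rm = TRUE), length.out = n_bins)
  curves <- lapply(strata, function(ids)
    cumulative_replication_rate(p_D, p_R, ids, alpha = alpha, bins = bins))
  structure(list(curves = curves, splits = splits, lambdas = lambdas,
                 p_D = p_D, p_R = p_R, alpha = alpha),
            class = "replication_analysis")
}
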