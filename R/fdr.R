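#' Empirical Bayesian FDR estimate
#'
#' For each SNP with p-value p, the empirical cdf is q = N_p / N (N_p = SNPs
#' with p-value <= p, ties counted together) and the conservative FDR
#' estimate with pi0 fixed at 1 is min(1, p / q), made non-decreasing in p
#' by a cumulative-maximum step so that it can drive a monotone discovery
#' rule.
#'
#' @param p Numeric vector of p-values in (0, 1], optionally named.
#' @param monotone Apply the cumulative-maximum monotonisation (default
#'   TRUE).
#' @return Numeric vector of FDR estimates, same order and names as
#'   \code{p}.
#' @export
fdr_estimate <- function(p, monotone = TRUE) {
  stopifnot(all(p > 0 & p <= 1))
  q <- rank(p, ties.method = "max") / length(p)
  fdr <- p / q
  fdr[fdr > 1] <- 1  # subsetting assignment keeps names where pmin would not
  if (monotone) {
    ord <- order(p)
    fdr[ord] <- cummax(fdr[ord])
  }
  fdr
}

#' Conditional FDR given stratum membership
#'
#' The conditioning variable is binary membership of an annotation stratum:
#' F(p | x) is estimated by the empirical cdf within the stratum and
#' condFDR = min(1, p / F(p | x)), monotonised within the stratum.  For an
#' enriched stratum F(p | x) > F(p), so condFDR < FDR at matched p.
#'
#' @param p Named vector of p-values for all SNPs.
#' @param stratum_ids SNP ids of the stratum.
#' @return Named vector of condFDR estimates for the stratum members (in
#'   \code{stratum_ids} order).
#' @export
cond_fdr <- function(p, stratum_ids) {
  stratum_ids <- as.character(stratum_ids)
  ps <- p[stratum_ids]
  if (anyNA(ps)) stop("stratum ids absent from p")
  if (length(ps) == 0) stop("empty stratum")
  if (length(ps) < 100)
    log_msg("cond_fdr: stratum has only %d SNPs; estimate may be unreliable",
            length(ps))
  fdr_estimate(ps)
}

#' True discovery rate
#'
#' @param fdr_values FDR (or condFDR) estimates.
#' @return 1 - FDR, elementwise.
#' @export
tdr <- function(fdr_values) 1 - fdr_values

#' Per-SNP FDR/condFDR table
#'
#' @param p Named vector of adjusted p-values for all SNPs.
#' @param strata Named list of stratum id sets; a condFDR column
#'   \code{cond_<name>} is added for each (NA outside the stratum).
#' @return Data frame: snp_id, p, fdr, tdr, and one condFDR column per
#'   stratum.
#' @export
fdr_table <- function(p, strata = list()) {
  out <- data.frame(snp_id = names(p), p = as.numeric(p),
                    fdr = fdr_estimate(p), stringsAsFactors = FALSE)
  out$tdr <- tdr(out$fdr)
  for (st in names(strata)) {
    v <- rep(NA_real_, nrow(out))
    cf <- cond_fdr(p, strata[[st]])
    v[match(names(cf), out$snp_id)] <- cf
    out[[paste0("cond_", st)]] <- v
  }
  out
}

# greedy LD pruning of a candidate id list ranked by `values` (ascending;
# ties broken by position): a candidate is retained iff it has r2 <=
# prune_r2 with every already-retained SNP within the store window
prune_by_value <- function(ids, values, neighbors, prune_r2 = 0.2) {
  idx <- match(ids, neighbors$ids)
  if (anyNA(idx)) stop("candidate ids absent from the LD store")
  ord <- order(values, neighbors$pos[idx])
  retained <- logical(length(neighbors$ids))
  keep <- character(0)
  for (k in ord) {
    s <- idx[k]
    nb <- neighbors$nbr_idx[[s]]
    if (!any(retained[nb] & nb != s & neighbors$nbr_r2[[s]] > prune_r2)) {
      retained[s] <- TRUE
      keep <- c(keep, ids[k])
    }
  }
  keep
}

#' Significant loci under condFDR, FDR and Bonferroni rules
#'
#' Counts LD-independent significant loci in a stratum under three rules:
#' condFDR < threshold, unconditional FDR < threshold, and the conventional
#' genome-wide Bonferroni p < 5e-8.  Candidates are greedily pruned so that
#' no two retained SNPs within the store window have r-squared above
#' \code{prune_r2}, keeping the smaller criterion value (ties by position).
#'
#' @param tbl Table from [fdr_table()] (needs the \code{cond_<stratum>}
#'   column).
#' @param stratum Name of the stratum (must match a condFDR column).
#' @param neighbors The \code{ld_neighbors} store.
#' @param threshold FDR/condFDR significance threshold.
#' @param prune_r2 Maximum r-squared between retained loci.
#' @param bonferroni Genome-wide significance p threshold.
#' @return List with per-rule id vectors (\code{condfdr}, \code{fdr},
#'   \code{bonferroni}) and a named count vector \code{counts}.
#' @export
significant_loci <- function(tbl, stratum, neighbors, threshold = 0.01,
                             prune_r2 = 0.2, bonferroni = 5e-8) {
  col <- paste0("cond_", stratum)
  if (!col %in% names(tbl)) stop("no condFDR column for stratum '", stratum, "'")
  member <- !is.na(tbl[[col]])
  rules <- list(
    condfdr = list(sel = member & tbl[[col]] < threshold, val = tbl[[col]]),
    fdr = list(sel = member & tbl$fdr < threshold, val = tbl$fdr),
    bonferroni = list(sel = member & tbl$p < bonferroni, val = tbl$p))
  out <- lapply(rules, function(r) {
    ids <- tbl$snp_id[r$sel]
    if (!length(ids)) return(character(0))
    prune_by_value(ids, r$val[r$sel], neighbors, prune_r2 = prune_r2)
  })
  out$counts <- lengths(out[c("condfdr", "fdr", "bonferroni")])
  out
}
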