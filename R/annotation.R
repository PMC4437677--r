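#' Extend annotation intervals symmetrically
#'
#' Pads every interval by \code{pad} base pairs on both sides, clipping at
#' the chromosome start.  In the pipeline this is applied to the miRNA
#' primary-transcript track only (10 kb each way), so that SNPs in the
#' regulatory regions of the miRNAs themselves are captured.
#'
#' @param track An [interval_track()].
#' @param pad Pad in base pairs.
#' @return The padded \code{interval_track}.
#' @export
extend_intervals <- function(track, pad = 10000) {
  stopifnot(inherits(track, "interval_track"), pad >= 0)
  out <- data.frame(chrom = track$chrom,
                    start = pmax(0, track$start - pad),
                    end = track$end + pad, stringsAsFactors = FALSE)
  attr(out, "category") <- attr(track, "category")
  class(out) <- c("interval_track", "data.frame")
  out
}

# TRUE for each (chrom, pos) that falls inside any interval of the track,
# optionally after padding.  pos is 1-based; intervals 0-based half-open,
# so a SNP at 1-based position P lies in [s, e) iff s <= P - 1 < e.
track_contains <- function(track, chrom, pos, pad = 0) {
  hit <- logical(length(pos))
  if (is.null(track) || nrow(track) == 0L) return(hit)
  s <- pmax(0, track$start - pad); e <- track$end + pad
  for (chr in unique(track$chrom)) {
    ti <- track$chrom == chr
    qi <- which(chrom == chr)
    if (!length(qi)) next
    ir <- IRanges::IRanges(start = s[ti] + 1, end = e[ti])
    qr <- IRanges::IRanges(start = pos[qi], width = 1L)
    hit[qi] <- IRanges::overlapsAny(qr, ir)
  }
  hit
}

#' Mutually exclusive positional category of panel SNPs
#'
#' Assigns each panel SNP the highest-priority genic category whose intervals
#' contain its position, or \code{"intergenic"} if none does.  The miRNA
#' track is assumed already extended.
#'
#' @param panel A [genotype_panel()] (or a data frame with chrom/pos).
#' @param tracks Named list of [interval_track()]s (names from
#'   [GENIC_CATEGORIES]; extra tracks ignored here).
#' @param priority Category priority order for overlap resolution.
#' @return Factor of length n SNPs with levels \code{c(priority,
#'   "intergenic")}.
#' @export
positional_category <- function(panel, tracks,
                                priority = GENIC_CATEGORIES) {
  map <- if (inherits(panel, "genotype_panel")) panel$map else panel
  cat <- rep(NA_character_, nrow(map))
  for (cg in rev(priority)) {  # highest priority assigned last, wins
    if (is.null(tracks[[cg]])) next
    hit <- track_contains(tracks[[cg]], map$chrom, map$pos)
    cat[hit] <- cg
  }
  cat[is.na(cat)] <- "intergenic"
  factor(cat, levels = c(priority, "intergenic"))
}

#' LD-weighted annotation scores for tag SNPs
#'
#' For tag SNP i and category C the score is \eqn{\sum_j \delta_j r^2_{ij}}
#' over panel SNPs j, where \eqn{\delta_j} indicates positional membership of
#' j in C and only r-squared values at or above the store threshold (0.2)
#' contribute (the self term r2 = 1 included when the tag SNP itself lies in
#' C).  Tag SNPs absent from the panel are excluded with a logged count.
#'
#' @param tag_snps A \code{summary_stats} table or character vector of ids.
#' @param panel_categories Factor from [positional_category()].
#' @param neighbors An \code{ld_neighbors} store over the panel.
#' @return Data frame of class \code{annotation_scores}: snp_id, chrom, pos,
#'   one score column per genic category, and \code{total_ld}.
#' @export
ld_weighted_scores <- function(tag_snps, panel_categories, neighbors) {
  ids <- if (is.data.frame(tag_snps)) tag_snps$snp_id else as.character(tag_snps)
  idx <- match(ids, neighbors$ids)
  if (anyNA(idx)) {
    log_msg("ld_weighted_scores: %d tag SNP(s) absent from the reference panel excluded",
            sum(is.na(idx)))
    ids <- ids[!is.na(idx)]; idx <- idx[!is.na(idx)]
  }
  if (!length(idx)) stop("no tag SNPs map onto the reference panel")
  cats <- as.character(panel_categories)
  score <- matrix(0, nrow = length(idx), ncol = length(GENIC_CATEGORIES),
                  dimnames = list(NULL, GENIC_CATEGORIES))
  totld <- numeric(length(idx))
  for (k in seq_along(idx)) {
    nb <- neighbors$nbr_idx[[idx[k]]]
    r2 <- neighbors$nbr_r2[[idx[k]]]
    totld[k] <- sum(r2)
    cs <- vapply(split(r2, factor(cats[nb], levels = GENIC_CATEGORIES)),
                 sum, numeric(1))
    score[k, ] <- cs
  }
  out <- data.frame(snp_id = ids, chrom = neighbors$chrom[idx],
                    pos = neighbors$pos[idx], stringsAsFactors = FALSE)
  out <- cbind(out, as.data.frame(score), total_ld = totld)
  class(out) <- c("annotation_scores", "data.frame")
  out
}

#' LD-based category membership
#'
#' A tag SNP is an LD member of a category iff its LD-weighted score for
#' that category is at least \code{threshold} (default 1, i.e. at least the
#' equivalent of one fully linked category SNP).  Membership is not
#' exclusive: a tag SNP may belong to several categories.
#'
#' @param scores An \code{annotation_scores} table.
#' @param threshold Score threshold.
#' @return Logical matrix (tag SNPs x genic categories).
#' @export
assign_ld_membership <- function(scores, threshold = 1.0) {
  as.matrix(scores[, GENIC_CATEGORIES, drop = FALSE]) >= threshold
}

#' Identify intergenic tag SNPs
#'
#' A tag SNP is intergenic iff (a) all ten genic LD-weighted scores are
#' exactly zero, and (b) no panel SNP in its LD neighbour list (self
#' included) lies within \code{gene_pad} base pairs of a protein-coding gene
#' interval or inside an ncRNA, TFBS or miRNA binding-site interval.
#' Intergenic SNPs form the likely-null stratum used for inflation control.
#'
#' @param scores An \code{annotation_scores} table.
#' @param panel The [genotype_panel()] the neighbour store was built on.
#' @param tracks Named list of tracks; \code{protein_coding_gene},
#'   \code{ncRNA}, \code{TFBS} and \code{miRNA_BS} are consulted.
#' @param neighbors The \code{ld_neighbors} store.
#' @param gene_pad Proximity pad for protein-coding genes (bp).
#' @return Logical vector, one flag per row of \code{scores}.
#' @export
identify_intergenic <- function(scores, panel, tracks, neighbors,
                                gene_pad = 1e5) {
  near <- track_contains(tracks$protein_coding_gene, panel$map$chrom,
                         panel$map$pos, pad = gene_pad)
  for (cg in c("ncRNA", "TFBS", "miRNA_BS"))
    near <- near | track_contains(tracks[[cg]], panel$map$chrom, panel$map$pos)
  idx <- match(scores$snp_id, neighbors$ids)
  zero_scores <- rowSums(as.matrix(scores[, GENIC_CATEGORIES, drop = FALSE])) == 0
  no_near <- !vapply(idx, function(s) any(near[neighbors$nbr_idx[[s]]]),
                     logical(1))
  zero_scores & no_near
}

#' Full annotation of tag SNPs
#'
#' Convenience wrapper: extends the miRNA track, assigns positional
#' categories to panel SNPs, computes LD-weighted scores, membership flags
#' and the intergenic flag for the tag SNPs.
#'
#' @inheritParams ld_weighted_scores
#' @inheritParams identify_intergenic
#' @param tag_snps A \code{summary_stats} table.
#' @param mirna_pad Extension of the miRNA track (bp each way).
#' @param score_threshold Membership threshold on the LD-weighted score.
#' @return An \code{annotation_scores} data frame with additional logical
#'   columns \code{member_<category>} and \code{intergenic}.
#' @export
annotate_tags <- function(tag_snps, panel, tracks, neighbors,
                          mirna_pad = 10000, score_threshold = 1.0,
                          gene_pad = 1e5) {
  if (!is.null(tracks$miRNA))
    tracks$miRNA <- extend_intervals(tracks$miRNA, pad = mirna_pad)
  pc <- positional_category(panel, tracks)
  scores <- ld_weighted_scores(tag_snps, pc, neighbors)
  member <- assign_ld_membership(scores, threshold = score_threshold)
  colnames(member) <- paste0("member_", colnames(member))
  scores <- cbind(scores, as.data.frame(member))
  scores$intergenic <- identify_intergenic(scores, panel, tracks, neighbors,
                                           gene_pad = gene_pad)
  class(scores) <- c("annotation_scores", "data.frame")
  scores
}

#' Strata (SNP-id sets) from an annotation table
#'
#' @param scores An annotated table from [annotate_tags()].
#' @return Named list of character vectors: one per genic category (LD
#'   members), plus \code{intergenic} and \code{all}.
#' @export
annotation_strata <- function(scores) {
  strata <- lapply(GENIC_CATEGORIES, function(cg)
    scores$snp_id[scores[[paste0("member_", cg)]]])
  names(strata) <- GENIC_CATEGORIES
  strata$intergenic <- scores$snp_id[scores$intergenic]
  strata$all <- scores$snp_id
  strata
}
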