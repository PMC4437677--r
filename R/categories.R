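#' Genomic annotation categories
#'
#' The ten genic annotation categories used for LD-weighted scoring, in the
#' priority order used to resolve overlapping positional assignments
#' (regulatory-RNA categories first, then transcript anatomy from most to
#' least specific, then regulatory DNA elements).  The protein-coding gene
#' track is carried separately: it never receives a score and is used only by
#' the intergenic proximity rule.
#'
#' @format Character vectors.
#' @name categories
NULL

#' @rdname categories
#' @export
GENIC_CATEGORIES <- c("miRNA", "miRNA_BS", "UTR5", "UTR3", "exon", "intron",
                      "enhancer", "silencer", "TFBS", "ncRNA")

#' @rdname categories
#' @export
TRACK_CATEGORIES <- c(GENIC_CATEGORIES, "protein_coding_gene")

# log helper: all pipeline-side bookkeeping (drop counts, filter tallies)
# goes through message() so callers can suppressMessages() cleanly
log_msg <- function(...) message(sprintf(...))
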