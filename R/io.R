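#' Read GWAS summary statistics
#'
#' Reads a tab- or whitespace-separated file with a header line into a
#' validated summary-statistics table.  Exactly one of a p-value column or a
#' z-score column must be mapped; the other is derived on load
#' (z = |qnorm(p/2)| when only p is given, in which case the z-scores carry
#' no sign and the table is flagged unsigned; p = 2*pnorm(-|z|) when z is
#' given).  Rows with p outside (0, 1], non-numeric fields, or duplicated
#' SNP ids are dropped with a logged count.
#'
#' @param path Path to the summary-statistics file.
#' @param column_map Named list mapping the roles \code{id}, \code{chrom},
#'   \code{pos} and exactly one of \code{p}, \code{z} to column names in the
#'   file header.
#' @return A \code{data.frame} of class \code{summary_stats} with columns
#'   \code{snp_id}, \code{chrom}, \code{pos}, \code{z}, \code{p} and an
#'   attribute \code{signed} (FALSE when z was derived from p).
#' @export
read_summary_stats <- function(path,
                               column_map = list(id = "snp_id", chrom = "chrom",
                                                 pos = "pos", z = "z")) {
  dat <- utils::read.table(path, header = TRUE, sep = "", quote = "",
                           comment.char = "", stringsAsFactors = FALSE,
                           check.names = FALSE)
  has_p <- !is.null(column_map[["p", exact = TRUE]])
  has_z <- !is.null(column_map[["z", exact = TRUE]])
  if (has_p == has_z)
    stop("column_map must name exactly one of 'p' or 'z'")
  needed <- unlist(column_map[c("id", "chrom", "pos", if (has_p) "p" else "z")])
  missing_cols <- setdiff(needed, names(dat))
  if (length(missing_cols))
    stop("missing mandatory column(s): ", paste(missing_cols, collapse = ", "))

  out <- data.frame(snp_id = as.character(dat[[column_map$id]]),
                    chrom  = as.character(dat[[column_map$chrom]]),
                    pos    = suppressWarnings(as.integer(dat[[column_map$pos]])),
                    stringsAsFactors = FALSE)
  if (has_p) {
    out$p <- suppressWarnings(as.numeric(dat[[column_map[["p"]]]]))
    bad <- is.na(out$p) | out$p <= 0 | out$p > 1
  } else {
    out$z <- suppressWarnings(as.numeric(dat[[column_map[["z"]]]]))
    bad <- is.na(out$z) | !is.finite(out$z)
  }
  bad <- bad | is.na(out$pos) | out$pos < 1
  dup <- duplicated(out$snp_id) | duplicated(out$snp_id, fromLast = TRUE)
  # every copy of a duplicated id is untrustworthy; drop them all
  drop <- bad | dup
  if (any(drop))
    log_msg("read_summary_stats: dropped %d of %d rows (%d invalid, %d duplicated id)",
            sum(drop), nrow(out), sum(bad), sum(dup & !bad))
  out <- out[!drop, , drop = FALSE]
  if (nrow(out) == 0L) stop("no valid rows in ", path)

  if (has_p) {
    out$z <- abs(stats::qnorm(out$p / 2))
    signed <- FALSE
  } else {
    out$p <- 2 * stats::pnorm(-abs(out$z))
    signed <- TRUE
  }
  out <- out[, c("snp_id", "chrom", "pos", "z", "p")]
  rownames(out) <- NULL
  attr(out, "signed") <- signed
  class(out) <- c("summary_stats", "data.frame")
  out
}

#' Construct a summary-statistics table in code
#'
#' @param snp_id,chrom,pos,z Vectors of equal length; \code{z} must be signed.
#' @param signed Whether the z-scores carry signs (default TRUE).
#' @return A \code{summary_stats} data frame (see [read_summary_stats()]).
#' @export
summary_stats <- function(snp_id, chrom, pos, z, signed = TRUE) {
  out <- data.frame(snp_id = as.character(snp_id), chrom = as.character(chrom),
                    pos = as.integer(pos), z = as.numeric(z),
                    p = 2 * stats::pnorm(-abs(as.numeric(z))),
                    stringsAsFactors = FALSE)
  attr(out, "signed") <- signed
  class(out) <- c("summary_stats", "data.frame")
  out
}

#' Read a BED3 annotation interval track
#'
#' Intervals are 0-based half-open per the BED convention.  Rows with
#' \code{start >= end} are rejected with a warning; output is sorted by
#' chromosome and start.
#'
#' @param path Path to a BED3 file (no header).
#' @param category One of [TRACK_CATEGORIES].
#' @return A \code{data.frame} of class \code{interval_track} with columns
#'   \code{chrom}, \code{start}, \code{end} and attribute \code{category}.
#' @export
read_interval_track <- function(path, category) {
  category <- match.arg(category, TRACK_CATEGORIES)
  dat <- utils::read.table(path, header = FALSE, sep = "", quote = "",
                           comment.char = "#", stringsAsFactors = FALSE)
  if (ncol(dat) < 3L) stop("BED3 file must have at least 3 columns: ", path)
  interval_track(chrom = as.character(dat[[1L]]),
                 start = as.numeric(dat[[2L]]),
                 end   = as.numeric(dat[[3L]]),
                 category = category)
}

#' @rdname read_interval_track
#' @param chrom,start,end Interval vectors (start 0-based inclusive, end
#'   exclusive).
#' @export
interval_track <- function(chrom, start, end, category) {
  category <- match.arg(category, TRACK_CATEGORIES)
  out <- data.frame(chrom = as.character(chrom), start = as.numeric(start),
                    end = as.numeric(end), stringsAsFactors = FALSE)
  bad <- is.na(out$start) | is.na(out$end) | out$start >= out$end
  if (any(bad)) {
    warning(sum(bad), " empty or malformed interval(s) rejected")
    out <- out[!bad, , drop = FALSE]
  }
  out <- out[order(out$chrom, out$start, out$end), , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "category") <- category
  class(out) <- c("interval_track", "data.frame")
  out
}

#' Read a reference genotype panel
#'
#' The panel is stored as two whitespace-separated text files: a SNP map
#' (columns id, chrom, pos, with header) and a genotype matrix of allele
#' counts in \{0, 1, 2\} with \code{-1} as the missing sentinel, one row per
#' individual, one column per SNP, in map order, no header.
#'
#' @param map_path Path to the SNP map file.
#' @param matrix_path Path to the allele-count matrix file.
#' @param missing Missing-genotype sentinel (fixed at -1 in the file format).
#' @return A list of class \code{genotype_panel}: \code{map} (data.frame
#'   id/chrom/pos), \code{counts} (individuals x SNPs integer matrix with NA
#'   for missing, column names = SNP ids), \code{maf}, \code{missingness}.
#' @export
read_genotype_panel <- function(map_path, matrix_path, missing = -1L) {
  map <- utils::read.table(map_path, header = TRUE, sep = "", quote = "",
                           stringsAsFactors = FALSE)
  if (!all(c("id", "chrom", "pos") %in% names(map)))
    stop("SNP map must have columns id, chrom, pos")
  counts <- as.matrix(utils::read.table(matrix_path, header = FALSE, sep = "",
                                        quote = ""))
  if (ncol(counts) != nrow(map))
    stop("map/matrix dimension mismatch: ", nrow(map), " SNPs in map, ",
         ncol(counts), " columns in matrix")
  counts[counts == missing] <- NA_integer_
  bad <- !is.na(counts) & !(counts %in% c(0L, 1L, 2L))
  if (any(bad))
    stop("genotype matrix contains values outside {0, 1, 2, ", missing, "}")
  genotype_panel(map, counts)
}

#' @rdname read_genotype_panel
#' @param map Data frame with columns id, chrom, pos.
#' @param counts Individuals x SNPs matrix of allele counts (NA = missing).
#' @export
genotype_panel <- function(map, counts) {
  map <- data.frame(id = as.character(map$id), chrom = as.character(map$chrom),
                    pos = as.integer(map$pos), stringsAsFactors = FALSE)
  storage.mode(counts) <- "integer"
  dimnames(counts) <- list(NULL, map$id)
  obj <- list(map = map, counts = counts)
  obj$missingness <- colMeans(is.na(counts))
  f <- colMeans(counts, na.rm = TRUE) / 2
  obj$maf <- pmin(f, 1 - f)
  class(obj) <- "genotype_panel"
  obj
}

#' @export
print.genotype_panel <- function(x, ...) {
  cat("Genotype panel:", nrow(x$counts), "individuals x", ncol(x$counts),
      "SNPs on", length(unique(x$map$chrom)), "chromosome(s)\n")
  cat(sprintf("  MAF range %.3f-%.3f, max SNP missingness %.3f\n",
              min(x$maf), max(x$maf), max(x$missingness)))
  invisible(x)
}

#' Write / read a TSV table with full numeric precision
#'
#' Numeric columns are serialised with \code{\%.17g} so that a write/read
#' round trip reproduces doubles exactly, and output is byte-deterministic.
#'
#' @param x A data frame.
#' @param path Output path.
#' @export
write_tsv <- function(x, path) {
  y <- as.data.frame(x, stringsAsFactors = FALSE)
  for (j in seq_along(y)) {
    if (is.double(y[[j]])) y[[j]] <- sprintf("%.17g", y[[j]])
    else if (is.logical(y[[j]])) y[[j]] <- as.integer(y[[j]])
  }
  utils::write.table(y, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     col.names = TRUE, eol = "\n")
  invisible(path)
}

#' @rdname write_tsv
#' @export
read_tsv <- function(path) {
  utils::read.table(path, header = TRUE, sep = "\t", quote = "",
                    comment.char = "", stringsAsFactors = FALSE)
}
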