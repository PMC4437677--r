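# In-code fixtures shared by the test files.

# a tiny deterministic panel built directly from a genotype matrix
make_panel <- function(counts, chrom = "1", pos = seq_len(ncol(counts)) * 1000,
                       ids = sprintf("s%03d", seq_len(ncol(counts)))) {
  genotype_panel(data.frame(id = ids, chrom = chrom, pos = pos,
                            stringsAsFactors = FALSE), counts)
}

# random clean panel: n individuals x m SNPs, MAF in (0.2, 0.5), no missing
random_panel <- function(n, m, seed = 1, chrom = rep("1", m),
                         pos = seq_len(m) * 1000) {
  set.seed(seed)
  f <- runif(m, 0.2, 0.5)
  counts <- sapply(f, function(fx) rbinom(n, 2, fx))
  make_panel(counts, chrom = chrom, pos = pos)
}

# independent brute-force oracle for windowed, thresholded r2:
# plain double loop with a hand-written Pearson correlation
oracle_r2_matrix <- function(panel, window = 1e6, r2_min = 0.2) {
  m <- ncol(panel$counts)
  out <- matrix(0, m, m)
  for (i in seq_len(m)) {
    out[i, i] <- 1
    for (j in seq_len(m)) {
      if (j == i) next
      if (panel$map$chrom[i] != panel$map$chrom[j]) next
      if (abs(panel$map$pos[i] - panel$map$pos[j]) > window) next
      x <- panel$counts[, i]; y <- panel$counts[, j]
      ok <- !is.na(x) & !is.na(y)
      x <- x[ok]; y <- y[ok]
      if (length(x) < 2 || var(x) == 0 || var(y) == 0) next
      r <- sum((x - mean(x)) * (y - mean(y))) /
        sqrt(sum((x - mean(x))^2) * sum((y - mean(y))^2))
      if (r^2 >= r2_min) out[i, j] <- r^2
    }
  }
  out
}

# brute-force LD-weighted scores and TotLD from an oracle r2 matrix
oracle_scores <- function(panel, categories, window = 1e6, r2_min = 0.2) {
  r2 <- oracle_r2_matrix(panel, window, r2_min)
  cats <- as.character(categories)
  m <- ncol(panel$counts)
  score <- matrix(0, m, length(GENIC_CATEGORIES),
                  dimnames = list(panel$map$id, GENIC_CATEGORIES))
  for (i in seq_len(m))
    for (j in seq_len(m))
      if (cats[j] %in% GENIC_CATEGORIES)
        score[i, cats[j]] <- score[i, cats[j]] + r2[i, j]
  list(score = score, total_ld = rowSums(r2))
}

# z-score mixture draw matching the generator's statistical model
draw_mixture_z <- function(n, pi1, sigma2, lambda = 1) {
  non_null <- runif(n) < pi1
  rnorm(n, 0, sqrt(ifelse(non_null, 1 + sigma2, 1))) * sqrt(lambda)
}

# small simulated pipeline shared by several files (built once per run)
small_sim <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      cfg <- sim_config(n_individuals = 300, n_blocks = 60, seed = 11)
      panel <- simulate_panel(cfg)
      tracks <- simulate_tracks(cfg, panel)
      ss <- simulate_summary_stats(cfg, panel, tracks)
      qc <- suppressMessages(qc_filter(panel))
      nb <- build_ld_neighbors(qc)
      scores <- suppressMessages(annotate_tags(ss, qc, tracks, nb))
      cache <<- list(cfg = cfg, panel = qc, tracks = tracks, ss = ss,
                     neighbors = nb, scores = scores,
                     strata = annotation_strata(scores))
    }
    cache
  }
})
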