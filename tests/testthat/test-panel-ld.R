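test_that("Hardy-Weinberg chi-square test matches hand computation", {
  # exact HWE proportions at f = 0.5
  expect_equal(hwe_test(25, 50, 25), 1)
  # total heterozygote deficit at f = 0.5: chi2 = n, far below 1e-6
  n <- 100
  chi2 <- sum((c(50, 0, 50) - c(25, 50, 25))^2 / c(25, 50, 25))
  expect_equal(chi2, n)
  expect_equal(hwe_test(50, 0, 50), pchisq(chi2, 1, lower.tail = FALSE))
  expect_lt(hwe_test(50, 0, 50), 1e-6)
  # monomorphic convention
  expect_equal(hwe_test(100, 0, 0), 1)
})

test_that("QC filter removes low-MAF, high-missingness SNPs and individuals first", {
  set.seed(2)
  n <- 200
  # 20 clean background SNPs keep per-individual missingness low
  counts <- sapply(runif(20, 0.2, 0.5), function(f) rbinom(n, 2, f))
  counts <- cbind(counts,
                  c(1L, rep(0L, n - 1)),        # MAF 1/400 = 0.0025 -> out
                  rbinom(n, 2, 0.4),            # 6% missing -> out
                  c(rep(0L, n / 2), rep(2L, n / 2)))  # HWE fail at f=0.5
  counts[sample(n, 12), 22] <- NA               # 6% > 5%
  panel <- make_panel(counts)
  out <- suppressMessages(qc_filter(panel))
  expect_equal(out$map$id, sprintf("s%03d", 1:20))

  # an individual missing >10% of genotypes is removed before SNP filters
  counts2 <- sapply(runif(20, 0.2, 0.5), function(f) rbinom(50, 2, f))
  counts2[1, 1:10] <- NA                        # 50% missing individual
  p2 <- suppressMessages(qc_filter(make_panel(counts2)))
  expect_equal(nrow(p2$counts), 49)
  expect_equal(ncol(p2$counts), 20)             # SNP missingness now fine

  # clean panel passes unchanged
  cp <- random_panel(100, 10, seed = 3)
  expect_equal(suppressMessages(qc_filter(cp))$map, cp$map)
})

test_that("pairwise r2 is squared Pearson correlation with edge conventions", {
  g <- cbind(c(0, 0, 1, 1, 2, 2), c(0, 0, 1, 1, 2, 2),
             c(2, 2, 1, 1, 0, 0), c(0, 1, 2, 1, 0, 1), c(0, 1, 1, 2, 1, 0),
             c(1, 1, 1, 1, 1, 1))
  panel <- make_panel(g)
  expect_equal(pairwise_r2(panel, 1, 2), 1)           # identical vectors
  expect_equal(pairwise_r2(panel, 1, 3), 1)           # perfect anticorrelation
  expect_equal(pairwise_r2(panel, 4, 5),
               cor(g[, 4], g[, 5])^2)                 # direct oracle
  expect_equal(pairwise_r2(panel, 1, 6), 0)           # zero variance -> 0
  # fewer than 2 complete pairs -> 0
  g2 <- cbind(c(0, NA, NA, 1), c(NA, 1, 2, NA))
  expect_equal(pairwise_r2(make_panel(g2), 1, 2), 0)
})

test_that("LD neighbour store equals the brute-force windowed computation", {
  pos <- c(seq(1e5, 1e5 + 49 * 2e4, by = 2e4),    # 50 SNPs spanning ~1 Mb
           seq(5e6, 5e6 + 9 * 1e3, by = 1e3))     # 10 distant SNPs
  panel <- random_panel(80, 60, seed = 9, pos = pos)
  nb <- build_ld_neighbors(panel)
  oracle <- oracle_r2_matrix(panel)
  got <- matrix(0, 60, 60)
  for (i in 1:60) got[i, nb$nbr_idx[[i]]] <- nb$nbr_r2[[i]]
  expect_equal(got, oracle, tolerance = 1e-12)
  # symmetry
  expect_equal(got, t(got))
  # window exclusion regardless of correlation: duplicate a SNP 2 Mb away
  g <- panel$counts[, 1]
  p2 <- make_panel(cbind(g, g), pos = c(1, 2.5e6))
  nb2 <- build_ld_neighbors(p2)
  expect_equal(nb2$nbr_idx[[1]], 1L)
  # sub-threshold r2 omitted, self always present
  expect_true(all(unlist(nb$nbr_r2) >= 0.2))
  expect_true(all(vapply(1:60, function(i) i %in% nb$nbr_idx[[i]], logical(1))))
})

test_that("r2 is invariant under permutation of individuals", {
  panel <- random_panel(100, 20, seed = 5)
  set.seed(1)
  perm <- sample(100)
  panel_p <- make_panel(panel$counts[perm, ])
  nb1 <- build_ld_neighbors(panel)
  nb2 <- build_ld_neighbors(panel_p)
  expect_equal(nb1$nbr_idx, nb2$nbr_idx)
  expect_equal(nb1$nbr_r2, nb2$nbr_r2, tolerance = 1e-12)
})

test_that("total LD sums stored r2 with the self term", {
  panel <- random_panel(80, 40, seed = 13)
  nb <- build_ld_neighbors(panel)
  oracle <- rowSums(oracle_r2_matrix(panel))
  expect_equal(total_ld(nb), oracle, tolerance = 1e-12)
  expect_true(all(total_ld(nb) >= 1))
  # isolated SNP: only itself
  iso <- make_panel(cbind(rbinom(50, 2, 0.4), rbinom(50, 2, 0.4)),
                    pos = c(1, 5e6))
  expect_equal(total_ld(build_ld_neighbors(iso)), c(1, 1))
})

test_that("pruning replicas are valid and maximal independent sets", {
  sim <- small_sim()
  reps <- ld_prune_replicas(sim$scores$snp_id, sim$neighbors, n_replicas = 5,
                            seed = 21)
  idx_of <- function(ids) match(ids, sim$neighbors$ids)
  for (r in reps) {
    keep <- idx_of(r)
    flag <- logical(length(sim$neighbors$ids)); flag[keep] <- TRUE
    # validity: no retained pair with r2 > 0.2
    viol <- vapply(keep, function(s) {
      nb <- sim$neighbors$nbr_idx[[s]]
      any(flag[nb] & nb != s & sim$neighbors$nbr_r2[[s]] > 0.2)
    }, logical(1))
    expect_false(any(viol))
    # maximality: every excluded tag SNP conflicts with a retained one
    excl <- setdiff(idx_of(sim$scores$snp_id), keep)
    uncov <- vapply(excl, function(s) {
      nb <- sim$neighbors$nbr_idx[[s]]
      !any(flag[nb] & nb != s & sim$neighbors$nbr_r2[[s]] > 0.2)
    }, logical(1))
    expect_false(any(uncov))
  }
})

test_that("pruning handles degenerate and chain LD structures", {
  # single SNP retained in every replica
  solo <- make_panel(cbind(rbinom(50, 2, 0.3)))
  nbs <- build_ld_neighbors(solo)
  expect_true(all(vapply(ld_prune_replicas("s001", nbs, 4, seed = 1),
                         identical, logical(1), "s001")))
  # two SNPs in near-perfect LD: exactly one retained
  set.seed(8)
  g <- rbinom(200, 2, 0.4)
  g2 <- g; flip <- sample(200, 5); g2[flip] <- rbinom(5, 2, 0.4)
  two <- make_panel(cbind(g, g2), pos = c(1000, 2000))
  nbt <- build_ld_neighbors(two)
  for (r in ld_prune_replicas(two$map$id, nbt, 6, seed = 2))
    expect_length(r, 1)
  # chain A-B, B-C linked, A-C not: valid maximal sets are {B} and {A, C},
  # and both occur across seeds
  chain <- local({
    set.seed(3)
    b <- rbinom(400, 2, 0.5)
    mix <- function(base, keep) ifelse(runif(400) < keep, base, rbinom(400, 2, 0.5))
    make_panel(cbind(A = mix(b, 0.62), B = b, C = mix(b, 0.62)),
               pos = c(1000, 2000, 3000), ids = c("A", "B", "C"))
  })
  nbc <- build_ld_neighbors(chain)
  r2 <- oracle_r2_matrix(chain)   # unnamed; A, B, C are columns 1..3
  expect_gt(r2[1, 2], 0.2); expect_gt(r2[2, 3], 0.2)
  expect_lt(r2[1, 3], 0.2)
  seen <- character(0)
  for (s in 1:20) {
    r <- ld_prune_replicas(c("A", "B", "C"), nbc, 1, seed = s)[[1]]
    expect_true(identical(sort(r), "B") || identical(sort(r), c("A", "C")))
    seen <- union(seen, paste(sort(r), collapse = "+"))
  }
  expect_setequal(seen, c("B", "A+C"))
})

test_that("simulated block-LD panels have higher within- than between-block r2", {
  cfg <- sim_config(n_individuals = 300, n_blocks = 10, snps_per_block = 10,
                    within_block_r2 = 0.6, seed = 17)
  panel <- simulate_panel(cfg)
  block <- attr(panel, "block")
  r2 <- suppressWarnings(cor(panel$counts))^2
  same <- outer(block, block, "==") & upper.tri(r2)
  diff <- !outer(block, block, "==") & upper.tri(r2)
  expect_gt(mean(r2[same]), mean(r2[diff]))
  expect_lt(mean(r2[diff]), 0.05)
})
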