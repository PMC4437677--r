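test_that("lambda_GC definition, scale equivariance, and Monte Carlo recovery", {
  # all z^2 equal to the chi-square(1) median -> lambda = 1
  z <- rep(c(-1, 1) * sqrt(qchisq(0.5, 1)), 50)
  expect_equal(estimate_lambda_gc(z), 1)
  expect_equal(estimate_lambda_gc(z * sqrt(2)), 2)
  # alternative quantile
  z95 <- rep(sqrt(qchisq(0.95, 1)), 200)
  expect_equal(estimate_lambda_gc(z95, quantile = 0.95), 1)
  # standard-normal z at n = 1e5 recovers 1 within 3%
  set.seed(100)
  expect_equal(estimate_lambda_gc(rnorm(1e5)), 1, tolerance = 0.03)
  expect_error(estimate_lambda_gc(numeric(0)), "no intergenic")
  expect_warning(estimate_lambda_gc(rnorm(50)), "only 50")
})

test_that("inflation control divides z by sqrt(lambda) and is a fixed point", {
  z <- c(a = 2, b = -1, c = 0.5)
  adj <- apply_inflation_control(z, 1)
  expect_equal(adj$z_adj, unname(z), ignore_attr = TRUE)
  adj4 <- apply_inflation_control(z, 4)
  expect_equal(adj4$z_adj[1], 1)
  expect_equal(adj4$p_adj, 2 * pnorm(-abs(z) / 2), ignore_attr = TRUE)
  # sign and |z| rank order preserved
  expect_equal(sign(adj4$z_adj), sign(unname(z)))
  expect_equal(order(abs(adj4$z_adj)), order(abs(z)))
  # re-estimating lambda on adjusted intergenic z returns 1 exactly
  set.seed(7)
  zi <- rnorm(5000) * sqrt(1.7)
  lam <- estimate_lambda_gc(zi)
  expect_equal(estimate_lambda_gc(zi / sqrt(lam)), 1, tolerance = 1e-12)
})

test_that("stratified Q-Q curves behave under null, constant, enriched strata", {
  set.seed(12)
  n <- 5000
  ids <- sprintf("s%05d", 1:n)
  enriched <- c(rep(TRUE, 1000), rep(FALSE, n - 1000))
  z <- draw_mixture_z(n, pi1 = ifelse(enriched, 0.3, 0), sigma2 = 9)
  p <- setNames(2 * pnorm(-abs(z)), ids)
  strata <- list(enriched = ids[enriched], null = ids[!enriched], all = ids)
  reps <- list(ids, ids)                     # no pruning needed here
  qq <- stratified_qq(p, strata, reps, n_bins = 200)
  # null stratum hugs the identity line over the well-populated range
  d0 <- qq$curves$null
  lo <- d0$nominal < 2
  expect_lt(max(abs(d0$mean[lo] - d0$nominal[lo])), 0.25)
  # curves are non-decreasing and the band contains the mean
  for (cv in qq$curves) {
    expect_true(all(diff(cv$mean) >= -1e-12))
    expect_true(all(cv$lower <= cv$mean & cv$mean <= cv$upper))
  }
  # enriched stratum deflects above the all-SNP curve
  expect_gt(mean(qq$curves$enriched$mean - qq$curves$all$mean), 0)
  # constant p -> horizontal curve at -log10(p)
  pc <- setNames(rep(1e-4, 50), sprintf("c%02d", 1:50))
  qqc <- stratified_qq(pc, list(const = names(pc)), list(names(pc)),
                       n_bins = 50)
  expect_true(all(qqc$curves$const$mean == 4))
  # a stratum with < 10 pruned SNPs is suppressed with a warning
  expect_warning(qs <- stratified_qq(p, list(tiny = ids[1:5]), reps, 50),
                 "suppressed")
  expect_null(qs$curves$tiny)
})

test_that("Q-Q deflection equals -log10 of the empirical FDR estimate", {
  set.seed(33)
  n <- 20000
  ids <- sprintf("s%05d", 1:n)
  z <- draw_mixture_z(n, 0.1, 16)
  p <- setNames(2 * pnorm(-abs(z)), ids)
  qq <- stratified_qq(p, list(all = ids), list(ids), n_bins = 300)
  d <- qq$curves$all
  fdr <- fdr_estimate(p, monotone = FALSE)
  # compare on grid points whose quantile index is comfortably interior
  sel <- which(10^(-d$nominal) * n >= 100)
  for (k in sel[seq(1, length(sel), by = 25)]) {
    i <- which.min(abs(-log10(p) - d$mean[k]))
    expect_lt(abs((d$mean[k] - d$nominal[k]) - unname(-log10(fdr[i]))), 0.05)
  }
})

test_that("two-proportion z matches hand computation and degenerate rules", {
  x1 <- 30; n1 <- 100; x2 <- 10; n2 <- 100
  pp <- (x1 + x2) / (n1 + n2)
  z_hand <- (x1 / n1 - x2 / n2) / sqrt(pp * (1 - pp) * (1 / n1 + 1 / n2))
  expect_equal(two_proportion_z(x1, n1, x2, n2), z_hand)
  expect_equal(z_hand, 3.5355339, tolerance = 1e-6)
  expect_equal(two_proportion_z(10, 50, 10, 50), 0)    # equal proportions
  expect_equal(two_proportion_z(0, 50, 0, 50), 0)      # degenerate pool
  expect_equal(two_proportion_z(50, 50, 50, 50), 0)
})

test_that("binomial proportion test: equal proportions give z = 0, p = 0.5", {
  set.seed(19)
  ids <- sprintf("s%04d", 1:2000)
  p <- setNames(runif(2000), ids)
  cat_ids <- ids[1:1000]; int_ids <- ids[1001:2000]
  # craft exact equality: use mirrored p-values across the two groups
  p[1001:2000] <- p[1:1000]
  out <- binomial_proportion_test(cat_ids, int_ids, p, list(ids))
  expect_equal(out$statistic, 0)
  expect_equal(out$p.value, 0.5)
})

test_that("binomial proportion test detects a planted enrichment", {
  set.seed(23)
  ids <- sprintf("s%04d", 1:4000)
  z <- c(draw_mixture_z(2000, 0.05, 9), rnorm(2000))
  p <- setNames(2 * pnorm(-abs(z)), ids)
  out <- binomial_proportion_test(ids[1:2000], ids[2001:4000], p, list(ids))
  expect_gt(out$statistic, 2)
  expect_lt(out$p.value, 0.05)
})

test_that("binomial proportion test power at the planted study condition", {
  # category pi1 = 0.05 vs null intergenic, n = 2000 per group
  set.seed(29)
  rej <- replicate(200, {
    ids <- sprintf("s%04d", 1:4000)
    z <- c(draw_mixture_z(2000, 0.05, 9), rnorm(2000))
    p <- setNames(2 * pnorm(-abs(z)), ids)
    binomial_proportion_test(ids[1:2000], ids[2001:4000], p,
                             list(ids))$p.value < 0.05
  })
  expect_gt(mean(rej), 0.8)
})

test_that("enrichment estimate: arithmetic, null, sign invariance, mixture mean", {
  expect_equal(enrichment_estimate(c(2, -2)), 3)
  set.seed(44)
  z <- rnorm(1e5)
  expect_equal(enrichment_estimate(z), 0, tolerance = 0.02)
  expect_equal(enrichment_estimate(z), enrichment_estimate(-z))
  expect_true(is.na(enrichment_estimate(numeric(0))))
  # mixture with non-null fraction pi1 and extra variance sigma2 -> pi1*sigma2
  set.seed(45)
  zm <- draw_mixture_z(1e5, 0.05, 9)
  expect_lt(abs(enrichment_estimate(zm) - 0.45), 3 * sd(zm^2) / sqrt(1e5))
})

test_that("normalisation divides by the per-phenotype maximum", {
  est <- c(UTR5 = 4, miRNA = 2)
  expect_equal(normalize_estimates(est), c(UTR5 = 1, miRNA = 0.5))
  expect_equal(unname(normalize_estimates(c(a = 3))), 1)
  # order preserved
  set.seed(2); e <- runif(5)
  expect_equal(order(normalize_estimates(e)), order(e))
  expect_warning(normalize_estimates(c(a = -1, b = -2)), "skipped")
})

test_that("annotation regression recovers a planted score effect", {
  sim <- small_sim()
  sc <- sim$scores
  set.seed(61)
  # plant: log z^2 responds to the miRNA score only
  z <- rnorm(nrow(sc)) * exp(0.4 * sc$miRNA / 2)
  reg <- annotation_regression(z, sc)
  est <- setNames(reg$estimate, reg$term)
  expect_gt(est[["miRNA"]], 0.2)
  expect_lt(reg$p_one_sided[reg$term == "miRNA"], 1e-4)
  other <- est[c("miRNA_BS", "UTR3", "UTR5", "exon", "intron")]
  expect_true(all(abs(other) < 0.2, na.rm = TRUE))

  # null scores except intercept: slopes ~0, intercept ~ mean log z^2
  sc0 <- sc
  for (cg in c("miRNA", "miRNA_BS", "UTR3", "UTR5", "exon", "intron"))
    sc0[[cg]] <- 0
  sc0$intergenic <- FALSE; sc0$total_ld <- 1
  z0 <- rnorm(nrow(sc0))
  reg0 <- suppressWarnings(annotation_regression(z0, sc0))
  expect_equal(reg0$estimate[reg0$term == "(Intercept)"], mean(log(z0^2)),
               tolerance = 1e-8)
})

test_that("collinear design columns are dropped without changing the fit", {
  sim <- small_sim()
  sc <- sim$scores
  set.seed(71)
  z <- rnorm(nrow(sc))
  sc_dup <- sc
  sc_dup$UTR3 <- sc_dup$miRNA            # duplicate column
  expect_warning(reg <- annotation_regression(z, sc_dup), "collinear")
  expect_false("UTR3" %in% reg$term)
  # fit identical to the model without the duplicated column
  ref <- lm(log(pmax(z^2, 1e-12)) ~ miRNA + miRNA_BS + UTR5 + exon + intron +
              intergenic + total_ld,
            data = transform(sc[, c("miRNA", "miRNA_BS", "UTR5", "exon",
                                    "intron", "total_ld")],
                             intergenic = as.numeric(sc$intergenic)))
  expect_equal(setNames(reg$estimate, reg$term)[names(coef(ref))],
               coef(ref), tolerance = 1e-10)
})
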