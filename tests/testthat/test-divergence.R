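test_that("log2 fold change is symmetric, non-negative, scale-invariant", {
  expect_equal(log2_fold_change(4, 1), 2)
  expect_equal(log2_fold_change(7.3, 7.3), 0)
  expect_equal(log2_fold_change(5, 2), log2(2.5), tolerance = 1e-9)
  set.seed(2)
  for (i in 1:20) {
    a <- rlnorm(1); b <- rlnorm(1); k <- rlnorm(1)
    expect_equal(log2_fold_change(a, b), log2_fold_change(b, a))
    expect_equal(log2_fold_change(a, b), log2_fold_change(k * a, k * b),
                 tolerance = 1e-12)
  }
  expect_error(log2_fold_change(-1, 2), "positive")
})

test_that("divergence ratio D measures transcription bias", {
  expect_equal(divergence_ratio(4, 1, 3, 3), 2)
  expect_equal(divergence_ratio(4, 1, 1, 4), 0)
  expect_equal(divergence_ratio(2, 1, 4, 1), -1)
})

test_that("records carry consistent absolute/signed fold changes", {
  rec <- fixture_records()
  expect_equal(nrow(rec), 65)
  expect_equal(rec$fc_bm, abs(rec$sfc_bm))
  expect_equal(rec$D, rec$fc_bm - rec$fc_bp)
  # protein fold change is the sum of the rate fold changes (constant
  # decay cancels from the ratio)
  expect_equal(rec$sfc_p, rec$sfc_bm + rec$sfc_bp, tolerance = 1e-12)
  expect_equal(rec$fc_p, abs(rec$sfc_bm + rec$sfc_bp), tolerance = 1e-12)
})

test_that("gene-specific decay changes transcription-rate records only", {
  pp <- fixture_pairs()
  rec0 <- divergence_records(pp$genes, pp$pairs)
  rec1 <- divergence_records(pp$genes, pp$pairs, use_gene_decay = TRUE)
  expect_equal(rec1$fc_bp, rec0$fc_bp)
  expect_false(isTRUE(all.equal(rec1$fc_bm, rec0$fc_bm)))
  # beta_m recomputation: m * alpha_m_gene
  g <- pp$genes
  i1 <- match(pp$pairs$gene1, g$id)
  expect_equal(rec1$bm1, (g$beta_m[i1] / 5.10) * g$alpha_m[i1],
               tolerance = 1e-12)
})

test_that("orientation duplication doubles rows antisymmetrically", {
  rec <- fixture_records()
  dup <- signed_fold_changes(rec)
  expect_equal(nrow(dup), 2 * nrow(rec))
  expect_equal(mean(dup$sfc_bm), 0)
  expect_equal(mean(dup$sfc_bp), 0)
  one <- signed_fold_changes(data.frame(sfc_bm = 0.7, sfc_bp = -0.2))
  expect_equal(one$sfc_bm, c(0.7, -0.7))
  expect_equal(one$sfc_bp, c(-0.2, 0.2))
})

test_that("divergence correlations behave at the edges", {
  # perfectly proportional magnitudes
  rec <- data.frame(fc_bm = c(1, 2, 3, 4), fc_bp = c(2, 4, 6, 8),
                    sfc_bm = c(1, -2, 3, -4), sfc_bp = c(2, -4, 6, -8))
  res <- divergence_correlations(rec, n_boot = 50, seed = 1)
  expect_equal(res$abs$rho, 1)
  expect_error(divergence_correlations(rec[1:2, ]), "3 pairs")
  # constant column flagged
  recc <- data.frame(fc_bm = c(1, 1, 1), fc_bp = c(1, 2, 3),
                     sfc_bm = c(1, 1, 1), sfc_bp = c(1, 2, 3))
  expect_match(divergence_correlations(recc, n_boot = 10)$abs$flag,
               "constant")
})

test_that("signed correlation is invariant to gene1/gene2 labeling", {
  rec <- fixture_records()
  set.seed(8)
  flip <- sample(c(TRUE, FALSE), nrow(rec), replace = TRUE)
  rec2 <- rec
  rec2$sfc_bm[flip] <- -rec$sfc_bm[flip]
  rec2$sfc_bp[flip] <- -rec$sfc_bp[flip]
  d1 <- signed_fold_changes(rec); d2 <- signed_fold_changes(rec2)
  expect_equal(spearman_safe(d1$sfc_bm, d1$sfc_bp),
               spearman_safe(d2$sfc_bm, d2$sfc_bp), tolerance = 1e-12)
})

test_that("correlation estimate recovers a generator-defined rank correlation", {
  # pairs whose signed log fold changes have known Pearson correlation
  # 0.5, hence Spearman 6/pi * asin(0.25)
  set.seed(11)
  n <- 2000
  z1 <- rnorm(n); z2 <- rnorm(n)
  rec <- data.frame(sfc_bm = 2 * z1,
                    sfc_bp = 0.5 * z1 + sqrt(1 - 0.25) * z2)
  rec$fc_bm <- abs(rec$sfc_bm); rec$fc_bp <- abs(rec$sfc_bp)
  res <- divergence_correlations(rec, n_boot = 500, seed = 3)
  truth <- (6 / pi) * asin(0.25)
  expect_gt(truth, res$signed$ci_low)
  expect_lt(truth, res$signed$ci_high)
})

test_that("bootstrap CI coverage is near nominal on synthetic data", {
  set.seed(21)
  truth <- (6 / pi) * asin(0.25)
  hits <- 0L
  reps <- 150L
  for (r in seq_len(reps)) {
    n <- 150
    z1 <- rnorm(n); z2 <- rnorm(n)
    rec <- data.frame(sfc_bm = z1, sfc_bp = 0.5 * z1 + sqrt(0.75) * z2)
    rec$fc_bm <- abs(rec$sfc_bm); rec$fc_bp <- abs(rec$sfc_bp)
    res <- divergence_correlations(rec, n_boot = 300)
    if (truth >= res$signed$ci_low && truth <= res$signed$ci_high)
      hits <- hits + 1L
  }
  coverage <- hits / reps
  expect_gte(coverage, 0.90)
  expect_lte(coverage, 0.99)
})

test_that("Mood's median test uses the grand-median 2x2 chi-square", {
  x <- c(1, 2, 3, 10, 11); y <- c(4, 5, 6, 7, 8)
  res <- mood_median_test(x, y)
  gm <- median(c(x, y))
  expect_equal(res$table["x", "above"], sum(x > gm))
  # hand-computed chi-square without continuity correction
  tab <- res$table
  expd <- outer(rowSums(tab), colSums(tab)) / sum(tab)
  expect_equal(res$statistic, sum((tab - expd)^2 / expd), tolerance = 1e-12)
  # values tied with the grand median count as "not above"
  res2 <- mood_median_test(c(5, 5, 5, 9), c(5, 1, 1, 1))
  expect_equal(unname(res2$table["x", "above"]), 1L)
  # degenerate: everything tied
  expect_equal(mood_median_test(rep(2, 5), rep(2, 5))$p_value, 1)
})

test_that("distribution comparison trio behaves at the extremes", {
  x <- c(1, 2, 3, 4, 5)
  res <- compare_distributions(x, x)
  expect_equal(res$ks_stat, 0)
  res2 <- compare_distributions(1:50, 101:150)
  expect_equal(res2$ks_stat, 1)
  expect_lt(res2$mww_p, 1e-6)
  expect_error(compare_distributions(numeric(0), 1:3), "non-empty")
})

test_that("MWW p-values are uniform under the null", {
  set.seed(31)
  ps <- replicate(200, {
    compare_distributions(rnorm(500), rnorm(500))$mww_p
  })
  # calibration: p-values indistinguishable from uniform at alpha 0.01
  expect_gt(suppressWarnings(ks.test(ps, "punif"))$p.value, 0.01)
})

test_that("analyze_divergence summarises medians, bias and tests", {
  pp <- fixture_pairs()
  res <- analyze_divergence(pp$genes, pp$pairs, n_boot = 100, seed = 2)
  s <- res$summary
  expect_equal(s$n_pairs, 65)
  expect_equal(s$median_ratio, s$median_fc_bm / s$median_fc_bp)
  expect_true(all(c("WGD", "SSD") %in% names(s$by_type)))
  expect_equal(s$by_type$WGD$n + s$by_type$SSD$n, 65)
  expect_true(s$frac_transcription_biased > 0.5)  # generator is
  # transcription-dominant (sd 2.29 vs 1.11)
})
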