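#' Magnitude of relative divergence as a log2 fold change
#'
#' `log2(max(theta1, theta2) / min(theta1, theta2))`: symmetric in its
#' arguments, non-negative, and invariant to rescaling both values by a
#' common factor.
#'
#' @param theta1,theta2 Strictly positive trait values (vectorised).
#' @return Non-negative log2 fold change(s).
#' @examples
#' log2_fold_change(4, 1)   # 2
#' log2_fold_change(2, 5)   # log2(2.5)
#' @export
log2_fold_change <- function(theta1, theta2) {
  stopifnot_positive(theta1 = theta1, theta2 = theta2)
  abs(log2(theta1 / theta2))
}

#' Divergence ratio: bias towards transcriptional change
#'
#' `D = log2((max(beta_m)/min(beta_m)) / (max(beta_p)/min(beta_p)))`,
#' i.e. the transcriptional minus the translational log2 fold change.
#' `D > 0` marks a pair whose divergence is transcription-biased.
#'
#' @param bm1,bm2 Transcription rates of the two paralogs.
#' @param bp1,bp2 Translation rates of the two paralogs.
#' @return Signed divergence ratio in log2 units.
#' @export
divergence_ratio <- function(bm1, bm2, bp1, bp2) {
  log2_fold_change(bm1, bm2) - log2_fold_change(bp1, bp2)
}

#' Per-pair divergence records from gene and pair tables
#'
#' Joins each paralog pair to its members' rates and computes the absolute
#' (`fc_*`) and signed (`sfc_*`, orientation gene1 over gene2) log2 fold
#' changes in transcription rate, translation rate and steady-state protein
#' abundance, plus the divergence ratio `D`.  When `use_gene_decay` is
#' TRUE, transcription rates are recomputed with gene-specific mRNA decay:
#' the stored `beta_m` (inferred under the median decay constant) is
#' converted back to mRNA abundance and multiplied by the gene's own
#' `alpha_m`; protein abundances then use the gene-specific decay rates
#' where available.
#'
#' @param gene_table Gene table (see [read_gene_table()]).
#' @param pair_table Pair table (see [read_pair_table()]).
#' @param constants A [rate_constants()] object.
#' @param use_gene_decay Recompute `beta_m` (and `p`) with the table's
#'   gene-specific decay columns.
#' @return A data.frame with one row per pair: `pair`, `gene1`, `gene2`,
#'   `dup_type`, `bm1`, `bm2`, `bp1`, `bp2`, `fc_bm`, `fc_bp`, `fc_p`,
#'   `sfc_bm`, `sfc_bp`, `sfc_p`, `D`.
#' @export
divergence_records <- function(gene_table, pair_table,
                               constants = rate_constants(),
                               use_gene_decay = FALSE) {
  gene_table <- validate_gene_table(gene_table)
  pair_table <- validate_pair_table(pair_table)
  idx1 <- match(pair_table$gene1, gene_table$id)
  idx2 <- match(pair_table$gene2, gene_table$id)
  if (anyNA(idx1) || anyNA(idx2))
    stop("pair table references gene ids absent from the gene table")

  pick <- function(col, idx) {
    if (col %in% names(gene_table)) gene_table[[col]][idx] else rep(NA_real_, length(idx))
  }
  bm1 <- pick("beta_m", idx1); bm2 <- pick("beta_m", idx2)
  bp1 <- pick("beta_p", idx1); bp2 <- pick("beta_p", idx2)
  am1 <- pick("alpha_m", idx1); am2 <- pick("alpha_m", idx2)
  if (anyNA(c(bm1, bm2, bp1, bp2)))
    stop("missing member rates for at least one pair")

  if (use_gene_decay) {
    if (anyNA(c(am1, am2)))
      stop("use_gene_decay = TRUE requires alpha_m for every pair member")
    # stored beta_m assumes the median decay constant; recover m and redo
    bm1 <- (bm1 / constants$alpha_m) * am1
    bm2 <- (bm2 / constants$alpha_m) * am2
  }
  # protein abundance for fold changes follows the steady-state relation
  # with median decay constants (gene-specific protein decay enters only
  # the abundance-validation procedure)
  p1 <- protein_abundance(bm1, bp1, constants$alpha_m, constants$alpha_p)
  p2 <- protein_abundance(bm2, bp2, constants$alpha_m, constants$alpha_p)

  sfc_bm <- log2(bm1 / bm2)
  sfc_bp <- log2(bp1 / bp2)
  sfc_p  <- log2(p1 / p2)
  data.frame(
    pair = seq_len(nrow(pair_table)),
    gene1 = pair_table$gene1, gene2 = pair_table$gene2,
    dup_type = pair_table$dup_type,
    bm1 = bm1, bm2 = bm2, bp1 = bp1, bp2 = bp2,
    fc_bm = abs(sfc_bm), fc_bp = abs(sfc_bp), fc_p = abs(sfc_p),
    sfc_bm = sfc_bm, sfc_bp = sfc_bp, sfc_p = sfc_p,
    D = abs(sfc_bm) - abs(sfc_bp),
    stringsAsFactors = FALSE
  )
}

#' Orientation-duplicated signed fold changes
#'
#' The orientation of a pair (which member is "gene1") is arbitrary, so
#' signed fold changes are computed in both orientations and stacked: each
#' of the `n` input pairs contributes rows `(x, y)` and `(-x, -y)`.  The
#' per-column mean of the result is exactly zero by construction.
#'
#' @param records Divergence records from [divergence_records()], or any
#'   data.frame with columns `sfc_bm` and `sfc_bp` (optionally `sfc_p`,
#'   `pair`).
#' @return A data.frame with `2n` rows: `pair`, `orientation` (1 or 2),
#'   `sfc_bm`, `sfc_bp` and, if present in the input, `sfc_p`.
#' @export
signed_fold_changes <- function(records) {
  if (!all(c("sfc_bm", "sfc_bp") %in% names(records)))
    stop("records must carry signed fold-change columns sfc_bm, sfc_bp")
  if (anyNA(records$sfc_bm) || anyNA(records$sfc_bp))
    stop("missing member rates: signed fold changes contain NA")
  pair <- records$pair %||% seq_len(nrow(records))
  out <- data.frame(
    pair = c(pair, pair),
    orientation = rep(1:2, each = nrow(records)),
    sfc_bm = c(records$sfc_bm, -records$sfc_bm),
    sfc_bp = c(records$sfc_bp, -records$sfc_bp)
  )
  if ("sfc_p" %in% names(records))
    out$sfc_p <- c(records$sfc_p, -records$sfc_p)
  out
}

cor_result <- function(rho, p_value, ci, n, flag = NA_character_) {
  structure(list(rho = rho, p_value = p_value,
                 ci_low = ci[1], ci_high = ci[2], n = n, flag = flag),
            class = "cor_result")
}

#' @export
print.cor_result <- function(x, ...) {
  cat(sprintf("Spearman rho = %.3f  [%.3f, %.3f]  (n = %d, p = %.3g)%s\n",
              x$rho, x$ci_low, x$ci_high, x$n, x$p_value,
              if (!is.na(x$flag)) paste0("  <", x$flag, ">") else ""))
  invisible(x)
}

spearman_safe <- function(x, y) {
  if (stats::sd(x) == 0 || stats::sd(y) == 0) return(NA_real_)
  stats::cor(x, y, method = "spearman")
}

#' Divergence correlations with bootstrap confidence intervals
#'
#' Two Spearman correlations between transcriptional and translational
#' divergence: (i) between the magnitudes `fc_bm` and `fc_bp` over the `n`
#' pairs, and (ii) between the signed fold changes over the
#' orientation-duplicated `2n` rows.  Percentile 95% confidence intervals
#' come from resampling *pairs* with replacement (`n_boot` times) and, for
#' the signed case, re-duplicating orientations of each resampled pair, so
#' the dependence between the two orientations of one pair is respected.
#' The p-value reported for the signed correlation is computed on the
#' duplicated dataset (nominal `n = 2n`) and is therefore anti-conservative
#' with respect to the `n` independent pairs; `n` is reported alongside so
#' the caveat is visible.
#'
#' @param records Divergence records ([divergence_records()]), at least 3
#'   rows.
#' @param n_boot Number of bootstrap resamples (default 10 000).
#' @param conf Confidence level (default 0.95).
#' @param seed Optional integer seed for the bootstrap.
#' @return A list with elements `abs` and `signed`, each a `cor_result`
#'   with `rho`, `p_value`, `ci_low`, `ci_high`, `n` (and a `flag` when a
#'   column is constant and rho undefined).
#' @export
divergence_correlations <- function(records, n_boot = 10000, conf = 0.95,
                                    seed = NULL) {
  n <- nrow(records)
  if (n < 3)
    stop("at least 3 pairs are required")
  if (!is.null(seed)) set.seed(seed)
  alpha <- (1 - conf) / 2

  rho_abs <- spearman_safe(records$fc_bm, records$fc_bp)
  dup <- signed_fold_changes(records)
  rho_sgn <- spearman_safe(dup$sfc_bm, dup$sfc_bp)

  if (is.na(rho_abs) || is.na(rho_sgn)) {
    flag <- "constant column: rho undefined"
    res <- cor_result(NA_real_, NA_real_, c(NA_real_, NA_real_), n, flag)
    return(list(abs = res, signed = res))
  }

  p_abs <- suppressWarnings(
    stats::cor.test(records$fc_bm, records$fc_bp, method = "spearman"))$p.value
  p_sgn <- suppressWarnings(
    stats::cor.test(dup$sfc_bm, dup$sfc_bp, method = "spearman"))$p.value

  boot_abs <- numeric(n_boot)
  boot_sgn <- numeric(n_boot)
  x <- records$fc_bm; y <- records$fc_bp
  sx <- records$sfc_bm; sy <- records$sfc_bp
  for (b in seq_len(n_boot)) {
    idx <- sample.int(n, n, replace = TRUE)
    boot_abs[b] <- spearman_safe(x[idx], y[idx])
    boot_sgn[b] <- spearman_safe(c(sx[idx], -sx[idx]), c(sy[idx], -sy[idx]))
  }
  qs <- function(v) stats::quantile(v, c(alpha, 1 - alpha), na.rm = TRUE,
                                    names = FALSE)
  list(
    abs    = cor_result(rho_abs, p_abs, qs(boot_abs), n),
    signed = cor_result(rho_sgn, p_sgn, qs(boot_sgn), 2L * n)
  )
}

#' Mood's median test (grand-median two-sample test)
#'
#' Classifies each observation as above or not above the pooled grand
#' median (ties with the median count as "not above") and tests the
#' resulting 2 x 2 table with a chi-square statistic without continuity
#' correction.
#'
#' @param x,y Non-empty numeric samples.
#' @return A list with `statistic`, `p_value` and the 2 x 2 `table`.
#' @export
mood_median_test <- function(x, y) {
  if (length(x) == 0 || length(y) == 0)
    stop("both samples must be non-empty")
  gm <- stats::median(c(x, y))
  tab <- rbind(x = c(above = sum(x > gm), not_above = sum(x <= gm)),
               y = c(above = sum(y > gm), not_above = sum(y <= gm)))
  rs <- rowSums(tab); csum <- colSums(tab); tot <- sum(tab)
  expected <- outer(rs, csum) / tot
  if (any(expected == 0)) {
    # degenerate split (e.g. all values tied at the median): no evidence
    return(list(statistic = 0, p_value = 1, table = tab))
  }
  stat <- sum((tab - expected)^2 / expected)
  list(statistic = stat,
       p_value = stats::pchisq(stat, df = 1, lower.tail = FALSE),
       table = tab)
}

#' Two-sample distribution comparisons
#'
#' The trio of tests used to compare divergence distributions: a two-sided
#' Mann-Whitney-Wilcoxon test, Mood's median test (grand-median 2 x 2
#' chi-square) and the two-sample Kolmogorov-Smirnov test, whose statistic
#' is the largest absolute difference between the two empirical CDFs.
#'
#' @param x,y Non-empty numeric samples.
#' @return A list with `mww_p`, `mood_p`, `ks_stat`, `ks_p`.
#' @export
compare_distributions <- function(x, y) {
  if (length(x) == 0 || length(y) == 0)
    stop("both samples must be non-empty")
  mww <- suppressWarnings(stats::wilcox.test(x, y, alternative = "two.sided",
                                             exact = FALSE))
  ks <- suppressWarnings(stats::ks.test(x, y))
  list(mww_p = mww$p.value,
       mood_p = mood_median_test(x, y)$p_value,
       ks_stat = unname(ks$statistic),
       ks_p = ks$p.value)
}

#' Full divergence analysis of a gene/pair table
#'
#' Convenience wrapper producing the per-pair records, the summary
#' statistics of transcriptional vs translational divergence (medians and
#' their ratio, fraction of transcription-biased pairs, the
#' Mann-Whitney-Wilcoxon / Mood / KS comparison of the two fold-change
#' distributions) and both divergence correlations with bootstrap CIs.
#'
#' @inheritParams divergence_records
#' @param n_boot Bootstrap resamples for the correlation CIs.
#' @param seed Optional seed for the bootstrap.
#' @param by_type Also compute medians separately for WGD and SSD pairs.
#' @return A list with `records` (data.frame) and `summary` (list).
#' @export
analyze_divergence <- function(gene_table, pair_table,
                               constants = rate_constants(),
                               use_gene_decay = FALSE,
                               n_boot = 10000, seed = NULL, by_type = TRUE) {
  rec <- divergence_records(gene_table, pair_table, constants, use_gene_decay)
  cors <- divergence_correlations(rec, n_boot = n_boot, seed = seed)
  cmp <- compare_distributions(rec$fc_bm, rec$fc_bp)
  summary <- list(
    n_pairs = nrow(rec),
    median_fc_bm = stats::median(rec$fc_bm),
    median_fc_bp = stats::median(rec$fc_bp),
    median_ratio = stats::median(rec$fc_bm) / stats::median(rec$fc_bp),
    sd_sfc_bm = stats::sd(rec$sfc_bm),
    sd_sfc_bp = stats::sd(rec$sfc_bp),
    frac_transcription_biased = mean(rec$D > 0),
    tests = cmp,
    correlations = cors
  )
  if (by_type) {
    summary$by_type <- lapply(split(rec, rec$dup_type), function(r) {
      list(n = nrow(r),
           median_fc_bm = stats::median(r$fc_bm),
           median_fc_bp = stats::median(r$fc_bp),
           median_ratio = stats::median(r$fc_bm) / stats::median(r$fc_bp),
           frac_transcription_biased = mean(r$D > 0),
           mww_p = suppressWarnings(
             stats::wilcox.test(r$fc_bm, r$fc_bp, exact = FALSE))$p.value)
    })
  }
  list(records = rec, summary = summary)
}
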