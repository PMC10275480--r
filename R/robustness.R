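#' Configuration for measurement-noise divergence simulations
#'
#' @param n_pairs Number of simulated gene pairs.
#' @param sigma_dbm,sigma_dbp SDs of the true signed log2 fold-change
#'   distributions for transcription and translation (log2 units).
#' @param cv_bm,cv_bp Relative measurement-error SDs for the mRNA and
#'   footprint measurements (fractions in `[0, 1)`).
#' @param decay_dataset Optional decay table (e.g. from
#'   [generate_decay_dataset()]) with columns `alpha_m` and
#'   `dlog2_alpha_m`; when present, true mRNA abundances use sampled
#'   gene-specific decay while apparent rates assume the constant median
#'   decay.
#' @param seed Integer seed.
#' @param constants A [rate_constants()] object.
#' @return A `noise_sim_config` list.
#' @export
noise_sim_config <- function(n_pairs = 10000, sigma_dbm = 2.29,
                             sigma_dbp = 1.11, cv_bm = 0.2, cv_bp = 0.2,
                             decay_dataset = NULL, seed = 1L,
                             constants = rate_constants()) {
  stopifnot_positive(n_pairs = n_pairs)
  if (sigma_dbm < 0 || sigma_dbp < 0) stop("fold-change SDs must be >= 0")
  if (cv_bm < 0 || cv_bm >= 1 || cv_bp < 0 || cv_bp >= 1)
    stop("cv values must lie in [0, 1)")
  structure(list(n_pairs = as.integer(n_pairs), sigma_dbm = sigma_dbm,
                 sigma_dbp = sigma_dbp, cv_bm = cv_bm, cv_bp = cv_bp,
                 decay_dataset = decay_dataset, seed = as.integer(seed),
                 constants = constants),
            class = "noise_sim_config")
}

# Gaussian relative noise, redrawing any draw that would make the
# measurement non-positive (truncation keeps rates positive)
relative_noise <- function(x, cv) {
  if (cv == 0) return(x)
  out <- x * (1 + stats::rnorm(length(x), 0, cv))
  bad <- which(out <= 0)
  while (length(bad)) {
    out[bad] <- x[bad] * (1 + stats::rnorm(length(bad), 0, cv))
    bad <- bad[out[bad] <= 0]
  }
  out
}

#' Simulate the impact of measurement noise on divergence estimates
#'
#' Builds gene pairs with known true fold changes, converts them to
#' exact mRNA (`m`) and footprint (`s = beta_p m`) measurements, adds
#' independent Gaussian relative noise to both, recomputes "apparent"
#' rates the way the measurement pipeline would (`beta_m` proportional
#' to noisy `m`; `beta_p` to noisy `s/m`), and compares apparent to true
#' fold-change magnitudes.  Because apparent translation rates compound
#' the noise of both measurements, noise typically deflates the
#' apparent transcription/translation divergence ratio.  With a decay
#' dataset in the config, true abundances use gene-specific mRNA decay
#' (with within-pair decay fold changes) while apparent rates assume the
#' median constant, adding the bias from unmodeled decay variation.
#'
#' @param cfg A [noise_sim_config()].
#' @param rate_pool Gene table supplying paralog-1 rates (sampled with
#'   replacement).
#' @return A list: `true_ratio` and `apparent_ratio` (median fc_bm /
#'   median fc_bp), and `pairs`, a data.frame of per-pair true and
#'   apparent fold changes.
#' @export
simulate_noisy_divergence <- function(cfg, rate_pool) {
  if (nrow(rate_pool) < 1) stop("empty rate pool")
  cs <- cfg$constants
  set.seed(cfg$seed)
  n <- cfg$n_pairs
  i <- sample.int(nrow(rate_pool), n, replace = TRUE)
  bm1 <- rate_pool$beta_m[i]
  bp1 <- rate_pool$beta_p[i]
  d_bm <- stats::rnorm(n, 0, cfg$sigma_dbm)
  d_bp <- stats::rnorm(n, 0, cfg$sigma_dbp)
  bm2 <- bm1 * 2^d_bm
  bp2 <- bp1 * 2^d_bp

  if (is.null(cfg$decay_dataset)) {
    m1 <- bm1 / cs$alpha_m; m2 <- bm2 / cs$alpha_m
  } else {
    dd <- cfg$decay_dataset
    j <- sample.int(nrow(dd), n, replace = TRUE)
    jf <- sample.int(nrow(dd), n, replace = TRUE)
    am1 <- dd$alpha_m[j]
    am2 <- am1 * 2^dd$dlog2_alpha_m[jf]
    m1 <- bm1 / am1; m2 <- bm2 / am2
  }
  s1 <- bp1 * m1; s2 <- bp2 * m2

  noiseless <- cfg$cv_bm == 0 && cfg$cv_bp == 0
  if (noiseless && is.null(cfg$decay_dataset)) {
    # exact measurements, constant decay: the apparent fold changes are
    # the true ones by construction
    pairs <- data.frame(
      true_fc_bm = abs(d_bm), true_fc_bp = abs(d_bp),
      app_fc_bm = abs(d_bm), app_fc_bp = abs(d_bp))
  } else {
    m1n <- relative_noise(m1, cfg$cv_bm); m2n <- relative_noise(m2, cfg$cv_bm)
    s1n <- relative_noise(s1, cfg$cv_bp); s2n <- relative_noise(s2, cfg$cv_bp)

    # apparent rates under the constant-decay assumption; shared constants
    # cancel from within-pair fold changes
    app_bm1 <- m1n * cs$alpha_m; app_bm2 <- m2n * cs$alpha_m
    app_bp1 <- s1n / m1n;        app_bp2 <- s2n / m2n

    pairs <- data.frame(
      true_fc_bm = abs(d_bm), true_fc_bp = abs(d_bp),
      app_fc_bm = abs(log2(app_bm1 / app_bm2)),
      app_fc_bp = abs(log2(app_bp1 / app_bp2))
    )
  }
  list(
    true_ratio = stats::median(pairs$true_fc_bm) /
      stats::median(pairs$true_fc_bp),
    apparent_ratio = stats::median(pairs$app_fc_bm) /
      stats::median(pairs$app_fc_bp),
    pairs = pairs
  )
}

#' Grid of apparent vs true divergence ratios over noise levels
#'
#' Runs [simulate_noisy_divergence()] over a grid of measurement-noise
#' levels and true divergence scenarios.
#'
#' @param cv_grid Noise levels applied to both measurements (default
#'   `c(0, 0.1, 0.2, 0.3)`).
#' @param sigma_pairs List of `c(sigma_dbm, sigma_dbp)` scenarios;
#'   defaults to transcription-dominant, translation-dominant and
#'   equal-contribution (same total variance) truths.
#' @param rate_pool Gene table for paralog-1 sampling.
#' @param n_pairs Pairs per cell.
#' @param seed Integer seed.
#' @param decay_dataset Optional decay table (see [noise_sim_config()]).
#' @return data.frame with `cv_bm`, `cv_bp`, `sigma_dbm`, `sigma_dbp`,
#'   `true_ratio`, `apparent_ratio`.
#' @export
noise_ratio_grid <- function(cv_grid = c(0, 0.1, 0.2, 0.3),
                             sigma_pairs = NULL, rate_pool,
                             n_pairs = 10000, seed = 1L,
                             decay_dataset = NULL) {
  if (is.null(sigma_pairs)) {
    eq <- sqrt((2.29^2 + 1.11^2) / 2)
    sigma_pairs <- list(c(2.29, 1.11), c(1.11, 2.29), c(eq, eq))
  }
  rows <- list()
  for (sp in sigma_pairs) for (cv in cv_grid) {
    cfg <- noise_sim_config(n_pairs = n_pairs, sigma_dbm = sp[1],
                            sigma_dbp = sp[2], cv_bm = cv, cv_bp = cv,
                            decay_dataset = decay_dataset, seed = seed)
    res <- simulate_noisy_divergence(cfg, rate_pool)
    rows[[length(rows) + 1L]] <- data.frame(
      cv_bm = cv, cv_bp = cv, sigma_dbm = sp[1], sigma_dbp = sp[2],
      true_ratio = res$true_ratio, apparent_ratio = res$apparent_ratio)
  }
  do.call(rbind, rows)
}

#' Null divergence correlations from the shared-mRNA construction
#'
#' Because translation rates are computed as footprints over mRNA, the
#' mRNA measurement enters both pseudo-rates; this simulation quantifies
#' the divergence correlations expected from that construction alone,
#' with no evolutionary signal.  Per paralog, `(m, s)` are drawn from a
#' bivariate distribution with correlation `r_ms` (log scale by
#' default, so pseudo-rates stay positive; `scale = "linear"` available
#' for comparison), pseudo-rates are set to `beta_m = m`,
#' `beta_p = s/m`, and both divergence correlations computed over `n`
#' pairs.
#'
#' @param n Number of pairs (>= 10).
#' @param r_ms Correlation between the two measurements, in `[-1, 1]`.
#' @param sdlog_m,sdlog_s Log-scale SDs of the two measurements (equal
#'   by default, the symmetric choice).
#' @param scale `"log"` (default) or `"linear"` sampling.
#' @param seed Integer seed.
#' @return A list with `rho_abs`, `rho_signed` (Spearman, the signed one
#'   on the orientation-duplicated rows) and `flag` (non-NA when the
#'   pseudo-translation fold changes degenerate, e.g. `r_ms = 1` with
#'   equal spreads).
#' @export
spurious_correlation_null <- function(n = 10000, r_ms = 0,
                                      sdlog_m = 1.2, sdlog_s = 1.2,
                                      scale = c("log", "linear"),
                                      seed = 1L) {
  if (n < 10) stop("n must be at least 10")
  if (abs(r_ms) > 1) stop("r_ms must lie in [-1, 1]")
  scale <- match.arg(scale)
  set.seed(seed)
  draw <- function() {
    z1 <- stats::rnorm(n); z2 <- stats::rnorm(n)
    lm_ <- sdlog_m * z1
    ls_ <- sdlog_s * (r_ms * z1 + sqrt(1 - r_ms^2) * z2)
    if (scale == "log") {
      list(m = exp(lm_), s = exp(ls_))
    } else {
      # linear-scale normal draws, shifted well away from zero
      list(m = pmax(1e-9, 5 + lm_), s = pmax(1e-9, 5 + ls_))
    }
  }
  g1 <- draw(); g2 <- draw()
  x <- log2(g1$m / g2$m)                      # pseudo beta_m fold change
  y <- log2((g1$s / g1$m) / (g2$s / g2$m))    # pseudo beta_p fold change
  flag <- NA_character_
  if (stats::sd(y) < 1e-8 || stats::sd(x) < 1e-8) {
    return(list(rho_abs = NA_real_, rho_signed = NA_real_,
                flag = "degenerate pseudo fold changes"))
  }
  rho_abs <- stats::cor(abs(x), abs(y), method = "spearman")
  rho_signed <- stats::cor(c(x, -x), c(y, -y), method = "spearman")
  list(rho_abs = rho_abs, rho_signed = rho_signed, flag = flag)
}

#' Validate translation rates against measured protein abundances
#'
#' Correlates protein-abundance log2 fold changes estimated from the
#' rate table (`p = m beta_p / alpha_p`, gene-specific protein decay
#' where available) with fold changes from an independent measured
#' abundance dataset, and situates the observed Pearson correlation in
#' a null distribution obtained by shuffling the translation rates
#' across genes.
#'
#' @param gene_table Gene table (needs `beta_m`, `beta_p`; `alpha_p`
#'   optional).
#' @param pair_table Pair table.
#' @param abundance Data.frame with `id`, `p_measured` (e.g. from
#'   [generate_protein_abundance_dataset()]).
#' @param n_shuffles Number of shuffles for the null (default 10 000).
#' @param seed Integer seed.
#' @param constants A [rate_constants()] object.
#' @return A list: `r_obs`, `null_quantile` (empirical quantile of
#'   `r_obs` in the null), `null` (the null correlations), `n_pairs`.
#' @export
protein_fc_validation <- function(gene_table, pair_table, abundance,
                                  n_shuffles = 10000, seed = 1L,
                                  constants = rate_constants()) {
  set.seed(seed)
  gene_table <- validate_gene_table(gene_table)
  pair_table <- validate_pair_table(pair_table)
  i1 <- match(pair_table$gene1, gene_table$id)
  i2 <- match(pair_table$gene2, gene_table$id)
  j1 <- match(pair_table$gene1, abundance$id)
  j2 <- match(pair_table$gene2, abundance$id)
  ok <- !is.na(i1) & !is.na(i2) & !is.na(j1) & !is.na(j2)
  if (sum(ok) < 10)
    stop("fewer than 10 pairs with complete rate and abundance data")
  i1 <- i1[ok]; i2 <- i2[ok]; j1 <- j1[ok]; j2 <- j2[ok]

  ap <- gene_table$alpha_p %||% rep(constants$alpha_p, nrow(gene_table))
  ap[is.na(ap)] <- constants$alpha_p
  m <- if ("m" %in% names(gene_table) && !anyNA(gene_table$m))
    gene_table$m else gene_table$beta_m / constants$alpha_m
  est_fc <- function(bp) {
    p <- m * bp / ap
    log2(p[i1] / p[i2])
  }
  obs_fc <- log2(abundance$p_measured[j1] / abundance$p_measured[j2])
  r_obs <- stats::cor(est_fc(gene_table$beta_p), obs_fc)

  null <- vapply(seq_len(n_shuffles), function(b) {
    stats::cor(est_fc(sample(gene_table$beta_p)), obs_fc)
  }, numeric(1))
  list(r_obs = r_obs, null_quantile = mean(null < r_obs), null = null,
       n_pairs = length(i1))
}
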