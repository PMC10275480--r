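#' Specification for synthetic yeast-like expression data
#'
#' Collects the parameters of the synthetic-data generators.  Defaults
#' emulate the statistical structure of the genome-wide budding-yeast
#' rate dataset the analyses assume: 4440 genes with log-normal rate
#' marginals whose implied transcriptome (~54 000 transcripts) and
#' proteome (~1e8 proteins) sizes match the cellular totals, a
#' near-perfect correlation (0.981) between log mRNA and log footprint
#' abundances, 245 whole-genome-duplication and 164 small-scale
#' duplication pairs whose signed log2 fold changes have standard
#' deviations 2.29 (transcription) and 1.11 (translation), and
#' gene-specific decay rates varying log-normally around the medians
#' (5.10 and 1.34 per hour).
#'
#' @param n_genes Number of genes (default 4440).
#' @param meanlog_bm,sdlog_bm Log-scale location/scale of the
#'   transcription-rate marginal (mRNA/h; defaults `log(30)`, 1.2).
#' @param meanlog_bp,sdlog_bp Same for translation rates (proteins per
#'   mRNA per hour; defaults `log(1500)`, 1.0).
#' @param r_ms Correlation between log mRNA abundance and log footprint
#'   abundance (default 0.981).
#' @param n_wgd,n_ssd Pair counts (defaults 245, 164).
#' @param sigma_dbm,sigma_dbp SDs of the signed within-pair log2 fold
#'   changes of the two rates (log2 units; defaults 2.29, 1.11).
#' @param rho_signed_target Correlation of the signed transcriptional and
#'   translational fold changes (default 0.45).
#' @param sdlog_alpha_m,sdlog_alpha_p Log-scale spread of gene-specific
#'   decay rates around the medians (defaults 0.35, 0.30).
#' @param decay_fc_sd SD of within-pair mRNA-decay log2 fold changes
#'   (default 0.8).
#' @param seed Integer seed.
#' @param constants A [rate_constants()] object.
#' @return A `synthetic_spec` list.
#' @export
synthetic_spec <- function(n_genes = 4440,
                           meanlog_bm = log(30), sdlog_bm = 1.2,
                           meanlog_bp = log(600), sdlog_bp = 1.0,
                           r_ms = 0.981,
                           n_wgd = 245, n_ssd = 164,
                           sigma_dbm = 2.29, sigma_dbp = 1.11,
                           rho_signed_target = 0.45,
                           sdlog_alpha_m = 0.35, sdlog_alpha_p = 0.30,
                           decay_fc_sd = 0.8,
                           seed = 1L, constants = rate_constants()) {
  stopifnot_positive(n_genes = n_genes, n_wgd = n_wgd, n_ssd = n_ssd,
                     sdlog_bm = sdlog_bm, sdlog_bp = sdlog_bp)
  if (abs(r_ms) > 1 || abs(rho_signed_target) > 1)
    stop("correlations must lie in [-1, 1]")
  if (sigma_dbm < 0 || sigma_dbp < 0)
    stop("fold-change SDs must be non-negative")
  structure(list(n_genes = as.integer(n_genes),
                 meanlog_bm = meanlog_bm, sdlog_bm = sdlog_bm,
                 meanlog_bp = meanlog_bp, sdlog_bp = sdlog_bp,
                 r_ms = r_ms, n_wgd = as.integer(n_wgd),
                 n_ssd = as.integer(n_ssd),
                 sigma_dbm = sigma_dbm, sigma_dbp = sigma_dbp,
                 rho_signed_target = rho_signed_target,
                 sdlog_alpha_m = sdlog_alpha_m,
                 sdlog_alpha_p = sdlog_alpha_p,
                 decay_fc_sd = decay_fc_sd,
                 seed = as.integer(seed), constants = constants),
            class = "synthetic_spec")
}

#' Generate a synthetic gene rate table
#'
#' Draws log-normal transcription rates, derives mRNA abundances under
#' the median decay constant (`m = beta_m / alpha_m`), and constructs
#' footprint measurements `s` so that `cor(log m, log s)` equals the
#' target `r_ms`; translation rates are then *defined* through the
#' flux-apportioning relation (`beta_p = N_p alpha_p s / (m sum(s))`),
#' with the log-scale spread of `s` solved so the resulting `beta_p`
#' marginal has the requested `sdlog_bp`; its location follows from the
#' cellular totals (`meanlog_bp` is a documentation target, matched
#' approximately under the default constants).  Gene-specific decay
#' rates are drawn log-normally
#' around the median constants.  The emitted columns are therefore
#' internally consistent: recomputing rates from `(r, s)` through the
#' measurement equations recovers the stored values.
#'
#' @param spec A [synthetic_spec()].
#' @return A gene table (data.frame) with columns `id`, `beta_m`,
#'   `beta_p`, `m`, `r`, `s`, `alpha_m`, `alpha_p`, `p`.
#' @export
generate_gene_table <- function(spec = synthetic_spec()) {
  cs <- spec$constants
  set.seed(spec$seed)
  n <- spec$n_genes

  log_bm <- stats::rnorm(n, spec$meanlog_bm, spec$sdlog_bm)
  beta_m <- exp(log_bm)
  m <- beta_m / cs$alpha_m
  log_m <- log(m)

  # spread of log s needed so that var(log beta_p) = sdlog_bp^2 given
  # log beta_p = log s - log m + const and cor(log m, log s) = r_ms:
  # sd_s^2 - 2 r sd_m sd_s + (sd_m^2 - sd_bp^2) = 0 (larger root)
  sd_m <- spec$sdlog_bm
  disc <- (spec$r_ms * sd_m)^2 - (sd_m^2 - spec$sdlog_bp^2)
  if (disc < 0)
    stop("no footprint spread satisfies the requested r_ms and sdlog_bp")
  sd_s <- spec$r_ms * sd_m + sqrt(disc)

  z <- stats::rnorm(n)
  zm <- (log_m - mean(log_m)) / stats::sd(log_m)
  log_s <- sd_s * (spec$r_ms * zm + sqrt(1 - spec$r_ms^2) * z)
  s <- exp(log_s)

  # translation rates straight from the flux-apportioning relation, so
  # the stored values are exactly what Eq-3 recomputation returns; their
  # location is an emergent property of the cellular totals (N_p alpha_p
  # spread over the transcriptome) and lands near the meanlog_bp target
  # under the default constants
  beta_p <- translation_rate(s, m, cs$N_p, cs$alpha_p)

  alpha_m_i <- exp(stats::rnorm(n, log(cs$alpha_m), spec$sdlog_alpha_m))
  alpha_p_i <- exp(stats::rnorm(n, log(cs$alpha_p), spec$sdlog_alpha_p))

  data.frame(
    id = sprintf("g%04d", seq_len(n)),
    beta_m = beta_m, beta_p = beta_p,
    m = m, r = m, s = s,
    alpha_m = alpha_m_i, alpha_p = alpha_p_i,
    p = protein_abundance(beta_m, beta_p, cs$alpha_m, cs$alpha_p),
    stringsAsFactors = FALSE
  )
}

#' Generate paralog pairs with known fold-change structure
#'
#' Picks `2 (n_wgd + n_ssd)` distinct genes from the table, designates
#' half as paralog 1, and rewrites each partner's rates as paralog-1
#' rates times signed log2 fold changes drawn from a bivariate normal
#' with SDs `(sigma_dbm, sigma_dbp)` and correlation
#' `rho_signed_target`.  The table's `m`, `r`, `s` and `p` columns are
#' rebuilt afterwards so measurement-level consistency holds table-wide.
#' The generating fold changes are returned as ground truth, so every
#' downstream divergence statistic has an oracle.
#'
#' @param spec A [synthetic_spec()].
#' @param gene_table A gene table from [generate_gene_table()].
#' @return A list: `pairs` (pair table), `genes` (updated gene table),
#'   `truth` (data.frame with the drawn `dlog2_bm`, `dlog2_bp` per pair).
#' @export
generate_paralog_pairs <- function(spec, gene_table) {
  cs <- spec$constants
  set.seed(spec$seed + 1L)
  n_pairs <- spec$n_wgd + spec$n_ssd
  if (nrow(gene_table) < 2 * n_pairs)
    stop("gene table too small for the requested number of pairs")
  idx <- sample.int(nrow(gene_table), 2 * n_pairs)
  i1 <- idx[seq_len(n_pairs)]
  i2 <- idx[n_pairs + seq_len(n_pairs)]

  z1 <- stats::rnorm(n_pairs); z2 <- stats::rnorm(n_pairs)
  rho <- spec$rho_signed_target
  d_bm <- spec$sigma_dbm * z1
  d_bp <- spec$sigma_dbp * (rho * z1 + sqrt(1 - rho^2) * z2)

  genes <- gene_table
  genes$beta_m[i2] <- genes$beta_m[i1] * 2^(-d_bm)
  genes$beta_p[i2] <- genes$beta_p[i1] * 2^(-d_bp)

  # rebuild measurement-level columns consistently; a common rescaling of
  # all translation rates restores the flux identity (it cancels in every
  # fold change)
  genes$m <- genes$beta_m / cs$alpha_m
  genes$beta_p <- genes$beta_p *
    (cs$N_p * cs$alpha_p / sum(genes$beta_p * genes$m))
  genes$r <- genes$m
  genes$s <- genes$beta_p * genes$m
  genes$s <- genes$s / sum(genes$s)
  genes$p <- protein_abundance(genes$beta_m, genes$beta_p,
                               cs$alpha_m, cs$alpha_p)

  pairs <- data.frame(
    gene1 = gene_table$id[i1],
    gene2 = gene_table$id[i2],
    dup_type = c(rep("WGD", spec$n_wgd), rep("SSD", spec$n_ssd)),
    stringsAsFactors = FALSE
  )
  truth <- data.frame(gene1 = pairs$gene1, gene2 = pairs$gene2,
                      dup_type = pairs$dup_type,
                      dlog2_bm = d_bm, dlog2_bp = d_bp,
                      dlog2_p = d_bm + d_bp)
  list(pairs = pairs, genes = genes, truth = truth)
}

#' Generate a synthetic measured-protein-abundance dataset
#'
#' Multiplies each gene's steady-state abundance (from its rates and
#' decay constants) by log-normal measurement noise of log2-scale SD
#' `noise_sd`, standing in for an independent experimental abundance
#' dataset.
#'
#' @param gene_table A gene table.
#' @param noise_sd Log2-scale SD of the multiplicative noise (0 gives
#'   exact abundances).
#' @param seed Integer seed.
#' @param constants A [rate_constants()] object.
#' @return data.frame with `id` and `p_measured`.
#' @export
generate_protein_abundance_dataset <- function(gene_table, noise_sd = 0.5,
                                               seed = 1L,
                                               constants = rate_constants()) {
  if (noise_sd < 0) stop("noise_sd must be non-negative")
  set.seed(seed)
  am <- gene_table$alpha_m %||% rep(constants$alpha_m, nrow(gene_table))
  ap <- gene_table$alpha_p %||% rep(constants$alpha_p, nrow(gene_table))
  am[is.na(am)] <- constants$alpha_m
  ap[is.na(ap)] <- constants$alpha_p
  p_true <- protein_abundance(gene_table$beta_m, gene_table$beta_p,
                              constants$alpha_m, ap)
  noise <- if (noise_sd > 0) 2^stats::rnorm(nrow(gene_table), 0, noise_sd)
           else 1
  data.frame(id = gene_table$id, p_measured = p_true * noise,
             stringsAsFactors = FALSE)
}

#' Generate a synthetic mRNA-decay dataset
#'
#' Stands in for an experimental transcript-decay dataset: gene-level
#' decay rates log-normal around the median constant, plus within-pair
#' decay log2 fold changes.
#'
#' @param n Number of entries.
#' @param spec A [synthetic_spec()] (supplies the spread parameters).
#' @param seed Integer seed.
#' @return data.frame with `alpha_m` (h^-1) and `dlog2_alpha_m`.
#' @export
generate_decay_dataset <- function(n, spec = synthetic_spec(), seed = 1L) {
  set.seed(seed)
  cs <- spec$constants
  data.frame(
    alpha_m = exp(stats::rnorm(n, log(cs$alpha_m), spec$sdlog_alpha_m)),
    dlog2_alpha_m = stats::rnorm(n, 0, spec$decay_fc_sd)
  )
}
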