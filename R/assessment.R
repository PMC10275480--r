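#' Fold-change distributions of a simulated population
#'
#' @param pop A `pair_population`.
#' @return data.frame with per-pair absolute and signed log2 fold
#'   changes of transcription rate, translation rate and protein
#'   abundance (`fc_bm`, `fc_bp`, `fc_p`, `sfc_bm`, `sfc_bp`, `sfc_p`).
#' @export
population_fold_changes <- function(pop) {
  sfc_bm <- log2(pop$bm1 / pop$bm2)
  sfc_bp <- log2(pop$bp1 / pop$bp2)
  data.frame(pair = seq_len(nrow(pop)),
             fc_bm = abs(sfc_bm), fc_bp = abs(sfc_bp),
             fc_p = abs(sfc_bm + sfc_bp),
             sfc_bm = sfc_bm, sfc_bp = sfc_bp, sfc_p = sfc_bm + sfc_bp)
}

#' Summarize a simulation run against a reference divergence pattern
#'
#' Computes, for the three divergence dimensions (transcription rate,
#' translation rate, protein abundance), the two-sample KS statistic and
#' p-value and the Mood's-median-test p-value between simulated and
#' reference absolute log2 fold changes; their mean KS; and the two
#' divergence correlations over the simulated pairs.
#'
#' @param pop Final `pair_population` (or anything accepted by
#'   [population_fold_changes()]).
#' @param reference A list/data.frame with numeric `fc_bm`, `fc_bp`,
#'   `fc_p` reference distributions.
#' @param seed Replicate seed to record (bookkeeping only).
#' @return A `run_summary` (one-row data.frame): `ks_bm`, `ks_bp`,
#'   `ks_p`, `mean_ks`, `ksp_*` and `mood_*` p-values, `rho_abs`,
#'   `rho_signed`, `n_pairs`, `seed`.
#' @export
summarize_run <- function(pop, reference, seed = NA_integer_) {
  if (nrow(pop) == 0) stop("empty population")
  fc <- population_fold_changes(pop)
  one <- function(x, y) {
    ks <- suppressWarnings(stats::ks.test(x, y))
    c(ks = unname(ks$statistic), ksp = ks$p.value,
      mood = mood_median_test(x, y)$p_value)
  }
  bm <- one(fc$fc_bm, reference$fc_bm)
  bp <- one(fc$fc_bp, reference$fc_bp)
  pp <- one(fc$fc_p, reference$fc_p)
  dup_sgn_x <- c(fc$sfc_bm, -fc$sfc_bm)
  dup_sgn_y <- c(fc$sfc_bp, -fc$sfc_bp)
  data.frame(
    ks_bm = bm[["ks"]], ks_bp = bp[["ks"]], ks_p = pp[["ks"]],
    mean_ks = mean(c(bm[["ks"]], bp[["ks"]], pp[["ks"]])),
    ksp_bm = bm[["ksp"]], ksp_bp = bp[["ksp"]], ksp_p = pp[["ksp"]],
    mood_bm = bm[["mood"]], mood_bp = bp[["mood"]], mood_p = pp[["mood"]],
    rho_abs = spearman_safe(fc$fc_bm, fc$fc_bp),
    rho_signed = spearman_safe(dup_sgn_x, dup_sgn_y),
    n_pairs = nrow(pop), seed = seed
  )
}

#' Reference fold-change distributions from divergence records
#'
#' Convenience: reshape [divergence_records()] output (optionally one
#' duplication type) into the reference list [summarize_run()] expects.
#'
#' @param records Divergence records.
#' @param dup_type Optional filter, `"WGD"` or `"SSD"`.
#' @return List with `fc_bm`, `fc_bp`, `fc_p`.
#' @export
reference_fold_changes <- function(records, dup_type = NULL) {
  if (!is.null(dup_type))
    records <- records[records$dup_type == dup_type, , drop = FALSE]
  list(fc_bm = records$fc_bm, fc_bp = records$fc_bp, fc_p = records$fc_p)
}

#' Grid search over mutation-parameter combinations
#'
#' For every combination of model, mutational-effect SD and
#' transcription:translation target-size ratio, runs `length(seeds)`
#' replicate simulations (same seed set in every cell, so results do not
#' depend on evaluation order), summarizes each against the reference,
#' and records the grand mean KS statistic (mean over replicates of the
#' per-replicate mean KS).  The best-fitting `sigma_mut` is the one
#' attaining the smallest grand mean KS anywhere in the grid.
#'
#' @param sigma_grid Mutational-effect SDs to scan.
#' @param ratio_grid `P_bm / P_bp` target-size ratios to scan.
#' @param models Character vector of fitness models.
#' @param N Selection-efficacy parameter.
#' @param reference Reference distributions (see
#'   [reference_fold_changes()]); its `fc_p` also serves as the stop
#'   rule's reference.
#' @param seeds Integer vector of replicate seeds (default `1:3`).
#' @param rate_pool Gene table for initialization.
#' @param n_pairs Pairs per replicate.
#' @param max_rounds Safety cap per replicate.
#' @param stop_p Stop-rule threshold.
#' @param constants A [rate_constants()] object.
#' @return A list: `table` (one row per cell: parameters, grand mean KS,
#'   mean correlations, `n_stopped` replicates, `flagged` if any
#'   replicate hit the round cap), `replicates` (per-replicate
#'   summaries), `best` (the argmin row), `best_sigma_mut`.
#' @export
grid_search <- function(sigma_grid, ratio_grid,
                        models = c("minimal", "precision_economy"),
                        N = 1e6, reference, seeds = 1:3, rate_pool,
                        n_pairs = 250, max_rounds = 50000, stop_p = 0.1,
                        constants = rate_constants()) {
  cells <- list(); reps <- list()
  for (model in models) for (sg in sigma_grid) for (rt in ratio_grid) {
    summaries <- list()
    for (sd_ in seeds) {
      cfg <- simulation_config(
        model = model, N = N, n_pairs = n_pairs,
        mutation = mutation_model("normal", sigma_mut = sg,
                                  p_bm = rt, p_bp = 1),
        reference_fc = reference$fc_p, stop_p = stop_p, seed = sd_,
        max_rounds = max_rounds, trace_every = NULL,
        constants = constants)
      sim <- run_simulation(cfg, rate_pool)
      sm <- summarize_run(sim$population, reference, seed = sd_)
      sm$model <- model; sm$sigma_mut <- sg; sm$ratio <- rt
      sm$rounds <- sim$rounds; sm$stopped <- sim$stopped
      summaries[[length(summaries) + 1L]] <- sm
    }
    smdf <- do.call(rbind, summaries)
    cells[[length(cells) + 1L]] <- data.frame(
      model = model, sigma_mut = sg, ratio = rt,
      grand_mean_ks = mean(smdf$mean_ks),
      mean_rho_abs = mean(smdf$rho_abs),
      mean_rho_signed = mean(smdf$rho_signed),
      n_stopped = sum(smdf$stopped),
      flagged = any(!smdf$stopped))
    reps[[length(reps) + 1L]] <- smdf
  }
  table <- do.call(rbind, cells)
  best <- table[which.min(table$grand_mean_ks), , drop = FALSE]
  list(table = table, replicates = do.call(rbind, reps), best = best,
       best_sigma_mut = best$sigma_mut)
}

#' Check replication of empirical divergence correlations
#'
#' A parameter combination replicates a correlation when at least one of
#' its replicate simulations yields a coefficient inside the supplied
#' empirical 95% confidence interval.
#'
#' @param run_summaries Per-replicate summaries (the `replicates`
#'   element of [grid_search()], or any data.frame with `model`,
#'   `sigma_mut`, `ratio`, `rho_abs`, `rho_signed`).
#' @param ci_abs,ci_signed Numeric length-2 vectors `c(low, high)`.
#' @return data.frame per combination: mean coefficients and logical
#'   `replicated_abs`, `replicated_signed`.
#' @export
correlation_replication_check <- function(run_summaries, ci_abs, ci_signed) {
  chk <- function(ci) {
    if (length(ci) != 2 || anyNA(ci) || ci[1] > ci[2])
      stop("malformed confidence interval")
    ci
  }
  ci_abs <- chk(ci_abs); ci_signed <- chk(ci_signed)
  key <- interaction(run_summaries$model, run_summaries$sigma_mut,
                     run_summaries$ratio, drop = TRUE)
  out <- lapply(split(run_summaries, key), function(g) {
    data.frame(
      model = g$model[1], sigma_mut = g$sigma_mut[1], ratio = g$ratio[1],
      mean_rho_abs = mean(g$rho_abs), mean_rho_signed = mean(g$rho_signed),
      replicated_abs = any(g$rho_abs >= ci_abs[1] &
                             g$rho_abs <= ci_abs[2], na.rm = TRUE),
      replicated_signed = any(g$rho_signed >= ci_signed[1] &
                                g$rho_signed <= ci_signed[2], na.rm = TRUE))
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out
}

#' Summary of simulated paralogs in transcription-translation space
#'
#' Pools the per-copy `(beta_m, beta_p)` rates of one or more final
#' populations, bins them on the log10 scale together with the gene
#' pool, and (optionally) reports the fraction of simulated gene copies
#' falling below a diagonal boundary `log10(beta_p) = intercept + slope
#' * log10(beta_m)`.
#'
#' @param pops A `pair_population` or list of them (replicates pooled).
#' @param gene_pool Gene table for comparison.
#' @param boundary Optional `list(intercept =, slope =)` in log10 space.
#' @param nbins Number of histogram bins per axis (default 40).
#' @return A list: `sim` (data.frame of pooled simulated rates),
#'   `hist_sim`, `hist_pool` (2-D count matrices on shared breaks),
#'   `breaks_bm`, `breaks_bp`, `frac_below_boundary` (NA without a
#'   boundary), `var_log_bm_sim`, `var_log_bm_pool`.
#' @export
expression_space_summary <- function(pops, gene_pool, boundary = NULL,
                                     nbins = 40) {
  if (inherits(pops, "pair_population")) pops <- list(pops)
  sim <- do.call(rbind, lapply(pops, function(p)
    data.frame(beta_m = c(p$bm1, p$bm2), beta_p = c(p$bp1, p$bp2))))
  lbm_s <- log10(sim$beta_m); lbp_s <- log10(sim$beta_p)
  lbm_g <- log10(gene_pool$beta_m); lbp_g <- log10(gene_pool$beta_p)
  brk <- function(a, b, n) seq(min(a, b), max(a, b), length.out = n + 1)
  bx <- brk(min(lbm_s, lbm_g), max(lbm_s, lbm_g), nbins)
  by <- brk(min(lbp_s, lbp_g), max(lbp_s, lbp_g), nbins)
  h2 <- function(x, y) {
    ix <- cut(x, bx, include.lowest = TRUE)
    iy <- cut(y, by, include.lowest = TRUE)
    table(ix, iy)
  }
  frac <- NA_real_
  if (!is.null(boundary))
    frac <- mean(lbp_s < boundary$intercept + boundary$slope * lbm_s)
  list(sim = sim, hist_sim = h2(lbm_s, lbp_s), hist_pool = h2(lbm_g, lbp_g),
       breaks_bm = bx, breaks_bp = by, frac_below_boundary = frac,
       var_log_bm_sim = stats::var(lbm_s),
       var_log_bm_pool = stats::var(lbm_g))
}
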