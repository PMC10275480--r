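make_pop <- function(n = 40, seed = 3, model = "minimal") {
  initialize_population(n, fixture_pool(), model, seed = seed)
}

diverged_pop <- function(pop, sd_bm = 1.5, sd_bp = 0.7, seed = 4) {
  set.seed(seed)
  pop$bm1 <- pop$bm1 * 2^rnorm(nrow(pop), 0, sd_bm)
  pop$bp1 <- pop$bp1 * 2^rnorm(nrow(pop), 0, sd_bp)
  pop
}

test_that("run summaries vanish against self-reference and saturate against mismatch", {
  pop <- diverged_pop(make_pop())
  fc <- population_fold_changes(pop)
  self_ref <- list(fc_bm = fc$fc_bm, fc_bp = fc$fc_bp, fc_p = fc$fc_p)
  sm <- summarize_run(pop, self_ref, seed = 1L)
  expect_equal(sm$ks_bm, 0)
  expect_equal(sm$ks_bp, 0)
  expect_equal(sm$ks_p, 0)
  expect_equal(sm$mean_ks, 0)
  expect_equal(sm$mean_ks, mean(c(sm$ks_bm, sm$ks_bp, sm$ks_p)))
  # an undiverged population against a strongly diverged reference
  pop0 <- make_pop()
  far_ref <- list(fc_bm = abs(rnorm(200, 0, 2)) + 3,
                  fc_bp = abs(rnorm(200, 0, 2)) + 3,
                  fc_p = abs(rnorm(200, 0, 2)) + 3)
  sm0 <- summarize_run(pop0, far_ref)
  expect_gt(sm0$mean_ks, 0.95)
  expect_error(summarize_run(pop0[0, ], far_ref), "empty")
})

test_that("KS statistic equals the brute-force sup-ECDF difference", {
  sup_ecdf <- function(x, y) {
    pts <- sort(c(x, y))
    max(abs(ecdf(x)(pts) - ecdf(y)(pts)))
  }
  set.seed(12)
  for (i in 1:5) {
    x <- rlnorm(sample(20:800, 1)); y <- rlnorm(sample(20:800, 1), 0.3)
    ks <- suppressWarnings(ks.test(x, y))$statistic
    expect_equal(unname(ks), sup_ecdf(x, y), tolerance = 1e-12)
  }
})

test_that("grid search is order-invariant and finds trivial argmins", {
  pop_ref <- diverged_pop(make_pop(60, seed = 9), seed = 9)
  fc <- population_fold_changes(pop_ref)
  ref <- list(fc_bm = fc$fc_bm, fc_bp = fc$fc_bp, fc_p = fc$fc_p)
  g1 <- grid_search(0.05, 2, models = "minimal", N = 1e6, reference = ref,
                    seeds = 1:2, rate_pool = fixture_pool(), n_pairs = 25,
                    max_rounds = 400)
  expect_equal(nrow(g1$table), 1)
  expect_equal(g1$best_sigma_mut, 0.05)
  # per-cell seeding: results identical whatever the scan order
  ga <- grid_search(c(0.05, 0.1), 2, models = "minimal", N = 1e6,
                    reference = ref, seeds = 1:2,
                    rate_pool = fixture_pool(), n_pairs = 25,
                    max_rounds = 400)
  gb <- grid_search(c(0.1, 0.05), 2, models = "minimal", N = 1e6,
                    reference = ref, seeds = 1:2,
                    rate_pool = fixture_pool(), n_pairs = 25,
                    max_rounds = 400)
  a <- ga$table[order(ga$table$sigma_mut), ]
  b <- gb$table[order(gb$table$sigma_mut), ]
  rownames(a) <- rownames(b) <- NULL
  expect_equal(a, b)
})

test_that("correlation replication follows the at-least-one-replicate rule", {
  sums <- data.frame(model = "minimal", sigma_mut = 0.025, ratio = 3,
                     rho_abs = c(0.1, 0.4, 0.9),
                     rho_signed = c(-0.2, 0.0, 0.2))
  always <- correlation_replication_check(sums, c(-1, 1), c(-1, 1))
  expect_true(always$replicated_abs & always$replicated_signed)
  never <- correlation_replication_check(sums, c(0.95, 0.99), c(0.5, 0.9))
  expect_false(never$replicated_abs)
  expect_false(never$replicated_signed)
  one <- correlation_replication_check(sums, c(0.35, 0.45), c(0.15, 0.25))
  expect_true(one$replicated_abs)
  expect_true(one$replicated_signed)
  expect_error(correlation_replication_check(sums, c(1, -1), c(-1, 1)),
               "malformed")
})

test_that("expression-space summaries track divergence in the rate plane", {
  pop <- make_pop(50, seed = 21)
  ess0 <- expression_space_summary(pop, fixture_pool(),
                                   boundary = list(intercept = 5,
                                                   slope = -1))
  # zero rounds of evolution: the cloud is the duplicated ancestors
  expect_equal(sort(unique(ess0$sim$beta_m)), sort(unique(pop$bm_anc)),
               tolerance = 1e-12)
  expect_gte(ess0$frac_below_boundary, 0)
  expect_lte(ess0$frac_below_boundary, 1)
  # a short neutral run adds variance to the log beta_m marginal
  cfg <- simulation_config("minimal", N = 1e6, n_pairs = 50,
                           mutation = mutation_model(sigma_mut = 0.1),
                           reference_fc = NULL, seed = 21,
                           max_rounds = 1500, trace_every = NULL,
                           flat_fitness = TRUE)
  sim <- run_simulation(cfg, fixture_pool(),
                        population = initialize_population(
                          50, fixture_pool(), "minimal", seed = 21,
                          flat_fitness = TRUE))
  ess1 <- expression_space_summary(sim$population, fixture_pool())
  pop_flat <- initialize_population(50, fixture_pool(), "minimal",
                                    seed = 21, flat_fitness = TRUE)
  init_var <- var(log10(c(pop_flat$bm1, pop_flat$bm2)))
  expect_gt(ess1$var_log_bm_sim, init_var)
  # pooling replicates stacks their copies
  ess2 <- expression_space_summary(list(pop, pop), fixture_pool())
  expect_equal(nrow(ess2$sim), 2 * nrow(ess0$sim))
})
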