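cs <- rate_constants()

test_that("mutation models validate their parameters", {
  expect_s3_class(mutation_model(), "mutation_model")
  expect_error(mutation_model(sigma_mut = 0), "positive")
  expect_error(mutation_model("skew_normal"), "alpha_skew")
  expect_error(mutation_model("bivariate", sigma_bm = 0.02), "sigma_bp")
  expect_error(mutation_model("bivariate", sigma_bm = 0.02,
                              sigma_bp = 0.01, r_mut = 1.5), "r_mut")
})

test_that("mutations split between levels by target size and between copies 50/50", {
  set.seed(3)
  mm <- mutation_model(p_bm = 4, p_bp = 1, sigma_mut = 0.02)
  d <- sample_mutation(mm, 40000)
  expect_equal(mean(d$delta_m != 0), 0.8, tolerance = 0.01)
  expect_true(all((d$delta_m != 0) != (d$delta_p != 0) |
                    (d$delta_m == 0 & d$delta_p == 0)))
  expect_equal(mean(d$copy == 1L), 0.5, tolerance = 0.02)
  # effect SD matches sigma_mut
  expect_equal(sd(d$delta_m[d$delta_m != 0]), 0.02, tolerance = 0.02)
})

test_that("skew-normal effects have mean 0, SD sigma_mut and the requested skew", {
  set.seed(5)
  mm <- mutation_model("skew_normal", sigma_mut = 0.05, alpha_skew = -4,
                       p_bm = 1, p_bp = 1)
  d <- sample_mutation(mm, 60000)
  eff <- c(d$delta_m[d$delta_m != 0], d$delta_p[d$delta_p != 0])
  expect_equal(mean(eff), 0, tolerance = 0.002)
  expect_equal(sd(eff), 0.05, tolerance = 0.02)
  skew <- mean(((eff - mean(eff)) / sd(eff))^3)
  expect_lt(skew, -0.3)
})

test_that("bivariate effects carry the requested correlation", {
  set.seed(6)
  mm <- mutation_model("bivariate", sigma_bm = 0.04, sigma_bp = 0.02,
                       r_mut = 0.5)
  d <- sample_mutation(mm, 60000)
  expect_equal(cor(d$delta_m, d$delta_p), 0.5, tolerance = 0.015)
  expect_equal(sd(d$delta_m), 0.04, tolerance = 0.001)
  expect_true(all(d$delta_m != 0 & d$delta_p != 0))
})

test_that("mutations apply multiplicatively and respect rate bounds", {
  f <- duplicate_fitness_function(build_fitness_function(1000, 1e-7))
  st <- pair_state(10, 300, 10, 300, f)
  s0 <- apply_mutation(st, list(delta_m = 0, delta_p = 0, copy = 1L))
  expect_equal(s0$bm1, 10)
  s1 <- apply_mutation(st, list(delta_m = 0.05, delta_p = 0, copy = 1L))
  expect_equal(s1$bm1, 10.5)
  expect_equal(s1$bm2, 10)
  expect_null(apply_mutation(st, list(delta_m = -1, delta_p = 0, copy = 2L)))
  expect_null(apply_mutation(st, list(delta_m = 0.5, delta_p = 0, copy = 1L),
                             bm_max = 14))
})

test_that("Metropolis fixation probabilities follow the modified criterion", {
  expect_equal(fixation_probability(0.5, 0.7, 1e6), 1)
  expect_equal(fixation_probability(0.5, 0.5, 1e6), 1)
  expect_equal(fixation_probability(exp(1e-7) * 0.9, 0.9, 1e6), exp(-0.2),
               tolerance = 1e-9)
  expect_error(fixation_probability(0, 0.5, 1e6), "positive")
  # neutral-drift limit: N -> 0 accepts everything
  expect_equal(fixation_probability(0.9, 0.5, 1e-9), 1, tolerance = 1e-6)
})

test_that("initialized pairs start as identical viable duplicates", {
  pool <- fixture_pool()
  for (model in c("minimal", "precision_economy")) {
    pop <- initialize_population(25, pool, model, N = 1e6, seed = 7)
    expect_equal(pop$bm1, pop$bm2)
    expect_equal(pop$bp1, pop$bp2)
    # cumulative abundance is twice the ancestral abundance
    p_anc <- protein_abundance(pop$bm_anc, pop$bp_anc)
    P <- protein_abundance(pop$bm1, pop$bp1) +
      protein_abundance(pop$bm2, pop$bp2)
    expect_equal(P, 2 * p_anc, tolerance = 1e-12)
    # post-duplication fitness strictly positive for every pair
    expect_true(all(pop_fitness(pop, model, cs) > 0))
    # every pair passes the curvature filter
    expect_true(all(curvature_filter(pop$p_opt, pop$Q, 1e6)))
  }
  # minimal-model ancestors sit exactly at p_opt by construction
  popm <- initialize_population(25, pool, "minimal", N = 1e6, seed = 7)
  expect_equal(protein_abundance(popm$bm_anc, popm$bp_anc), popm$p_opt,
               tolerance = 1e-9)
  expect_true(all(infer_Q(popm$bm_anc, popm$bp_anc) <= cs$Q_max))
})

test_that("evolution rounds share one mutation stream across models", {
  pool <- fixture_pool()
  popm <- initialize_population(15, pool, "minimal", seed = 2)
  pope <- initialize_population(15, pool, "precision_economy", seed = 2)
  set.seed(42)
  d <- sample_mutation(mutation_model(sigma_mut = 0.025), 15)
  d$u_accept <- runif(15)
  both <- evolution_round(list(minimal = popm, pe = pope), d, N = 1e6)
  alone <- evolution_round(popm, d, N = 1e6)
  expect_identical(both$minimal$bm1, alone$bm1)
  expect_identical(both$minimal$fitness, alone$fitness)
  # a zero-effect mutation is always accepted and changes nothing
  d0 <- data.frame(delta_m = 0, delta_p = 0, copy = 1L,
                   u_accept = 0.999)[rep(1, 15), ]
  r0 <- evolution_round(popm, d0, N = 1e6)
  expect_true(all(attr(r0, "accepted")))
  expect_equal(r0$bm1, popm$bm1)
})

test_that("whole runs are deterministic given config and seed", {
  pool <- fixture_pool()
  cfg <- simulation_config("minimal", N = 1e6, n_pairs = 12,
                           mutation = mutation_model(sigma_mut = 0.05),
                           reference_fc = NULL, seed = 9, max_rounds = 300,
                           trace_every = 100)
  s1 <- run_simulation(cfg, pool)
  s2 <- run_simulation(cfg, pool)
  expect_identical(s1$population$bm1, s2$population$bm1)
  expect_identical(s1$mean_fitness, s2$mean_fitness)
  expect_equal(s1$rounds, 300)
  expect_false(s1$stopped)
})

test_that("the stop rule fires on matched divergence and not on mismatch", {
  pool <- fixture_pool()
  pop <- initialize_population(40, pool, "minimal", seed = 3)
  # no divergence vs a diverged reference: must not stop
  expect_false(check_stop(pop, abs(rnorm(200, 0, 2)) + 0.2))
  # reference drawn from the simulated distribution itself: stops
  pop2 <- pop
  set.seed(1)
  pop2$bm1 <- pop2$bm1 * 2^rnorm(40, 0, 1)
  fc <- abs(log2((pop2$bm1 * pop2$bp1) / (pop2$bm2 * pop2$bp2)))
  expect_true(check_stop(pop2, sample(fc, 200, replace = TRUE)))
  expect_error(check_stop(pop, numeric(0)), "empty")
})

test_that("bivariate effect SDs calibrate to the univariate reference", {
  cal <- calibrate_bivariate_sigmas(1, 0.025, r_mut = 0, seed = 2)
  expect_equal(unname(cal["sigma_bm"] / cal["sigma_bp"]), 1)
  # recovered mean |protein effect| matches sigma_mut * sqrt(2/pi) within 1%
  set.seed(77)
  dm <- rnorm(2e5, 0, cal["sigma_bm"]); dp <- rnorm(2e5, 0, cal["sigma_bp"])
  expect_equal(mean(abs(dm + dp + dm * dp)), 0.025 * sqrt(2 / pi),
               tolerance = 0.01)
  cal2 <- calibrate_bivariate_sigmas(2, 0.025, r_mut = 0, seed = 2)
  expect_equal(unname(cal2["sigma_bm"]), 2 * unname(cal2["sigma_bp"]),
               tolerance = 1e-12)
  # correlated effects compound, so calibrated SDs shrink
  cal3 <- calibrate_bivariate_sigmas(1, 0.025, r_mut = 0.8, seed = 2)
  expect_lt(cal3[["sigma_bp"]], cal[["sigma_bp"]])
})

test_that("post-hoc loss filter keeps only pairs with two needed copies", {
  pool <- fixture_pool()
  pop <- initialize_population(30, pool, "minimal", seed = 5)
  # just after duplication, losing a copy means halving 2*p_opt, which
  # the curvature filter guaranteed to be deleterious beyond 1/N
  kept <- post_hoc_loss_filter(pop, N = 1e6)
  expect_equal(nrow(kept), 30)
  # with N -> infinity every pair with any contribution is retained;
  # with tiny N (loss threshold 1/N huge) none survive
  expect_equal(nrow(post_hoc_loss_filter(pop, N = 1e12)), 30)
  expect_equal(nrow(post_hoc_loss_filter(pop, N = 1e-3)), 0)
})
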