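cs <- rate_constants()

test_that("fitness parabola has the right vertex, symmetry and curvature", {
  f <- build_fitness_function(1000, 1e-7)
  expect_equal(eval_fitness(f, 1000), 0.42)
  expect_equal(eval_fitness(f, 1000 + 137), eval_fitness(f, 1000 - 137),
               tolerance = 1e-12)
  expect_lt(f$a, 0)
  # larger Q -> lower fitness at the same relative deviation
  f2 <- build_fitness_function(1000, 5e-7)
  expect_lt(eval_fitness(f2, 1050), eval_fitness(f, 1050))
  expect_error(build_fitness_function(1000, 0), "Q must")
  expect_error(build_fitness_function(1000, 1e-4), "Q must")
})

test_that("duplication shifts the optimum to delta_opt times ancestral", {
  f <- build_fitness_function(1000, 1e-6)
  fd <- duplicate_fitness_function(f)
  expect_equal(eval_fitness(fd, 1870), 0.42)
  expect_equal(fd$Q, f$Q)
  expect_error(duplicate_fitness_function(fd), "already")
  # doubling overshoots the optimum but stays on the near side of it
  expect_lt(eval_fitness(fd, 1000), eval_fitness(fd, 2000))
  expect_gt(eval_fitness(fd, 2000), 0)
})

test_that("singleton noise variance follows the three-term formula", {
  expect_equal(singleton_noise_variance(100, 13.4), 1200)
  # floor limit: cv^2 -> cv0^2 as both p and beta_m grow
  expect_equal(singleton_noise_variance(1e9, 1e9) / 1e18, 0.01,
               tolerance = 1e-6)
  # Poisson term plus floor at p = 1
  expect_equal(singleton_noise_variance(1, 1e12), 1.01, tolerance = 1e-6)
  expect_error(singleton_noise_variance(-1, 10), "positive")
})

test_that("pair noise variance collapses onto the singleton for identical copies", {
  # two identical copies (p = 100, beta_m = 13.4 each) match a singleton
  # with the summed transcription rate at the same total abundance
  expect_equal(pair_noise_variance(100, 100, 13.4, 13.4), 2600)
  expect_equal(pair_noise_variance(100, 100, 13.4, 13.4),
               singleton_noise_variance(200, 26.8))
  # noise floor limit
  expect_equal(pair_noise_variance(5e8, 5e8, 1e9, 1e9) / 1e18, 0.01,
               tolerance = 1e-6)
  # invariance along the equal-translation-rate ridge: redistributing
  # transcription (abundance follows) leaves the variance unchanged
  bp <- 300; k <- cs$alpha_m * cs$alpha_p
  v1 <- pair_noise_variance(10 * bp / k, 20 * bp / k, 10, 20)
  v2 <- pair_noise_variance(25 * bp / k, 5 * bp / k, 25, 5)
  expect_equal(v1, v2, tolerance = 1e-12)
  # asymmetric translational split of the same totals raises the variance
  p <- c(150, 50)  # same P_tot as (100, 100), same bm split
  expect_gt(pair_noise_variance(p[1], p[2], 13.4, 13.4),
            pair_noise_variance(100, 100, 13.4, 13.4))
})

test_that("transcription cost is linear in the summed rate", {
  expect_equal(transcription_cost(0, 0), 0)
  expect_equal(transcription_cost(4, 6), 1.62e-5, tolerance = 1e-12)
  expect_equal(transcription_cost(10, 0), transcription_cost(5, 5))
  expect_error(transcription_cost(-1), "non-negative")
})

test_that("expected fitness matches its closed forms", {
  f <- duplicate_fitness_function(build_fitness_function(800, 2e-7))
  st <- pair_state(20, 300, 25, 280, f)
  # minimal model: the parabola at cumulative abundance
  expect_equal(expected_fitness(st, "minimal"), eval_fitness(f, st$P_tot))
  # precision-economy: mean of W under noise minus cost
  manual <- f$a * (st$sigma_tot2 + st$P_tot^2) + f$b * st$P_tot + f$c -
    transcription_cost(20, 25)
  expect_equal(expected_fitness(st, "precision_economy"), manual,
               tolerance = 1e-12)
  # redistributing total abundance between the copies leaves
  # minimal-model fitness unchanged (same rate-product sum)
  stA <- pair_state(10, 400, 10, 400, f)
  stB <- pair_state(10, 700, 10, 100, f)
  expect_equal(stA$P_tot, stB$P_tot)
  expect_equal(expected_fitness(stA, "minimal"),
               expected_fitness(stB, "minimal"), tolerance = 1e-12)
})

test_that("Q inference inverts to the optimal rate balance", {
  Q <- infer_Q(12, 480)
  expect_equal(Q, cs$c_m * cs$alpha_m * cs$l_m * 12 / 480, tolerance = 1e-12)
  # round trip through the optimal-ratio inversion
  ratio <- cs$c_m * cs$alpha_m * cs$l_m / Q     # beta_p / beta_m
  expect_equal(ratio, 480 / 12, tolerance = 1e-12)
  # raising the transcriptional share at fixed protein output raises Q
  p <- protein_abundance(12, 480)
  expect_gt(infer_Q(24, 480 / 2), Q)  # same p, doubled beta_m share
  # a synthetic pool has only a small tail beyond Q_max, and filtering
  # drops exactly that tail
  g <- fixture_genes()
  Qs <- infer_Q(g$beta_m, g$beta_p)
  frac <- mean(Qs > cs$Q_max)
  expect_lt(frac, 0.05)
  expect_true(all(Qs[Qs <= cs$Q_max] <= cs$Q_max))
})

test_that("minimal-model optimal rates satisfy both constraints", {
  r <- optimal_rates_minimal(5000, 1e-7)
  expect_equal(protein_abundance(r[["beta_m"]], r[["beta_p"]]), 5000,
               tolerance = 1e-9)
  expect_equal(r[["beta_m"]] / r[["beta_p"]],
               1e-7 / (cs$c_m * cs$alpha_m * cs$l_m), tolerance = 1e-9)
  # doubling p_opt at fixed Q scales both rates by sqrt(2)
  r2 <- optimal_rates_minimal(10000, 1e-7)
  expect_equal(unname(r2 / r), c(sqrt(2), sqrt(2)), tolerance = 1e-9)
})

test_that("precision-economy optimum dominates the minimal-model rates", {
  set.seed(14)
  for (i in 1:25) {
    p_opt <- rlnorm(1, log(2000), 1)
    Q <- exp(runif(1, log(1e-9), log(cs$Q_max)))
    f <- build_fitness_function(p_opt, Q)
    pe <- optimal_rates_precision_economy(f, n_extra = 0)
    rmin <- optimal_rates_minimal(p_opt, Q)
    f_min <- singleton_fitness(rmin[["beta_m"]], rmin[["beta_p"]], f, cs)
    expect_gte(pe[["fitness"]], f_min)
    # noise pulls the optimal abundance at or below p_opt
    expect_lte(protein_abundance(pe[["beta_m"]], pe[["beta_p"]]),
               p_opt * (1 + 1e-6))
  }
})

test_that("precision-economy optimizer is restart-stable", {
  f <- build_fitness_function(3000, 5e-7)
  a <- optimal_rates_precision_economy(f, n_extra = 2, seed = 1)
  b <- optimal_rates_precision_economy(f, n_extra = 2, seed = 99)
  expect_equal(a[["fitness"]], b[["fitness"]], tolerance = 1e-8)
})

test_that("curvature filter demands deleterious copy loss", {
  expect_false(curvature_filter(100, 1e-12, 1e6))       # flat: loss neutral
  expect_true(curvature_filter(3000, cs$Q_max, 1e6))    # sharp: loss costly
  # threshold monotone in N
  p <- 500; Q <- 1e-8
  Ns <- 10^(3:8)
  res <- curvature_filter(rep(p, length(Ns)), rep(Q, length(Ns)), 1)
  passes <- vapply(Ns, function(N) curvature_filter(p, Q, N), logical(1))
  expect_true(all(diff(as.integer(passes)) >= 0))
})

test_that("smallest viable optimum multiple is 1.87 and monotone-bounded", {
  expect_equal(minimal_delta_opt(), 1.87, tolerance = 1e-9)
  expect_lte(minimal_delta_opt(Q = cs$Q_max / 2), 1.87)
  # delta = 2 is always viable: doubling lands exactly on the vertex
  f <- duplicate_fitness_function(build_fitness_function(1e6, cs$Q_max),
                                  delta_opt = 2)
  expect_equal(eval_fitness(f, 2e6), 0.42)
})
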