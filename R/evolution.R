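#' Mutation model for expression-evolution simulations
#'
#' Describes how per-round mutational effects on transcription and
#' translation rates are drawn.
#'
#' * `normal`: one effect `delta ~ N(0, sigma_mut)` per pair, assigned to
#'   `beta_m` with probability `p_bm / (p_bm + p_bp)` and to `beta_p`
#'   otherwise — the relative probabilities are the mutational target
#'   sizes of the two traits.
#' * `skew_normal`: as `normal`, but `delta` is drawn from a skew-normal
#'   re-parameterized so that the *distribution* (not its location
#'   parameter) has mean 0 and standard deviation `sigma_mut`, with shape
#'   `alpha_skew` (negative values bias mutations towards decreased
#'   expression).
#' * `bivariate`: every mutation affects both rates at once:
#'   `(delta_m, delta_p)` from a mean-zero bivariate normal with standard
#'   deviations `(sigma_bm, sigma_bp)` and correlation `r_mut`; target
#'   sizes are encoded in the effect magnitudes (see
#'   [calibrate_bivariate_sigmas()]) instead of assignment probabilities.
#'
#' In all families the mutated gene copy is chosen 50/50.
#'
#' @param family Distribution family.
#' @param sigma_mut SD of relative effects (fraction of the current rate).
#' @param p_bm,p_bp Relative mutational target sizes (normal/skew only).
#' @param alpha_skew Skewness shape parameter (skew_normal only).
#' @param sigma_bm,sigma_bp Per-level effect SDs (bivariate only).
#' @param r_mut Correlation between the two effects (bivariate only).
#' @return An object of class `mutation_model`.
#' @export
mutation_model <- function(family = c("normal", "skew_normal", "bivariate"),
                           sigma_mut = 0.025, p_bm = 1, p_bp = 1,
                           alpha_skew = NULL, sigma_bm = NULL,
                           sigma_bp = NULL, r_mut = 0) {
  family <- match.arg(family)
  if (family %in% c("normal", "skew_normal")) {
    stopifnot_positive(sigma_mut = sigma_mut, p_bm = p_bm, p_bp = p_bp)
    if (family == "skew_normal") {
      if (is.null(alpha_skew) || !is.finite(alpha_skew))
        stop("skew_normal requires a finite alpha_skew")
    }
  } else {
    stopifnot_positive(sigma_bm = sigma_bm, sigma_bp = sigma_bp)
    if (abs(r_mut) > 1) stop("r_mut must lie in [-1, 1]")
  }
  structure(list(family = family, sigma_mut = sigma_mut,
                 p_bm = p_bm, p_bp = p_bp, alpha_skew = alpha_skew,
                 sigma_bm = sigma_bm, sigma_bp = sigma_bp, r_mut = r_mut),
            class = "mutation_model")
}

# standardized skew-normal draws: distribution mean 0, SD 1, shape alpha
rskewnorm_std <- function(n, alpha) {
  d0 <- alpha / sqrt(1 + alpha^2)
  z0 <- stats::rnorm(n)
  z1 <- stats::rnorm(n)
  z <- d0 * abs(z0) + sqrt(1 - d0^2) * z1          # SN(0, 1, alpha)
  omega <- 1 / sqrt(1 - 2 * d0^2 / pi)
  xi <- -omega * d0 * sqrt(2 / pi)
  xi + omega * z
}

#' Sample mutations for a round
#'
#' Draws one mutation specification per pair from the current RNG stream:
#' relative effects `delta_m`, `delta_p` (at most one nonzero except in
#' the bivariate family) and the targeted copy (1 or 2).  The number and
#' order of random draws per call is fixed for a given family, which is
#' what keeps mutation streams identical across simulations run from the
#' same seed.
#'
#' @param model A [mutation_model()].
#' @param n Number of pairs.
#' @return A data.frame with columns `delta_m`, `delta_p`, `copy`.
#' @export
sample_mutation <- function(model, n = 1) {
  d <- mutation_draws(model, n)
  data.frame(delta_m = d$delta_m, delta_p = d$delta_p, copy = d$copy)
}

# hot-path version of sample_mutation: same draws in the same order,
# returned as a plain list
mutation_draws <- function(model, n) {
  if (model$family == "bivariate") {
    z <- stats::rnorm(2 * n)
    z1 <- z[seq_len(n)]; z2 <- z[n + seq_len(n)]
    r <- model$r_mut
    dm <- model$sigma_bm * z1
    dp <- model$sigma_bp * (r * z1 + sqrt(1 - r^2) * z2)
  } else {
    u_level <- stats::runif(n)
    delta <- if (model$family == "normal")
      stats::rnorm(n, 0, model$sigma_mut)
    else
      model$sigma_mut * rskewnorm_std(n, model$alpha_skew)
    to_bm <- u_level < model$p_bm / (model$p_bm + model$p_bp)
    dm <- delta * to_bm
    dp <- delta * (1 - to_bm)
  }
  copy <- 1L + (stats::runif(n) >= 0.5)
  list(delta_m = dm, delta_p = dp, copy = copy)
}

#' Apply a mutation specification to a pair state
#'
#' Effects are multiplicative: the targeted rate(s) of the targeted copy
#' become `beta * (1 + delta)`.  The candidate is rejected outright
#' (`NULL` returned) when any resulting rate is non-positive or exceeds
#' its configured maximum.
#'
#' @param state A [pair_state()].
#' @param spec One row of [sample_mutation()] output (list or data.frame
#'   row with `delta_m`, `delta_p`, `copy`).
#' @param bm_max,bp_max Rate upper bounds.
#' @return The mutated `pair_state`, or `NULL` if the candidate violates
#'   the rate bounds.
#' @export
apply_mutation <- function(state, spec, bm_max = Inf, bp_max = Inf) {
  bm1 <- state$bm1; bp1 <- state$bp1; bm2 <- state$bm2; bp2 <- state$bp2
  if (spec$copy == 1L) {
    bm1 <- bm1 * (1 + spec$delta_m); bp1 <- bp1 * (1 + spec$delta_p)
  } else {
    bm2 <- bm2 * (1 + spec$delta_m); bp2 <- bp2 * (1 + spec$delta_p)
  }
  if (min(bm1, bp1, bm2, bp2) <= 0 || max(bm1, bm2) > bm_max ||
      max(bp1, bp2) > bp_max)
    return(NULL)
  pair_state(bm1, bp1, bm2, bp2, state$fitness_fn, state$constants)
}

#' Fixation probability under the modified Metropolis criterion
#'
#' Any beneficial or perfectly neutral mutation fixes; a deleterious one
#' fixes with probability `exp(-2 N (log F_i - log F_j))`, where `F_i`
#' and `F_j` are the ancestral and mutant fitness values scaled to
#' `(0, 1]` and `N` tunes selection efficacy (analogous to an effective
#' population size).  Candidates with negative fitness must be discarded
#' before calling this.
#'
#' @param F_i,F_j Scaled ancestral and mutant fitness, in `(0, 1]`
#'   (vectorised).
#' @param N Selection-efficacy parameter (> 0).
#' @return Fixation probabilities in `[0, 1]`.
#' @examples
#' fixation_probability(exp(-1e-7) * 0.9, 0.9, N = 1e6)  # exp(-0.2)
#' @export
fixation_probability <- function(F_i, F_j, N) {
  stopifnot_positive(N = N)
  if (any(!is.finite(F_i)) || any(F_i <= 0))
    stop("invalid state: ancestral fitness must be strictly positive")
  ifelse(F_j > F_i, 1, exp(-2 * N * (log(F_i) - log(F_j))))
}

# ---- vectorised population machinery ---------------------------------------

# scaled (F / mu) populational fitness for every pair of a population
pop_fitness <- function(pop, model, constants,
                        bm1 = pop$bm1, bp1 = pop$bp1,
                        bm2 = pop$bm2, bp2 = pop$bp2) {
  if (isTRUE(attr(pop, "flat_fitness")))
    return(rep(1, length(bm1)))
  k <- constants$alpha_m * constants$alpha_p
  p1 <- bm1 * bp1 / k
  p2 <- bm2 * bp2 / k
  P <- p1 + p2
  if (model == "minimal") {
    Fv <- pop$a * P^2 + pop$b * P + pop$cc
  } else {
    s2 <- P + constants$alpha_p * (p1^2 / bm1 + p2^2 / bm2) +
      constants$cv0^2 * P^2
    Fv <- pop$a * (s2 + P^2) + pop$b * P + pop$cc -
      constants$l_m * constants$c_m * (bm1 + bm2)
  }
  Fv / constants$mu
}

# sample (p_opt, Q) base combinations that pass Q_max and the curvature
# filter; vectorised rejection sampling from the current RNG stream
sample_admissible_combos <- function(n, p_pool, Q_pool, N, constants,
                                     max_tries = 1000) {
  out_p <- numeric(0); out_q <- numeric(0)
  tries <- 0
  while (length(out_p) < n) {
    tries <- tries + 1
    if (tries > max_tries)
      stop("resampling cap exceeded while drawing admissible (p_opt, Q)")
    m <- 2 * (n - length(out_p)) + 16
    p <- sample(p_pool, m, replace = TRUE)
    q <- sample(Q_pool, m, replace = TRUE)
    keep <- curvature_filter(p, q, N, constants)
    out_p <- c(out_p, p[keep]); out_q <- c(out_q, q[keep])
  }
  data.frame(p_opt = out_p[seq_len(n)], Q = out_q[seq_len(n)])
}

#' Initialize a population of duplicate pairs
#'
#' Builds `n` post-duplication pair states from a pool of gene rates.
#' Protein-abundance optima `p_opt` and noise sensitivities `Q` (from
#' [infer_Q()], values above `Q_max` excluded) are sampled independently
#' with replacement from the pool; combinations failing the curvature
#' filter at efficacy `N` are resampled.  Ancestral rates are then set
#' per model: under `minimal`, the analytic [optimal_rates_minimal()]
#' combination, after which `Q` is resampled from the pool distribution
#' (the minimal model must not inherit precision-economy information);
#' under `precision_economy`, the rates maximizing singleton fitness
#' ([optimal_rates_precision_economy()]).  Each ancestor is duplicated
#' into two copies carrying its rates, and the fitness function's optimum
#' is shifted to `delta_opt * p_opt`.  Combinations whose immediate
#' post-duplication fitness would not be strictly positive are resampled,
#' so every initialized pair starts viable.
#'
#' @param n Number of pairs (>= 1).
#' @param rate_pool Gene table (data.frame with `beta_m`, `beta_p`; at
#'   least 2 genes).
#' @param model `"minimal"` or `"precision_economy"`.
#' @param N Selection efficacy used in the curvature filter.
#' @param constants A [rate_constants()] object.
#' @param delta_opt Post-duplication optimum multiple (default from
#'   `constants`).
#' @param seed Optional seed (otherwise the current RNG stream is used).
#' @param flat_fitness Build a neutral population (fitness identically 1;
#'   used for neutral-accumulation checks; skips all fitness filters).
#' @param max_tries Resampling cap per admissibility loop.
#' @return A `pair_population`: a data.frame with one row per pair
#'   (`p_opt`, `Q`, `bm_anc`, `bp_anc`, `bm1`, `bp1`, `bm2`, `bp2`,
#'   parabola coefficients `a`, `b`, `cc`, vertex `opt`) carrying the
#'   model, constants and rate bounds as attributes.
#' @export
initialize_population <- function(n, rate_pool,
                                  model = c("minimal", "precision_economy"),
                                  N = 1e6, constants = rate_constants(),
                                  delta_opt = NULL, seed = NULL,
                                  flat_fitness = FALSE, max_tries = 1000) {
  model <- match.arg(model)
  if (n < 1) stop("n must be at least 1")
  if (nrow(rate_pool) < 2) stop("rate pool must contain at least 2 genes")
  if (!is.null(seed)) set.seed(seed)
  delta_opt <- delta_opt %||% constants$delta_opt
  cs <- constants

  p_pool <- protein_abundance(rate_pool$beta_m, rate_pool$beta_p,
                              cs$alpha_m, cs$alpha_p)
  Q_all <- infer_Q(rate_pool$beta_m, rate_pool$beta_p, cs)
  Q_pool <- Q_all[Q_all <= cs$Q_max]
  if (!length(Q_pool))
    stop("rate pool has no genes with Q <= Q_max")

  mk_coef <- function(p_opt, Q) {
    opt <- delta_opt * p_opt
    a <- -cs$mu * Q / (2 * opt)
    list(a = a, b = -2 * a * opt, cc = cs$mu + a * opt^2, opt = opt)
  }

  if (flat_fitness) {
    base <- data.frame(
      p_opt = sample(p_pool, n, replace = TRUE),
      Q = sample(Q_pool, n, replace = TRUE))
  } else {
    base <- sample_admissible_combos(n, p_pool, Q_pool, N, cs, max_tries)
  }

  rows <- vector("list", n)
  for (i in seq_len(n)) {
    tries <- 0
    repeat {
      tries <- tries + 1
      if (tries > max_tries)
        stop("resampling cap exceeded during population initialization")
      p_opt <- base$p_opt[i]; Qi <- base$Q[i]
      if (model == "minimal") {
        r <- optimal_rates_minimal(p_opt, Qi, cs)
        if (!flat_fitness) {
          # the fitness landscape's curvature is decoupled from the rates
          Qi <- sample(Q_pool, 1)
          ok_curv <- curvature_filter(p_opt, Qi, N, cs)
        } else ok_curv <- TRUE
      } else {
        r <- optimal_rates_precision_economy(
          build_fitness_function(p_opt, Qi, constants = cs), cs,
          n_extra = 0)
        ok_curv <- TRUE
      }
      if (ok_curv) {
        cf <- mk_coef(p_opt, Qi)
        bm <- r[["beta_m"]]; bp <- r[["beta_p"]]
        if (flat_fitness) {
          F0 <- 1
        } else {
          P0 <- 2 * protein_abundance(bm, bp, cs$alpha_m, cs$alpha_p)
          F0 <- if (model == "minimal") {
            (cf$a * P0^2 + cf$b * P0 + cf$cc) / cs$mu
          } else {
            s2 <- P0^2 * (1 / P0 + cs$alpha_p / (2 * bm) + cs$cv0^2)
            (cf$a * (s2 + P0^2) + cf$b * P0 + cf$cc -
               cs$l_m * cs$c_m * 2 * bm) / cs$mu
          }
        }
        if (F0 > 0) {
          rows[[i]] <- data.frame(p_opt = p_opt, Q = Qi,
                                  bm_anc = bm, bp_anc = bp,
                                  bm1 = bm, bp1 = bp, bm2 = bm, bp2 = bp,
                                  a = cf$a, b = cf$b, cc = cf$cc,
                                  opt = cf$opt)
          break
        }
      }
      # draw a fresh base combination for this pair and retry
      base[i, ] <- sample_admissible_combos(1, p_pool, Q_pool, N, cs,
                                            max_tries)
    }
  }
  pop <- do.call(rbind, rows)
  attr(pop, "model") <- model
  attr(pop, "constants") <- cs
  attr(pop, "flat_fitness") <- flat_fitness
  attr(pop, "bounds") <- c(bm_max = max(rate_pool$beta_m),
                           bp_max = max(rate_pool$beta_p))
  class(pop) <- c("pair_population", "data.frame")
  pop
}

#' One mutation-selection round over populations sharing a mutation stream
#'
#' Applies a common block of mutation draws to each supplied population
#' (typically the minimal-model and precision-economy populations evolved
#' side by side): pair `i` of every population receives the same effect,
#' level assignment, target copy and acceptance uniform, but acceptance is
#' evaluated against each population's own fitness model.  Candidates
#' taking a rate to zero or negative values or above its bound are
#' rejected (the round is still consumed), as are candidates with
#' non-positive fitness; the rest fix with the Metropolis probability.
#'
#' @param populations A `pair_population` or a list of them (equal sizes).
#' @param draws A draw block from [sample_mutation()] (one row per pair),
#'   plus an `u_accept` column; if `u_accept` is absent, uniforms are
#'   drawn from the current stream (after the mutation draws, in the
#'   canonical order).
#' @param N Selection-efficacy parameter.
#' @return Populations of the same shape, advanced by one round, each
#'   with an `accepted` attribute (logical vector for the round).
#' @export
evolution_round <- function(populations, draws, N) {
  single <- inherits(populations, "pair_population")
  pops <- if (single) list(populations) else populations
  n <- nrow(pops[[1]])
  if (is.null(draws$u_accept))
    draws$u_accept <- stats::runif(n)
  out <- lapply(pops, function(pop) step_population(pop, draws, N))
  if (single) out[[1]] else out
}

step_population <- function(pop, draws, N) {
  cs <- attr(pop, "constants")
  model <- attr(pop, "model")
  bounds <- attr(pop, "bounds")
  n <- nrow(pop)

  on1 <- draws$copy == 1L
  fm <- 1 + draws$delta_m
  fp <- 1 + draws$delta_p
  cbm1 <- ifelse(on1, pop$bm1 * fm, pop$bm1)
  cbp1 <- ifelse(on1, pop$bp1 * fp, pop$bp1)
  cbm2 <- ifelse(on1, pop$bm2, pop$bm2 * fm)
  cbp2 <- ifelse(on1, pop$bp2, pop$bp2 * fp)

  valid <- cbm1 > 0 & cbp1 > 0 & cbm2 > 0 & cbp2 > 0 &
    cbm1 <= bounds[["bm_max"]] & cbm2 <= bounds[["bm_max"]] &
    cbp1 <= bounds[["bp_max"]] & cbp2 <= bounds[["bp_max"]]

  Fi <- pop$fitness %||% pop_fitness(pop, model, cs)
  Fj <- pop_fitness(pop, model, cs, cbm1, cbp1, cbm2, cbp2)
  ok <- valid & Fj > 0
  pfix <- rep(0, n)
  if (any(ok))
    pfix[ok] <- fixation_probability(Fi[ok], Fj[ok], N)
  acc <- ok & draws$u_accept < pfix

  pop$bm1[acc] <- cbm1[acc]; pop$bp1[acc] <- cbp1[acc]
  pop$bm2[acc] <- cbm2[acc]; pop$bp2[acc] <- cbp2[acc]
  Fi[acc] <- Fj[acc]
  pop$fitness <- Fi
  attr(pop, "accepted") <- acc
  pop
}

#' Stop condition: has simulated protein divergence become realistic?
#'
#' Compares the simulated distribution of absolute protein-abundance log2
#' fold changes with a reference distribution using Mood's median test;
#' the simulation has reached a realistic magnitude of divergence when the
#' two medians are no longer distinguishable (p-value above `stop_p`).
#'
#' @param pop A `pair_population`.
#' @param reference_fc Non-empty numeric vector of reference absolute
#'   log2 fold changes of protein abundance.
#' @param stop_p p-value threshold (default 0.1).
#' @return TRUE when the Mood p-value exceeds `stop_p`.
#' @export
check_stop <- function(pop, reference_fc, stop_p = 0.1) {
  if (length(reference_fc) == 0)
    stop("reference fold-change distribution is empty")
  fc <- abs(log2((pop$bm1 * pop$bp1) / (pop$bm2 * pop$bp2)))
  mood_median_test(fc, reference_fc)$p_value > stop_p
}

#' Simulation configuration
#'
#' @param model `"minimal"` or `"precision_economy"`.
#' @param N Selection-efficacy parameter (> 0).
#' @param n_pairs Number of simulated duplicate pairs.
#' @param mutation A [mutation_model()].
#' @param reference_fc Reference distribution of absolute protein log2
#'   fold changes for the stop rule (NULL: run to `max_rounds`).
#' @param stop_p Mood p-value threshold of the stop rule, in (0, 1).
#' @param seed Integer replicate seed; every random draw of the run flows
#'   from it.
#' @param max_rounds Safety cap on mutation-selection rounds.
#' @param trace_every Record per-pair fitness/rate traces every this many
#'   rounds (default 10).
#' @param flat_fitness Neutral-evolution override (fitness identically 1).
#' @param constants A [rate_constants()] object.
#' @return A `simulation_config` list.
#' @export
simulation_config <- function(model = c("minimal", "precision_economy"),
                              N = 1e6, n_pairs = 50,
                              mutation = mutation_model(),
                              reference_fc = NULL, stop_p = 0.1,
                              seed = 1L, max_rounds = 200000,
                              trace_every = 10, flat_fitness = FALSE,
                              constants = rate_constants()) {
  model <- match.arg(model)
  stopifnot_positive(N = N, n_pairs = n_pairs, max_rounds = max_rounds)
  if (stop_p <= 0 || stop_p >= 1) stop("stop_p must lie in (0, 1)")
  structure(list(model = model, N = N, n_pairs = n_pairs,
                 mutation = mutation, reference_fc = reference_fc,
                 stop_p = stop_p, seed = as.integer(seed),
                 max_rounds = max_rounds, trace_every = trace_every,
                 flat_fitness = flat_fitness, constants = constants),
            class = "simulation_config")
}

#' Run a sequential-fixation simulation of post-duplication divergence
#'
#' Initializes (or accepts) a population of duplicate pairs and iterates
#' mutation-selection rounds until the stop rule fires or `max_rounds` is
#' reached.  All randomness flows from `config$seed`: the population is
#' initialized from `seed`, after which the mutation stream is re-seeded
#' from the same value, so two runs with the same seed and `n_pairs` —
#' even under different fitness models — consume identical mutation
#' series and acceptance uniforms, pair by pair and round by round.
#'
#' @param config A [simulation_config()].
#' @param rate_pool Gene table supplying the pools of rates, optima and
#'   noise sensitivities (and the default rate bounds).
#' @param population Optional pre-built `pair_population` (bypasses
#'   initialization; its model attribute must match the config).
#' @return A list of class `paradiv_sim`: `population` (final states),
#'   `rounds` (rounds used), `stopped` (did the stop rule fire),
#'   `stop_p_value` (last Mood p), `mean_fitness` (per-round mean scaled
#'   fitness), `trace` (thinned per-pair scaled fitness matrix and median
#'   absolute log2 fold changes), `config`.
#' @export
run_simulation <- function(config, rate_pool, population = NULL) {
  cs <- config$constants
  if (is.null(population)) {
    population <- initialize_population(
      config$n_pairs, rate_pool, config$model, N = config$N,
      constants = cs, seed = config$seed,
      flat_fitness = config$flat_fitness)
  } else if (attr(population, "model") != config$model) {
    stop("population was initialized for a different model")
  }
  pop <- population
  n <- nrow(pop)
  set.seed(config$seed)  # mutation stream, shared across models

  # hoist state and constants out of the data.frame for the hot loop
  bm1 <- pop$bm1; bp1 <- pop$bp1; bm2 <- pop$bm2; bp2 <- pop$bp2
  av <- pop$a; bv <- pop$b; cv <- pop$cc
  k <- cs$alpha_m * cs$alpha_p
  alpha_p <- cs$alpha_p; cv0sq <- cs$cv0^2
  lmcm <- cs$l_m * cs$c_m; mu <- cs$mu
  flat <- isTRUE(attr(pop, "flat_fitness"))
  minimal <- config$model == "minimal"
  bounds <- attr(pop, "bounds")
  bm_max <- bounds[["bm_max"]]; bp_max <- bounds[["bp_max"]]
  N <- config$N
  ref <- config$reference_fc

  fit_of <- function(b1, q1, b2, q2) {
    if (flat) return(rep(1, n))
    p1 <- b1 * q1 / k; p2 <- b2 * q2 / k
    P <- p1 + p2
    if (minimal) {
      (av * P^2 + bv * P + cv) / mu
    } else {
      s2 <- P + alpha_p * (p1^2 / b1 + p2^2 / b2) + cv0sq * P^2
      (av * (s2 + P^2) + bv * P + cv - lmcm * (b1 + b2)) / mu
    }
  }
  Fi <- fit_of(bm1, bp1, bm2, bp2)

  mean_fit <- numeric(0)
  tr_rounds <- integer(0)
  tr_fit <- list(); tr_med <- list()
  stopped <- FALSE
  last_p <- NA_real_
  rounds <- 0

  while (rounds < config$max_rounds) {
    rounds <- rounds + 1
    d <- mutation_draws(config$mutation, n)
    u_acc <- stats::runif(n)
    on1 <- d$copy == 1L
    f1m <- 1 + d$delta_m * on1; f1p <- 1 + d$delta_p * on1
    f2m <- 1 + d$delta_m * (!on1); f2p <- 1 + d$delta_p * (!on1)
    cbm1 <- bm1 * f1m; cbp1 <- bp1 * f1p
    cbm2 <- bm2 * f2m; cbp2 <- bp2 * f2p
    ok <- cbm1 > 0 & cbp1 > 0 & cbm2 > 0 & cbp2 > 0 &
      cbm1 <= bm_max & cbm2 <= bm_max & cbp1 <= bp_max & cbp2 <= bp_max
    Fj <- fit_of(cbm1, cbp1, cbm2, cbp2)
    ok <- ok & Fj > 0
    acc <- ok & (Fj > Fi | u_acc < exp(-2 * N * (log(Fi) - log(pmax(Fj, 1e-300)))))
    if (any(acc)) {
      bm1[acc] <- cbm1[acc]; bp1[acc] <- cbp1[acc]
      bm2[acc] <- cbm2[acc]; bp2[acc] <- cbp2[acc]
      Fi[acc] <- Fj[acc]
    }
    mean_fit[rounds] <- mean(Fi)

    if (!is.null(config$trace_every) && rounds %% config$trace_every == 0) {
      tr_rounds[[length(tr_rounds) + 1L]] <- rounds
      tr_fit[[length(tr_fit) + 1L]] <- Fi
      tr_med[[length(tr_med) + 1L]] <- c(
        bm = stats::median(abs(log2(bm1 / bm2))),
        bp = stats::median(abs(log2(bp1 / bp2))))
    }

    if (!is.null(ref)) {
      fc <- abs(log2((bm1 * bp1) / (bm2 * bp2)))
      last_p <- mood_median_test(fc, ref)$p_value
      if (last_p > config$stop_p) { stopped <- TRUE; break }
    }
  }
  pop$bm1 <- bm1; pop$bp1 <- bp1; pop$bm2 <- bm2; pop$bp2 <- bp2
  pop$fitness <- Fi

  structure(list(
    population = pop, rounds = rounds, stopped = stopped,
    stop_p_value = last_p, mean_fitness = mean_fit,
    trace = list(rounds = unlist(tr_rounds),
                 fitness = if (length(tr_fit)) do.call(rbind, tr_fit),
                 median_fc = if (length(tr_med)) do.call(rbind, tr_med)),
    config = config), class = "paradiv_sim")
}

#' @export
print.paradiv_sim <- function(x, ...) {
  cat(sprintf("Sequential-fixation run: %s model, %d pairs, %d rounds (%s)\n",
              x$config$model, nrow(x$population), x$rounds,
              if (x$stopped) sprintf("stopped, Mood p = %.3f", x$stop_p_value)
              else "round cap reached"))
  invisible(x)
}

#' Retain only pairs for which losing either copy would be deleterious
#'
#' Re-evaluates each final pair after setting either copy's expression to
#' zero (the pair becomes a singleton with the surviving copy's rates,
#' still judged on the post-duplication fitness function) and keeps pairs
#' where both losses lower scaled fitness by more than `1/N` — the pairs
#' selection would have preserved had loss-of-function mutations been
#' allowed.
#'
#' @param pop A `pair_population` (e.g. `run_simulation(...)$population`).
#' @param N Selection-efficacy parameter.
#' @return The surviving subset (same class, attributes preserved).
#' @export
post_hoc_loss_filter <- function(pop, N) {
  cs <- attr(pop, "constants")
  model <- attr(pop, "model")
  tiny <- 1e-12  # a lost copy: expression driven to (numerically) zero
  F_full <- pop_fitness(pop, model, cs)
  F_no1 <- pop_fitness(pop, model, cs,
                       bm1 = rep(tiny, nrow(pop)), bp1 = rep(tiny, nrow(pop)))
  F_no2 <- pop_fitness(pop, model, cs,
                       bm2 = rep(tiny, nrow(pop)), bp2 = rep(tiny, nrow(pop)))
  keep <- (F_full - F_no1 > 1 / N) & (F_full - F_no2 > 1 / N)
  out <- pop[keep, , drop = FALSE]
  for (at in c("model", "constants", "flat_fitness", "bounds"))
    attr(out, at) <- attr(pop, at)
  class(out) <- class(pop)
  out
}

#' Calibrate bivariate effect SDs to a univariate reference
#'
#' Finds `(sigma_bm, sigma_bp)` with `sigma_bm / sigma_bp = ratio` such
#' that the mean absolute relative protein-abundance change per mutation,
#' `E|delta_m + delta_p + delta_m * delta_p|`, matches the univariate
#' reference `E|delta| = sigma_mut * sqrt(2/pi)`.  Under the
#' multiplicative mutation model the relative protein change does not
#' depend on the current rates, so the match holds uniformly over any
#' rate pool.  The bivariate mean is estimated by fixed-seed Monte Carlo
#' with common random numbers and the scale solved by bisection.
#'
#' @param ratio Target `sigma_bm / sigma_bp` (> 0).
#' @param reference_sigma_mut Univariate reference SD.
#' @param r_mut Correlation between the two effects.
#' @param n_mc Monte-Carlo draws (default 2e5).
#' @param seed Seed for the draws.
#' @param tol Relative matching tolerance (default 0.01).
#' @return Named vector `c(sigma_bm =, sigma_bp =)`.
#' @export
calibrate_bivariate_sigmas <- function(ratio, reference_sigma_mut,
                                       r_mut = 0, n_mc = 2e5, seed = 1L,
                                       tol = 0.01) {
  stopifnot_positive(ratio = ratio, reference_sigma_mut = reference_sigma_mut)
  if (abs(r_mut) > 1) stop("r_mut must lie in [-1, 1]")
  target <- reference_sigma_mut * sqrt(2 / pi)
  old <- if (exists(".Random.seed", .GlobalEnv))
    get(".Random.seed", .GlobalEnv) else NULL
  set.seed(seed)
  z1 <- stats::rnorm(n_mc); z2 <- stats::rnorm(n_mc)
  if (!is.null(old)) assign(".Random.seed", old, .GlobalEnv)
  e2 <- r_mut * z1 + sqrt(1 - r_mut^2) * z2
  mean_effect <- function(sp) {
    dm <- sp * ratio * z1
    dp <- sp * e2
    mean(abs(dm + dp + dm * dp))
  }
  g <- function(sp) mean_effect(sp) - target
  lo <- 1e-6; hi <- 1
  while (g(hi) < 0 && hi < 1e3) hi <- hi * 2
  if (g(lo) > 0 || g(hi) < 0)
    stop("calibration failed to bracket the reference effect size")
  sp <- stats::uniroot(g, c(lo, hi), tol = 1e-10)$root
  if (abs(mean_effect(sp) - target) > tol * target)
    stop("calibration did not converge within tolerance")
  c(sigma_bm = sp * ratio, sigma_bp = sp)
}
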