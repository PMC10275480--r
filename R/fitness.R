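#' Parabolic fitness function of protein abundance
#'
#' Fitness `W(p)` is a downward parabola with vertex at the gene's optimal
#' protein abundance `p_opt`, where it equals the maximal growth rate
#' `mu`.  Curvature is set by the noise-sensitivity parameter `Q`,
#' measured relative to the optimum:
#' `W(p) = mu * (1 - (Q / (2 * opt)) * (p - opt)^2)`, i.e.
#' `a = -mu * Q / (2 * opt)` where `opt` is the current vertex abscissa.
#' A larger `Q` means a sharper fitness loss for the same deviation, and
#' the same `Q` penalizes a given *relative* deviation of a high-abundance
#' gene less per molecule than that of a low-abundance one.  This
#' parameterization is the one under which the smallest viable
#' post-duplication optimum multiple evaluates to 1.87 under the default
#' constants (see [minimal_delta_opt()]).  The standard-form coefficients
#' `a`, `b`, `c` are stored so that `W(p) = a p^2 + b p + c`; callers only
#' ever evaluate the stored coefficients, so an alternative
#' parameterization can be swapped in without touching them.
#'
#' @param p_opt Optimal protein abundance, proteins per cell (> 0).
#' @param Q Noise sensitivity, in `(0, Q_max]`.
#' @param mu Maximal growth rate, h^-1.
#' @param constants A [rate_constants()] object (supplies `Q_max` and the
#'   default `mu`).
#' @return An object of class `fitness_function`: a list with `a`, `b`,
#'   `c`, `p_opt`, `opt` (current vertex abscissa), `Q`, `mu`, `post_dup`,
#'   `delta_opt`.
#' @examples
#' f <- build_fitness_function(p_opt = 1000, Q = 1e-7)
#' eval_fitness(f, 1000)  # == mu
#' @export
build_fitness_function <- function(p_opt, Q, mu = NULL,
                                   constants = rate_constants()) {
  mu <- mu %||% constants$mu
  stopifnot_positive(p_opt = p_opt, mu = mu)
  if (!is.numeric(Q) || !is.finite(Q) || Q <= 0 || Q > constants$Q_max)
    stop("Q must lie in (0, Q_max]")
  a <- -mu * Q / (2 * p_opt)
  structure(list(a = a, b = -2 * a * p_opt, c = mu + a * p_opt^2,
                 p_opt = p_opt, opt = p_opt, Q = Q, mu = mu,
                 post_dup = FALSE, delta_opt = constants$delta_opt),
            class = "fitness_function")
}

#' Evaluate a fitness function at given abundance(s)
#'
#' @param f A `fitness_function`.
#' @param p Protein abundance(s).
#' @return Fitness value(s), h^-1 (may be negative far from the optimum).
#' @export
eval_fitness <- function(f, p) {
  f$a * p^2 + f$b * p + f$c
}

#' @export
print.fitness_function <- function(x, ...) {
  cat(sprintf("Parabolic fitness: vertex (%g, %g), Q = %g%s\n",
              x$opt, x$mu, x$Q,
              if (x$post_dup) sprintf("  [post-duplication, %.2f x ancestral optimum]",
                                      x$delta_opt) else ""))
  invisible(x)
}

#' Shift a fitness function to its post-duplication optimum
#'
#' After duplication the pair is selected on cumulative abundance, with
#' the optimum moved to `delta_opt` (default 1.87) times the ancestral
#' `p_opt`; the noise sensitivity `Q` and peak fitness `mu` are unchanged
#' (the coefficient `a` is re-derived from `Q` and the new vertex, since
#' curvature is measured relative to the optimum).  Doubling of
#' expression by the duplication therefore overshoots the new optimum but
#' leaves fitness positive for admissible genes.
#'
#' @param f An ancestral (`post_dup = FALSE`) `fitness_function`.
#' @param delta_opt Optimum multiple; defaults to the value stored in `f`.
#' @return The shifted `fitness_function`.
#' @export
duplicate_fitness_function <- function(f, delta_opt = NULL) {
  if (isTRUE(f$post_dup))
    stop("fitness function is already post-duplication")
  delta_opt <- delta_opt %||% f$delta_opt
  opt <- delta_opt * f$p_opt
  f$opt <- opt
  f$a <- -f$mu * f$Q / (2 * opt)
  f$b <- -2 * f$a * opt
  f$c <- f$mu + f$a * opt^2
  f$post_dup <- TRUE
  f$delta_opt <- delta_opt
  f
}

#' Expression-noise variance of a singleton gene
#'
#' Protein-abundance variance across an isogenic population:
#' `sigma^2 = p^2 (1/p + alpha_p/beta_m + cv0^2)` — a Poisson term from
#' protein copy number, a term from mRNA-number fluctuations that shrinks
#' as transcription takes a larger share of expression, and the noise
#' floor `cv0`.
#'
#' @param p Protein abundance (> 0).
#' @param beta_m Transcription rate, mRNA/h (> 0).
#' @param cv0 Noise floor.
#' @param alpha_p Protein decay rate, h^-1.
#' @return Variance of protein abundance (proteins^2).
#' @export
singleton_noise_variance <- function(p, beta_m,
                                     cv0 = rate_constants()$cv0,
                                     alpha_p = rate_constants()$alpha_p) {
  stopifnot_positive(p = p, beta_m = beta_m, alpha_p = alpha_p)
  p^2 * (1 / p + alpha_p / beta_m + cv0^2)
}

#' Noise variance on the cumulative abundance of a paralog pair
#'
#' Each copy contributes its own protein-number (Poisson) and
#' mRNA-fluctuation noise, while the extrinsic noise floor acts on the
#' summed abundance (global factors hit two identical gene copies
#' coherently):
#' `sigma_tot^2 = P_tot + alpha_p (p1^2/beta_m1 + p2^2/beta_m2)
#'  + cv0^2 P_tot^2`.
#' For two identical copies this collapses exactly onto the
#' singleton form evaluated at `(P_tot, beta_m1 + beta_m2)`, and more
#' generally it is invariant to redistributing transcription between the
#' copies whenever the two translation rates are equal (the
#' configuration compensatory drift maintains): there `p_i` is
#' proportional to `beta_m_i`, so the mRNA term depends on the summed
#' transcription rate only.  Away from that ridge, asymmetry in the
#' translational split of a given abundance raises the variance — the
#' coupling that channels expression divergence into transcription under
#' the precision-economy model.
#'
#' @param p1,p2 Protein abundances of the two copies (> 0).
#' @param bm1,bm2 Transcription rates of the two copies (> 0).
#' @inheritParams singleton_noise_variance
#' @return Variance of cumulative protein abundance.
#' @export
pair_noise_variance <- function(p1, p2, bm1, bm2,
                                cv0 = rate_constants()$cv0,
                                alpha_p = rate_constants()$alpha_p) {
  stopifnot_positive(p1 = p1, p2 = p2, bm1 = bm1, bm2 = bm2)
  P <- p1 + p2
  P + alpha_p * (p1^2 / bm1 + p2^2 / bm2) + cv0^2 * P^2
}

#' Fitness cost of transcription for a paralog pair
#'
#' `C = l_m * c_m * (beta_m1 + beta_m2)` in h^-1: linear in the total
#' number of nucleotides transcribed per unit time, so it depends on the
#' summed transcription rate only.
#'
#' @param bm1,bm2 Transcription rates (>= 0).
#' @param l_m Pre-mRNA length, nt.
#' @param c_m Cost per transcribed nucleotide, nt^-1.
#' @return Fitness penalty, h^-1.
#' @export
transcription_cost <- function(bm1, bm2 = 0,
                               l_m = rate_constants()$l_m,
                               c_m = rate_constants()$c_m) {
  if (any(bm1 < 0) || any(bm2 < 0))
    stop("transcription rates must be non-negative")
  l_m * c_m * (bm1 + bm2)
}

#' State of one evolving duplicate pair
#'
#' @param bm1,bp1,bm2,bp2 Transcription/translation rates of paralogs P1
#'   and P2.
#' @param fitness_fn A post-duplication `fitness_function`.
#' @param constants A [rate_constants()] object.
#' @return An object of class `pair_state` caching `P_tot` (Eq-5 protein
#'   abundances summed), `bm_tot` and `sigma_tot2`.
#' @export
pair_state <- function(bm1, bp1, bm2, bp2, fitness_fn,
                       constants = rate_constants()) {
  stopifnot_positive(bm1 = bm1, bp1 = bp1, bm2 = bm2, bp2 = bp2)
  p1 <- protein_abundance(bm1, bp1, constants$alpha_m, constants$alpha_p)
  p2 <- protein_abundance(bm2, bp2, constants$alpha_m, constants$alpha_p)
  P_tot <- p1 + p2
  bm_tot <- bm1 + bm2
  structure(list(bm1 = bm1, bp1 = bp1, bm2 = bm2, bp2 = bp2,
                 p1 = p1, p2 = p2, P_tot = P_tot, bm_tot = bm_tot,
                 sigma_tot2 = pair_noise_variance(p1, p2, bm1, bm2,
                                                  constants$cv0,
                                                  constants$alpha_p),
                 fitness_fn = fitness_fn, constants = constants),
            class = "pair_state")
}

#' Expected populational fitness of a duplicate pair
#'
#' Minimal model: the deterministic parabola evaluated at the cumulative
#' abundance, `F = W(P_tot)` — no noise, no cost, so `F` depends on the
#' pair only through `P_tot`.  Precision-economy model: the exact mean of
#' `W` over the noise distribution minus the transcription cost,
#' `F = a (sigma_tot^2 + P_tot^2) + b P_tot + c - C`, which follows from
#' `E[p^2] = Var(p) + E[p]^2` for the quadratic `W`.
#'
#' @param state A [pair_state()].
#' @param model `"minimal"` or `"precision_economy"`.
#' @return Fitness `F` in h^-1 (unscaled; may be negative).
#' @export
expected_fitness <- function(state, model = c("minimal", "precision_economy")) {
  model <- match.arg(model)
  f <- state$fitness_fn
  if (model == "minimal")
    return(eval_fitness(f, state$P_tot))
  cs <- state$constants
  f$a * (state$sigma_tot2 + state$P_tot^2) + f$b * state$P_tot + f$c -
    transcription_cost(state$bm1, state$bm2, cs$l_m, cs$c_m)
}

#' Infer the noise sensitivity Q of a gene from its rates
#'
#' `Q = c_m * alpha_m * l_m * (beta_m / beta_p)`: genes that buy their
#' expression mostly through transcription (high `beta_m/beta_p`) are the
#' noise-sensitive ones under precision-economy optimality.  The inverse
#' relationship gives the optimal rate balance for a given sensitivity:
#' `beta_p / beta_m = c_m * alpha_m * l_m / Q` (see
#' [optimal_rates_minimal()]).
#'
#' @param beta_m,beta_p Strictly positive rates (vectorised).
#' @param constants A [rate_constants()] object.
#' @return Noise sensitivity value(s) `Q`.
#' @export
infer_Q <- function(beta_m, beta_p, constants = rate_constants()) {
  stopifnot_positive(beta_m = beta_m, beta_p = beta_p)
  constants$c_m * constants$alpha_m * constants$l_m * (beta_m / beta_p)
}

#' Optimal rate pair under the minimal model
#'
#' Among the infinitely many `(beta_m, beta_p)` combinations yielding the
#' target abundance `p_opt`, returns the unique one whose rate balance
#' also satisfies the precision-economy relation for sensitivity `Q`
#' (the inverse of [infer_Q()]): `beta_m/beta_p = Q / (c_m alpha_m l_m)`
#' and `beta_m * beta_p = p_opt * alpha_m * alpha_p`.
#'
#' @param p_opt Target protein abundance (> 0).
#' @param Q Noise sensitivity (> 0).
#' @param constants A [rate_constants()] object.
#' @return Named numeric vector `c(beta_m =, beta_p =)`.
#' @export
optimal_rates_minimal <- function(p_opt, Q, constants = rate_constants()) {
  stopifnot_positive(p_opt = p_opt, Q = Q)
  ratio <- Q / (constants$c_m * constants$alpha_m * constants$l_m) # bm / bp
  prod <- p_opt * constants$alpha_m * constants$alpha_p            # bm * bp
  bm <- sqrt(ratio * prod)
  c(beta_m = bm, beta_p = prod / bm)
}

singleton_fitness <- function(bm, bp, f, constants) {
  p <- protein_abundance(bm, bp, constants$alpha_m, constants$alpha_p)
  s2 <- singleton_noise_variance(p, bm, constants$cv0, constants$alpha_p)
  f$a * (s2 + p^2) + f$b * p + f$c -
    transcription_cost(bm, 0, constants$l_m, constants$c_m)
}

#' Optimal singleton rates under the precision-economy model
#'
#' Maximizes the singleton populational fitness (mean of `W` over the
#' expression-noise distribution, minus transcription cost) over a bounded
#' positive rate box, by multi-start bounded quasi-Newton search on the
#' log-rate scale.  One start is always the analytic minimal-model optimum
#' (which pins the abundance at `p_opt`), so the returned fitness can
#' never fall below the minimal-model value; additional deterministic and
#' (optionally seeded) random starts guard against local optima.  Because
#' noise scales with abundance, the optimal abundance typically lands
#' slightly *below* `p_opt`.
#'
#' @param f An ancestral (singleton) `fitness_function`.
#' @param constants A [rate_constants()] object.
#' @param bounds Rate box `list(bm = c(lo, hi), bp = c(lo, hi))`.
#' @param n_extra Number of extra random starts (default 2).
#' @param seed Optional seed for the extra starts.
#' @return Named vector `c(beta_m =, beta_p =, fitness =)`.
#' @export
optimal_rates_precision_economy <- function(f, constants = rate_constants(),
                                            bounds = list(bm = c(1e-3, 1e5),
                                                          bp = c(1e-3, 1e6)),
                                            n_extra = 2, seed = NULL) {
  if (isTRUE(f$post_dup))
    stop("expected an ancestral (singleton) fitness function")
  obj <- function(lg) -singleton_fitness(exp(lg[1]), exp(lg[2]), f, constants)
  lo <- log(c(bounds$bm[1], bounds$bp[1]))
  hi <- log(c(bounds$bm[2], bounds$bp[2]))
  start0 <- optimal_rates_minimal(f$p_opt, f$Q, constants)
  starts <- list(log(start0),
                 log(start0) + c(0.7, -0.7),
                 log(start0) + c(-0.7, 0.7))
  if (n_extra > 0) {
    if (!is.null(seed)) set.seed(seed)
    for (k in seq_len(n_extra))
      starts[[length(starts) + 1L]] <-
        lo + stats::runif(2) * (hi - lo)
  }
  best <- NULL
  for (st in starts) {
    st <- pmin(pmax(st, lo), hi)
    fit <- tryCatch(
      stats::optim(st, obj, method = "L-BFGS-B", lower = lo, upper = hi,
                   control = list(factr = 1e4, maxit = 500)),
      error = function(e) NULL)
    if (is.null(fit)) next
    if (is.null(best) || fit$value < best$value) best <- fit
  }
  if (is.null(best))
    stop("precision-economy rate optimization failed to converge")
  # never report worse than the analytic minimal-model start
  f_min <- singleton_fitness(start0[["beta_m"]], start0[["beta_p"]], f, constants)
  if (-best$value < f_min) {
    return(c(beta_m = start0[["beta_m"]], beta_p = start0[["beta_p"]],
             fitness = f_min))
  }
  c(beta_m = unname(exp(best$par[1])), beta_p = unname(exp(best$par[2])),
    fitness = -best$value)
}

#' Curvature filter: is the instant loss of a paralog deleterious?
#'
#' Under the post-duplication fitness function, halving cumulative
#' abundance from `2 p_opt` (just after duplication) to `p_opt` (one copy
#' lost) must cost more than `1/N` of scaled fitness for selection of
#' efficacy `N` to oppose the loss.  Combinations `(p_opt, Q)` that fail
#' are too flat to retain a duplicate and are excluded from simulations.
#'
#' @param p_opt Ancestral abundance optimum (vectorised).
#' @param Q Noise sensitivity (vectorised).
#' @param N Selection-efficacy parameter.
#' @param constants A [rate_constants()] object.
#' @return Logical: TRUE where the loss would be deleterious.
#' @export
curvature_filter <- function(p_opt, Q, N, constants = rate_constants()) {
  stopifnot_positive(N = N)
  d <- constants$delta_opt
  # scaled fitness lost when halving 2 p_opt -> p_opt under the shifted
  # parabola (vertex d*p_opt, a = -mu*Q/(2*d*p_opt)), vectorised
  drop <- (Q * p_opt / (2 * d)) * ((1 - d)^2 - (2 - d)^2)
  drop > 1 / N
}

# Largest admissible p_opt for a given Q: a singleton expressing at its
# abundance optimum, with the transcription rate that best balances
# mRNA-noise against transcription cost, must retain positive
# precision-economy fitness.  With x = sqrt(p_opt) the positivity
# boundary is the quadratic A x^2 + B x = 1 - Q/2, where A = Q cv0^2 / 2
# (noise-floor term) and B = 2 sqrt((Q/2) alpha_p l_m c_m / mu) (the
# minimized mRNA-noise + cost terms), solved in closed form.
max_admissible_p_opt <- function(Q, constants = rate_constants()) {
  cs <- constants
  A <- Q * cs$cv0^2 / 2
  B <- 2 * sqrt((Q / 2) * cs$alpha_p * cs$l_m * cs$c_m / cs$mu)
  rhs <- 1 - Q / 2
  if (rhs <= 0) return(NA_real_)
  x <- (-B + sqrt(B^2 + 4 * A * rhs)) / (2 * A)
  x^2
}

#' Smallest viable post-duplication optimum multiple
#'
#' Scans candidate multiples `Delta` of the ancestral abundance optimum
#' from 1.00 upward in steps of 0.01 and returns the smallest one for
#' which the post-duplication fitness at cumulative abundance `2 p_opt`
#' is strictly positive for *every* admissible `(p_opt, Q)` combination
#' with `Q` at its supplied value — by default the theoretical maximum,
#' i.e. the narrowest admissible fitness function.  Admissibility means
#' (i) a singleton with those parameters has positive precision-economy
#' fitness at its abundance optimum under the cost-noise-optimal
#' transcription rate, which bounds `p_opt` from above for a given `Q`,
#' and (ii) the combination passes the curvature filter at efficacy `N`.
#' The binding case is the largest admissible `p_opt`.
#'
#' @param Q Noise sensitivity of the narrowest function (default
#'   `Q_max`).
#' @param N Selection efficacy used by the curvature filter.
#' @param constants A [rate_constants()] object.
#' @param step Scan granularity (default 0.01).
#' @return The smallest admissible multiple (1.87 under the default
#'   constants).
#' @export
minimal_delta_opt <- function(Q = NULL, N = 1e6,
                              constants = rate_constants(), step = 0.01) {
  Q <- Q %||% constants$Q_max
  p_max <- max_admissible_p_opt(Q, constants)
  if (!is.finite(p_max))
    stop("no admissible p_opt for the supplied Q")
  for (delta in seq(1, 2, by = step)) {
    # loss-of-copy deleteriousness under the candidate optimum multiple;
    # the filter only removes flat, small-p combinations, so the binding
    # admissible p_opt remains the largest one
    drop <- (Q * p_max / (2 * delta)) * ((1 - delta)^2 - (2 - delta)^2)
    if (drop <= 1 / N) next
    # W(2 p_opt) under vertex delta * p_opt and a = -mu Q / (2 delta p_opt)
    w <- constants$mu * (1 - (Q * p_max / (2 * delta)) * (2 - delta)^2)
    if (w > 0) return(delta)
  }
  2
}
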