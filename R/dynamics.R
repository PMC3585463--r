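## Model right-hand sides -----------------------------------------------------

## guard rail: below this glucose concentration the storage boundary ratio
## xi*/A ~ k/G is numerically singular; biologically G stays positive because
## of the constant hepatic production p6. An integrator trial step proposing
## G <= .G_min raises, which forces step rejection.
.G_min <- 1e-6

#' Cell-cycle right-hand side
#'
#' Rates of the three-compartment beta-cell-cycle model at a fixed glucose
#' concentration. Glucose enters linearly through the G1->S transition rate
#' \eqn{p_1 (1 + p_5 G)}; the factor 2 on the G2/M->G1 flux accounts for cell
#' division.
#'
#' @param G1,S,G2M cell counts in the three phases, non-negative.
#' @param G glucose concentration, mg/100ml, non-negative.
#' @param params an [islet_parameters()] object.
#' @return Named numeric vector `c(G1, S, G2M)` of rates (cells/min).
#' @export
rhs_cell_cycle <- function(G1, S, G2M, G, params) {
  if (any(!is.finite(c(G1, S, G2M, G))) || any(c(G1, S, G2M, G) < 0))
    stop("cell-cycle inputs must be non-negative and finite")
  trans <- params$p1 * (1 + params$p5 * G)
  c(G1 = 2 * params$p3 * G2M - (trans + params$p4) * G1,
    S = trans * G1 - params$p2 * S,
    G2M = params$p2 * S - params$p3 * G2M)
}

#' Blood glucose and insulin right-hand side
#'
#' \eqn{\dot G = p_6 - (p_7 + p_8 I) G} (production minus insulin-independent
#' and insulin-dependent uptake) and
#' \eqn{\dot I = p_9 X_1 / bv - p_{10} I} (secretion of the releasable store
#' relative to the blood volume, minus first-order decay).
#'
#' @param G,I blood glucose and insulin concentrations, mg/100ml,
#'   non-negative.
#' @param X1 releasable insulin mass, mg, non-negative.
#' @inheritParams rhs_cell_cycle
#' @return Named numeric vector `c(G, I)` of rates.
#' @export
rhs_blood <- function(G, I, X1, params) {
  if (any(!is.finite(c(G, I, X1))) || any(c(G, I, X1) < 0))
    stop("blood inputs must be non-negative and finite")
  c(G = params$p6 - (params$p7 + params$p8 * I) * G,
    I = params$p9 * X1 / params$bv - params$p10 * I)
}

#' Insulin storage right-hand side
#'
#' Rates of the releasable store `X1`, the non-releasable store `X2` and the
#' provision factor `P`:
#' \deqn{\dot X_1 = X_1 \frac{\xi^*(G)}{A} \dot G - p_9 X_1
#'   + \tilde f (A X_2 - B X_1) + f A P,}
#' \deqn{\dot X_2 = -X_2 \frac{\xi^*(G)}{B} \dot G
#'   + \tilde f (B X_1 - A X_2) + f B P, \qquad
#'   \dot P = p_{11} (P_\infty(G) - P).}
#' The boundary terms move mass between the compartments as the glucose
#' threshold sweeps across the packet axis; the \eqn{\tilde f} terms
#' redistribute mass and conserve `X1 + X2` exactly.
#'
#' All `G1`-dependent factors are evaluated in their analytically cancelled
#' form (\eqn{\tilde f A}, \eqn{\tilde f B} and the boundary ratios
#' \eqn{\xi^*/A}, \eqn{\xi^*/B} do not depend on `G1`), so the rates extend
#' continuously to `G1 = 0` and are exactly zero at the trivial steady state.
#'
#' @param G glucose concentration, mg/100ml, must exceed the guard rail
#'   `1e-6` (the boundary ratio is singular at zero glucose).
#' @param Gdot current glucose rate of change (supplied by [rhs_blood()]).
#' @param G1 cell count in G1 phase, non-negative.
#' @param X1,X2 stored insulin masses, mg, non-negative.
#' @param P provision factor, non-negative.
#' @inheritParams rhs_cell_cycle
#' @return Named numeric vector `c(X1, X2, P)` of rates.
#' @export
rhs_storage <- function(G, Gdot, G1, X1, X2, P, params) {
  if (!is.finite(G) || G <= .G_min)
    stop(sprintf("G must exceed the guard rail %g mg/100ml", .G_min))
  if (any(!is.finite(c(Gdot, G1, X1, X2, P))) || any(c(G1, X1, X2, P) < 0))
    stop("storage inputs must be finite and non-negative")
  Ck <- params$C^params$k
  gk <- exp(params$k * log(G))
  u <- transition_functions(G, params)
  ratio1 <- params$k * Ck / (G * (Ck + gk))            # xi*(G)/A, G1-free
  ratio2 <- params$k * gk / (G * (Ck + gk))            # xi*(G)/B, G1-free
  c(X1 = X1 * ratio1 * Gdot - params$p9 * X1 +
        u$u2 * X2 - u$u1 * X1 + u$u3 * G1 * P,
    X2 = -X2 * ratio2 * Gdot +
        u$u1 * X1 - u$u2 * X2 + u$u4 * G1 * P,
    P = params$p11 * (provision_steady_state(G, params) - P))
}

#' Complete model right-hand side
#'
#' Assembles the cell-cycle, blood and storage right-hand sides into the full
#' eight-state autonomous system (component order as in [state_names()]).
#' The glucose rate from the blood block is passed to the storage boundary
#' terms. The signature `(t, state, params)` matches the `deSolve` contract;
#' the system is autonomous, `t` is unused.
#'
#' @param t time (unused; kept for the integrator interface).
#' @param state named or unnamed numeric vector of length 8 in the canonical
#'   order `G1, S, G2M, G, I, X1, X2, P`.
#' @inheritParams rhs_cell_cycle
#' @return Named numeric vector of the eight rates.
#' @export
rhs_full <- function(t, state, params) {
  if (length(state) != 8L || any(!is.finite(state)))
    stop("state must be a finite numeric vector of length 8")
  y <- as.numeric(state)
  cc <- rhs_cell_cycle(y[1], y[2], y[3], y[4], params)
  bl <- rhs_blood(y[4], y[5], y[6], params)
  st <- rhs_storage(y[4], bl[["G"]], y[1], y[6], y[7], y[8], params)
  out <- c(cc, bl, st)
  names(out) <- .state_names
  out
}

## deSolve-facing wrapper. Adaptive trial stages may overshoot a fast-decaying
## component slightly below zero; the right-hand side is evaluated on the
## continuous extension f(max(y, 0)) so such stages do not abort the run.
## This is not solution clipping: simulate_islet() still rejects any accepted
## solution point below -1e-12. The glucose guard rail remains a hard error.
.rhs_desolve <- function(t, y, params) {
  list(rhs_full(t, pmax(y, 0), params))
}

#' Boundary positivity check
#'
#' Verifies the invariance (positivity) condition for the model: for each
#' state component \eqn{x_i}, the rate \eqn{f_i} evaluated at \eqn{x_i = 0}
#' with all other components strictly positive must be positive, which is
#' necessary and sufficient for solutions started at positive initial values
#' to remain positive. The other components are drawn from fixed ranges
#' covering all simulated regimes (cells in `[1, 1e9]`, glucose in
#' `[1, 600]` mg/100ml, insulin in `[1e-6, 1]` mg/100ml, stored masses in
#' `[1e-9, 1e-2]` mg, provision in `[1e-6, 1]`), log-uniformly for the
#' wide-ranged components, with a fixed seed for reproducibility.
#'
#' @param params an [islet_parameters()] object.
#' @param n_samples number of random boundary states per component.
#' @param seed integer seed for the sampler.
#' @return A data frame with one row per component: `component`, `min_rate`
#'   (the smallest boundary rate observed) and `pass` (`min_rate > 0`), with
#'   attribute `pass` giving the overall verdict.
#' @examples
#' rep <- check_positivity(islet_parameters(), n_samples = 100)
#' attr(rep, "pass")
#' @export
check_positivity <- function(params, n_samples = 10000, seed = 20121119) {
  stopifnot(n_samples >= 1)
  runif_log <- function(n, lo, hi) exp(stats::runif(n, log(lo), log(hi)))
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed)
  draw_state <- function(n) {
    cbind(G1 = runif_log(n, 1, 1e9), S = runif_log(n, 1, 1e9),
          G2M = runif_log(n, 1, 1e9), G = stats::runif(n, 1, 600),
          I = runif_log(n, 1e-6, 1), X1 = runif_log(n, 1e-9, 1e-2),
          X2 = runif_log(n, 1e-9, 1e-2), P = runif_log(n, 1e-6, 1))
  }
  states <- draw_state(n_samples)
  mins <- rep(Inf, 8L)
  for (s in seq_len(n_samples)) {
    y <- states[s, ]
    for (i in seq_len(8L)) {
      yi <- y
      yi[i] <- 0
      ## G = 0 sits on the storage singularity; the G rate itself is the
      ## constant production p6 there, evaluated directly
      rate <- if (i == 4L) params$p6 else rhs_full(0, yi, params)[[i]]
      if (rate < mins[i]) mins[i] <- rate
    }
  }
  out <- data.frame(component = .state_names, min_rate = mins,
                    pass = mins > 0)
  attr(out, "pass") <- all(out$pass)
  out
}
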