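## Threshold-density method-of-lines oracle -----------------------------------
##
## Independent verification route for the two-compartment storage reduction:
## the packet density xi(theta, t) is discretized on a uniform threshold
## grid and evolved per node under the original distribution-level dynamics
## at constant glucose. Quadrature of the density below/above the threshold
## then reproduces the compartment masses X1(t), X2(t), which are compared
## against the reduced two-compartment ODE system. At constant glucose the
## reduction is exact, so any discrepancy measures discretization and solver
## error only. The oracle covers constant glucose by construction: the
## moving-threshold exchange has no distribution-level specification here.

#' Discretized initial packet distribution
#'
#' Builds a uniform threshold grid on `[0, theta_max]` carrying the initial
#' packet density \eqn{\xi_0(\theta) = \bar X_{max} k C^k \theta^{k-1} /
#' (C^k + \theta^k)^2}. The truncated tail mass beyond `theta_max`
#' (relative share \eqn{C^k/(C^k + \theta_{max}^k)}) must stay below
#' `tail_tol`.
#'
#' @inheritParams provision_steady_state
#' @param theta_max truncation point of the threshold axis, mg/100ml.
#' @param n_nodes number of grid nodes (at least 100).
#' @param tail_tol maximal tolerated relative tail mass.
#' @return An object of class `packet_grid`: list with `theta` (nodes),
#'   `density` (initial values), `spacing`, `theta_max`, `tail_rel`.
#' @examples
#' g <- packet_grid(islet_parameters(), n_nodes = 500)
#' g$tail_rel < 1e-3
#' @export
packet_grid <- function(params, theta_max = 2000, n_nodes = 2000,
                        tail_tol = 1e-3) {
  stopifnot(theta_max > 0, n_nodes >= 100)
  tail_rel <- params$C^params$k / (params$C^params$k + theta_max^params$k)
  if (tail_rel >= tail_tol)
    stop(sprintf("truncated tail mass %.3g exceeds tolerance %.3g; increase theta_max",
                 tail_rel, tail_tol))
  theta <- seq(0, theta_max, length.out = n_nodes)
  dens <- params$Xbar_max * params$k * params$C^params$k *
    .pospow(theta, params$k - 1) / (params$C^params$k +
                                    .pospow(theta, params$k))^2
  structure(list(theta = theta, density = dens,
                 spacing = theta_max / (n_nodes - 1),
                 theta_max = theta_max, tail_rel = tail_rel,
                 params = params),
            class = "packet_grid")
}

## trapezoid weights on a uniform grid of m nodes with spacing h
.trap_weights <- function(m, h) {
  w <- rep(h, m)
  w[c(1L, m)] <- h / 2
  w
}

#' Evolve the packet density at constant glucose
#'
#' Integrates the distribution-level storage dynamics on the threshold grid:
#' below the (node-snapped) glucose threshold each node obeys
#' \eqn{\dot\xi = -p_9 \xi + f \xi_0 P(t) - \tilde f \bar X_{max} \xi
#' + \tilde f \xi_0 X_\infty(t)}, above it the same without the secretion
#' term, where \eqn{X_\infty(t)} is the trapezoid quadrature of the current
#' density. The threshold node is duplicated into both sub-grids so each
#' compartment quadrature acts on a smooth integrand (the density develops a
#' jump at the threshold).
#'
#' @param grid a [packet_grid()].
#' @param G constant glucose concentration, mg/100ml.
#' @param P_input provision forcing: a function of time returning a scalar.
#'   Default: relaxation of the provision factor from 0 toward
#'   \eqn{P_\infty(G)} at rate `p11`, matching the provision dynamics at
#'   constant glucose.
#' @param f_tilde_const constant redistribution factor. Default:
#'   \eqn{\tilde f(G, G1_0)}, the factor frozen at the run's glucose value
#'   and the reference cell count, matching the constant-coefficient
#'   distribution model.
#' @param t_span output times (minutes); a scalar is interpreted as a
#'   horizon sampled at 1-min spacing.
#' @param rtol,atol solver tolerances (tight by default so discretization
#'   error dominates any comparison).
#' @return An object of class `packet_run`: list with `time`, `X1`, `X2`
#'   (compartment masses by quadrature), `below`/`above` density snapshot
#'   matrices, the snapped threshold `G_snapped`, `split` index, `G`,
#'   `f_tilde`, `P_input` and the originating `grid`.
#' @export
evolve_density <- function(grid, G, P_input = NULL, f_tilde_const = NULL,
                           t_span = 200, rtol = 1e-12, atol = 1e-18) {
  stopifnot(inherits(grid, "packet_grid"))
  params <- grid$params
  if (!is.finite(G) || G <= 0 || G >= grid$theta_max)
    stop("G must lie strictly inside (0, theta_max)")
  if (is.null(f_tilde_const))
    f_tilde_const <- redistribution_factor(G, params$G1_0, params)
  if (is.null(P_input)) {
    pinf <- provision_steady_state(G, params)
    P_input <- function(t) pinf * (1 - exp(-params$p11 * t))
  }
  if (length(t_span) == 1L) t_span <- seq(0, t_span, by = 1)
  n <- length(grid$theta)
  j <- which.min(abs(grid$theta - G))          # snap threshold to a node
  if (j < 2L || j > n - 1L) stop("threshold snaps to a grid boundary")
  Gsn <- grid$theta[j]
  h <- grid$spacing
  wb <- .trap_weights(j, h)
  wa <- .trap_weights(n - j + 1L, h)
  xb0 <- grid$density[1:j]                     # below (secreting) sub-grid
  xa0 <- grid$density[j:n]                     # above sub-grid
  decay_b <- params$p9 + f_tilde_const * params$Xbar_max
  decay_a <- f_tilde_const * params$Xbar_max
  rhs <- function(t, y, parms) {
    yb <- y[1:j]
    ya <- y[(j + 1L):(n + 1L)]
    Xinf <- sum(wb * yb) + sum(wa * ya)
    forcing <- params$f * P_input(t) + f_tilde_const * Xinf
    list(c(-decay_b * yb + xb0 * forcing,
           -decay_a * ya + xa0 * forcing))
  }
  ## hmax caps the internal step so accuracy does not degrade on coarse
  ## output grids (the rk dense output
  ## interpolation is the accuracy floor otherwise)
  sol <- deSolve::ode(c(xb0, xa0), t_span, rhs, NULL, method = "ode45",
                      rtol = rtol, atol = atol, hmax = 0.25)
  below <- sol[, 2:(j + 1L), drop = FALSE]
  above <- sol[, (j + 2L):(n + 2L), drop = FALSE]
  if (any(below < -1e-12 * max(abs(grid$density))) ||
      any(above < -1e-12 * max(abs(grid$density))))
    stop("packet density went negative beyond solver noise")
  structure(list(time = t_span,
                 X1 = drop(below %*% wb), X2 = drop(above %*% wa),
                 below = below, above = above,
                 split = j, G = G, G_snapped = Gsn,
                 f_tilde = f_tilde_const, P_input = P_input, grid = grid),
            class = "packet_run")
}

#' Compare the density evolution with the two-compartment reduction
#'
#' Integrates the reduced two-compartment system at the same constant
#' glucose (boundary terms vanish since \eqn{\dot G = 0}):
#' \deqn{\dot X_1 = -p_9 X_1 + \tilde f A_0 (X_1 + X_2)
#'   - \tilde f \bar X_{max} X_1 + f A_0 P(t),}
#' \deqn{\dot X_2 = \tilde f B_0 (X_1 + X_2)
#'   - \tilde f \bar X_{max} X_2 + f B_0 P(t),}
#' with \eqn{A_0, B_0} the analytic integrals of the initial density below
#' and above the snapped threshold (truncated at `theta_max`), and reports
#' the sup-norm relative discrepancy against the grid run's quadrature
#' masses. At constant glucose the reduction is exact, so the discrepancy
#' measures the trapezoid discretization (second order in the node spacing)
#' plus solver tolerance.
#'
#' @param run a `packet_run` from [evolve_density()].
#' @param rtol,atol tolerances for the reduced system's solver.
#' @return List with `sup_rel_X1`, `sup_rel_X2`, `sup_rel` (their maximum),
#'   `X1_grid`, `X2_grid`, `X1_reduced`, `X2_reduced`, `A0`, `B0`, `time`.
#' @examples
#' \donttest{
#' g <- packet_grid(islet_parameters(), n_nodes = 1000)
#' run <- evolve_density(g, G = 150, t_span = 50)
#' reduce_and_compare(run)$sup_rel
#' }
#' @export
reduce_and_compare <- function(run, rtol = 1e-12, atol = 1e-18) {
  stopifnot(inherits(run, "packet_run"))
  params <- run$grid$params
  cum <- function(g) params$Xbar_max * .pospow(g, params$k) /
    (params$C^params$k + .pospow(g, params$k))
  A0 <- cum(run$G_snapped)
  B0 <- cum(run$grid$theta_max) - cum(run$G_snapped)
  ft <- run$f_tilde
  rhs <- function(t, y, parms) {
    Xinf <- y[1] + y[2]
    Pin <- run$P_input(t)
    list(c(-params$p9 * y[1] + ft * A0 * Xinf -
             ft * params$Xbar_max * y[1] + params$f * A0 * Pin,
           ft * B0 * Xinf - ft * params$Xbar_max * y[2] +
             params$f * B0 * Pin))
  }
  sol <- deSolve::ode(c(A0, B0), run$time, rhs, NULL, method = "ode45",
                      rtol = rtol, atol = atol, hmax = 0.25)
  X1r <- sol[, 2]
  X2r <- sol[, 3]
  e1 <- max(abs(run$X1 - X1r) / pmax(abs(X1r), 1e-300))
  e2 <- max(abs(run$X2 - X2r) / pmax(abs(X2r), 1e-300))
  list(sup_rel_X1 = e1, sup_rel_X2 = e2, sup_rel = max(e1, e2),
       X1_grid = run$X1, X2_grid = run$X2,
       X1_reduced = X1r, X2_reduced = X2r,
       A0 = A0, B0 = B0, time = run$time)
}

#' One-call oracle check
#'
#' Convenience wrapper: build the grid, evolve the density at constant
#' glucose, reduce and compare, and return a pass/fail report against a
#' tolerance.
#'
#' @inheritParams provision_steady_state
#' @param G constant glucose concentration, mg/100ml.
#' @param n_nodes number of threshold grid nodes.
#' @param horizon run length in minutes.
#' @param tol maximal accepted sup-norm relative discrepancy.
#' @return List with `sup_rel`, `pass`, `n_nodes`, `G`, `horizon` and the
#'   full comparison report under `detail`.
#' @export
oracle_check <- function(params = islet_parameters(), G = 150,
                         n_nodes = 2000, horizon = 200, tol = 1e-4) {
  grid <- packet_grid(params, n_nodes = n_nodes)
  run <- evolve_density(grid, G, t_span = horizon)
  rep <- reduce_and_compare(run)
  list(sup_rel = rep$sup_rel, pass = rep$sup_rel < tol,
       n_nodes = n_nodes, G = G, horizon = horizon, detail = rep)
}
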