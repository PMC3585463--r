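## Steady states, Jacobian, stability ----------------------------------------

#' Glucose threshold of the cell cycle
#'
#' The glucose concentration \eqn{\hat G = (p_4 - p_1)/(p_1 p_5)} at which
#' the glucose-enhanced G1->S transition exactly balances apoptosis. Above it
#' the beta-cell population grows, below it the population decays; with the
#' default parameters it evaluates to 79.82 mg/100ml.
#'
#' @inheritParams provision_steady_state
#' @return Threshold in mg/100ml.
#' @examples
#' round(glucose_threshold(islet_parameters()))  # 80
#' @export
glucose_threshold <- function(params) {
  if (params$p4 <= params$p1)
    stop("p4 > p1 required for a positive glucose threshold")
  (params$p4 - params$p1) / (params$p1 * params$p5)
}

## per-component magnitude scales used for residual normalisation, Jacobian
## steps and Jacobian balancing; taken from the closed-form non-trivial
## steady-state seed (the state spans ~14 orders of magnitude)
.state_scales <- function(params) {
  s <- abs(.f2_seed(params))
  pmax(s, 1e-12)
}

## closed-form seed for the non-trivial steady state: G, I, X1, P are forced
## by Gdot = Idot = Pdot = 0; G1 follows from d(X1+X2)/dt = 0, the cell-cycle
## components from their fixed-point ratios, X2 from dX1 = 0 at Gdot = 0
.f2_seed <- function(params) {
  Gs <- glucose_threshold(params)
  Is <- (params$p6 - params$p7 * Gs) / (params$p8 * Gs)
  X1s <- params$bv * params$p10 * Is / params$p9
  Ps <- provision_steady_state(Gs, params)
  G1s <- params$p9 * X1s / (params$p12 * params$f * Ps)
  Ss <- params$p4 * G1s / params$p2
  G2Ms <- params$p4 * G1s / params$p3
  ab <- compartment_integrals(Gs, G1s, params)
  ft <- redistribution_factor(Gs, G1s, params)
  X2s <- (params$p9 * X1s + ft * ab$B * X1s - params$f * ab$A * Ps) /
    (ft * ab$A)
  stats::setNames(c(G1s, Ss, G2Ms, Gs, Is, X1s, X2s, Ps), .state_names)
}

## residual norm: max_i |f_i(x)| / max(|x_i|, scale_i)
.residual_norm <- function(state, params, scales = .state_scales(params)) {
  r <- rhs_full(0, state, params)
  max(abs(r) / pmax(abs(state), scales))
}

.new_steady_state <- function(label, state, params, converged = TRUE,
                              seeds = NULL) {
  scales <- .state_scales(params)
  res <- .residual_norm(state, params, scales)
  J <- model_jacobian(state, params)
  ev <- eigen(.balance(J, scales), only.values = TRUE)$values
  cls <- .classify(ev)
  structure(list(label = label, state = state, residual_norm = res,
                 jacobian = J, eigenvalues = ev, classification = cls,
                 converged = converged, seeds = seeds, params = params),
            class = "islet_steady_state")
}

## similarity transform D^-1 J D with D = diag(scales); preserves the
## spectrum exactly while collapsing the ~1e14 dynamic range between cell
## counts and insulin masses that would otherwise corrupt the eigensolve
.balance <- function(J, scales) {
  sweep(sweep(J, 1, scales, "/"), 2, scales, "*")
}

.classify <- function(ev, tol_factor = 1e-12) {
  tol <- tol_factor * max(Mod(ev))
  re <- Re(ev)
  if (all(re < -tol)) "stable"
  else if (any(re > tol)) "unstable"
  else "marginal"
}

#' Trivial steady state
#'
#' The fixed point with all cell counts at zero:
#' \eqn{F_1^* = (0, 0, 0, p_6/p_7, 0, 0, 0, P_\infty(p_6/p_7))}. Glucose
#' settles at the insulin-free balance `p6/p7` (100 mg/100ml with defaults);
#' the provision factor at its Hill steady state there. The right-hand side
#' vanishes identically at this state. With the default parameters the point
#' is unstable: any remaining beta cell grows the population because
#' `p6/p7` exceeds the glucose threshold.
#'
#' @inheritParams provision_steady_state
#' @return An `islet_steady_state` object: fields `label`, `state`,
#'   `residual_norm`, `jacobian`, `eigenvalues`, `classification`,
#'   `converged`.
#' @export
trivial_steady_state <- function(params) {
  Gs <- params$p6 / params$p7
  st <- stats::setNames(c(0, 0, 0, Gs, 0, 0, 0,
                          provision_steady_state(Gs, params)), .state_names)
  .new_steady_state("trivial", st, params)
}

#' Non-trivial steady state
#'
#' The physiological fixed point \eqn{F_2^*}. Four components are forced by
#' closed forms: \eqn{G^* = \hat G}, \eqn{I^* = (p_6 - p_7 G^*)/(p_8 G^*)},
#' \eqn{X_1^* = bv\, p_{10} I^*/p_9}, \eqn{P^* = P_\infty(G^*)}. The
#' remaining four (`G1`, `S`, `G2M`, `X2`) are obtained by damped Newton
#' iteration on the full right-hand side with the pinned components held
#' fixed, seeded by the closed-form fixed-point relations
#' (\eqn{G_1^* = p_9 X_1^*/(p_{12} f P^*)}, \eqn{S^* = p_4 G_1^*/p_2},
#' \eqn{G_2/M^* = p_4 G_1^*/p_3} and \eqn{X_2^*} from \eqn{\dot X_1 = 0}).
#' If Newton stalls, a long-horizon integration fallback refines the root.
#' Convergence requires a scaled residual below `tol`.
#'
#' @inheritParams provision_steady_state
#' @param tol convergence tolerance on the scaled residual norm.
#' @param max_iter maximal number of Newton steps.
#' @return An `islet_steady_state` object (see [trivial_steady_state()]);
#'   `seeds` records the closed-form seed vector.
#' @examples
#' f2 <- nontrivial_steady_state(islet_parameters())
#' f2$state[["G"]]          # equals glucose_threshold()
#' f2$classification        # "stable"
#' @export
nontrivial_steady_state <- function(params, tol = 1e-8, max_iter = 50L) {
  viol <- validate_parameters(params)
  if (nrow(viol))
    stop("invalid parameters: ", paste(viol$message, collapse = "; "))
  Gs <- glucose_threshold(params)
  Is <- (params$p6 - params$p7 * Gs) / (params$p8 * Gs)
  if (Is <= 0)
    stop("I* <= 0: non-trivial steady state requires Ghat < p6/p7")
  seed <- .f2_seed(params)
  free <- c(1L, 2L, 3L, 7L)  # G1, S, G2M, X2
  scales <- .state_scales(params)
  state <- seed
  resid <- function(st) rhs_full(0, st, params)[free]
  r <- resid(state)
  for (it in seq_len(max_iter)) {
    if (max(abs(r) / pmax(abs(state[free]), scales[free])) < tol * 1e-2) break
    ## finite-difference Jacobian of the free residuals
    Jf <- matrix(0, 4, 4)
    for (j in seq_along(free)) {
      hstep <- 1e-7 * max(abs(state[free[j]]), scales[free[j]])
      up <- state; up[free[j]] <- up[free[j]] + hstep
      dn <- state; dn[free[j]] <- dn[free[j]] - hstep
      Jf[, j] <- (resid(up) - resid(dn)) / (2 * hstep)
    }
    step <- tryCatch(solve(Jf, -r), error = function(e) NULL)
    if (is.null(step)) break
    lambda <- 1
    repeat {
      cand <- state
      cand[free] <- state[free] + lambda * step
      if (all(cand[free] >= 0)) {
        rc <- tryCatch(resid(cand), error = function(e) NULL)
        if (!is.null(rc) && all(is.finite(rc)) &&
            sum((rc / scales[free])^2) <= sum((r / scales[free])^2)) {
          state <- cand; r <- rc; break
        }
      }
      lambda <- lambda / 2
      if (lambda < 1e-8) break
    }
    if (lambda < 1e-8) break
  }
  if (.residual_norm(state, params, scales) >= tol) {
    ## fallback: relax toward the attractor by integration, then re-seed
    traj <- deSolve::ode(state, c(0, 1e6), .rhs_desolve, params,
                         method = "lsoda", rtol = 1e-10,
                         atol = scales * 1e-10)
    state <- stats::setNames(traj[nrow(traj), -1], .state_names)
    state[c(4L, 5L, 6L, 8L)] <- seed[c(4L, 5L, 6L, 8L)]
  }
  conv <- .residual_norm(state, params, scales) < tol
  if (!conv)
    warning(sprintf("non-trivial steady state did not converge: residual %.3e",
                    .residual_norm(state, params, scales)))
  .new_steady_state("nontrivial", state, params, converged = conv,
                    seeds = seed)
}

#' Both steady states
#'
#' Convenience wrapper returning the trivial and the non-trivial steady-state
#' reports in one list.
#'
#' @inheritParams provision_steady_state
#' @return List with elements `trivial` and `nontrivial`.
#' @export
steady_states <- function(params) {
  list(trivial = trivial_steady_state(params),
       nontrivial = nontrivial_steady_state(params))
}

#' Finite-difference Jacobian of the full model
#'
#' Central finite differences of [rhs_full()] with per-component step
#' `eps_rel * max(|x_i|, scale_i)`, where the component scales are taken
#' from the closed-form non-trivial steady-state seed (documented magnitudes
#' spanning cell counts to insulin masses).
#'
#' @param state numeric state vector of length 8.
#' @inheritParams provision_steady_state
#' @param eps_rel relative step size, in `(1e-10, 1e-2)`.
#' @return An 8x8 matrix with rows/columns in [state_names()] order.
#' @export
model_jacobian <- function(state, params, eps_rel = 1e-6) {
  stopifnot(length(state) == 8L, eps_rel > 1e-10, eps_rel < 1e-2)
  scales <- .state_scales(params)
  J <- matrix(0, 8, 8, dimnames = list(.state_names, .state_names))
  y <- as.numeric(state)
  for (j in seq_len(8L)) {
    hstep <- eps_rel * max(abs(y[j]), scales[j])
    up <- y; up[j] <- y[j] + hstep
    dn <- y; dn[j] <- max(y[j] - hstep, if (j == 4L) .G_min * 2 else 0)
    J[, j] <- (rhs_full(0, up, params) - rhs_full(0, dn, params)) /
      (up[j] - dn[j])
  }
  bad <- which(!is.finite(J), arr.ind = TRUE)
  if (nrow(bad))
    stop("non-finite Jacobian entries at (row, column): ",
         paste(apply(bad, 1, paste, collapse = ","), collapse = "; "))
  J
}

#' Stability classification of a steady state
#'
#' Classifies a fixed point from the eigenvalues of its Jacobian, computed on
#' a row/column-balanced matrix (a similarity transform, so the spectrum is
#' unchanged). The label is `"stable"` when all real parts are below
#' `-tol`, `"unstable"` when any exceeds `+tol`, and `"marginal"` otherwise,
#' with `tol = 1e-12` times the spectral radius.
#'
#' @param x an `islet_steady_state` object, or a numeric state vector (in
#'   which case `params` must be supplied).
#' @inheritParams provision_steady_state
#' @return Character label `"stable"`, `"unstable"` or `"marginal"`.
#' @export
classify_stability <- function(x, params = NULL) {
  if (inherits(x, "islet_steady_state")) return(.classify(x$eigenvalues))
  stopifnot(!is.null(params))
  scales <- .state_scales(params)
  ev <- eigen(.balance(model_jacobian(x, params), scales),
              only.values = TRUE)$values
  .classify(ev)
}

#' @export
print.islet_steady_state <- function(x, ...) {
  cat(sprintf("%s steady state (%s, residual %.2e%s)\n", x$label,
              x$classification, x$residual_norm,
              if (x$converged) "" else ", NOT converged"))
  print(signif(x$state, 6))
  cat("eigenvalue real parts:\n")
  print(signif(sort(Re(x$eigenvalues)), 4))
  invisible(x)
}
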