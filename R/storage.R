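## Insulin storage algebra ----------------------------------------------------
##
## All closed-form pieces of the packet-distribution storage model: the
## provision steady state P_inf(G), the capacity Xmax, the target packet
## density and its cumulative, the two compartment integrals, the
## redistribution factor f~ and the four transition functions u1..u4.
## Powers with real exponents (k = 3.3, h = 5) are evaluated through exp/log
## for positive arguments and defined as 0 at the origin (valid since k > 1).

## x^a for x >= 0, a > 0, with 0^a := 0; avoids NaN from pow at the origin
.pospow <- function(x, a) {
  out <- numeric(length(x))
  pos <- x > 0
  out[pos] <- exp(a * log(x[pos]))
  out
}

#' Provision steady state
#'
#' The glucose-dependent steady state of the insulin provision factor,
#' a Hill function \eqn{P_\infty(G) = G^h / (P_0^h + G^h)} with
#' half-saturation at `P0`.
#'
#' @param G glucose concentration(s), mg/100ml, non-negative.
#' @param params an [islet_parameters()] object.
#' @return Value(s) in `[0, 1)`.
#' @examples
#' p <- islet_parameters()
#' provision_steady_state(p$P0, p)  # 0.5
#' @export
provision_steady_state <- function(G, params) {
  if (any(!is.finite(G)) || any(G < 0)) stop("G must be non-negative and finite")
  gh <- .pospow(G, params$h)
  gh / (params$P0^params$h + gh)
}

#' Storage capacity for a given beta-cell mass
#'
#' Maximal amount of insulin the pancreas can store when `G1` cells are in
#' G1 phase: \eqn{X_{max} = p_{12} G_1}.
#'
#' @param G1 cell count(s) in G1 phase, non-negative.
#' @inheritParams provision_steady_state
#' @return Insulin mass (mg).
#' @export
storage_capacity <- function(G1, params) {
  if (any(!is.finite(G1)) || any(G1 < 0)) stop("G1 must be non-negative and finite")
  params$p12 * G1
}

#' Cumulative target insulin below a glucose threshold
#'
#' The target amount of stored insulin in packets with release threshold
#' below `G`: \eqn{X^*(G) = X_{max}(G_1)\, G^k / (C^k + G^k)}. Monotone
#' non-decreasing in `G`, saturating at the capacity.
#'
#' @param G glucose concentration(s), mg/100ml, non-negative.
#' @param G1 cell count in G1 phase, non-negative scalar.
#' @inheritParams provision_steady_state
#' @return Insulin mass (mg).
#' @export
target_cumulative <- function(G, G1, params) {
  if (any(!is.finite(G)) || any(G < 0)) stop("G must be non-negative and finite")
  gk <- .pospow(G, params$k)
  storage_capacity(G1, params) * gk / (params$C^params$k + gk)
}

#' Target packet density
#'
#' Density of the target packet distribution over the release-threshold axis,
#' the derivative of [target_cumulative()]:
#' \eqn{\xi^*(\theta) = X_{max} k C^k \theta^{k-1} / (C^k + \theta^k)^2}.
#'
#' @param theta release threshold(s), mg/100ml, non-negative.
#' @inheritParams target_cumulative
#' @return Density in mg per (mg/100ml); zero at `theta = 0` since `k > 1`.
#' @export
target_density <- function(theta, G1, params) {
  if (any(!is.finite(theta)) || any(theta < 0))
    stop("theta must be non-negative and finite")
  Ck <- params$C^params$k
  tk <- .pospow(theta, params$k)
  storage_capacity(G1, params) * params$k * Ck *
    .pospow(theta, params$k - 1) / (Ck + tk)^2
}

#' Releasable- and non-releasable-side integrals of the target density
#'
#' Closed forms of the two compartment integrals of the target density:
#' \eqn{A = \int_0^G \xi^* d\theta = X_{max} G^k/(C^k+G^k)} and
#' \eqn{B = \int_G^\infty \xi^* d\theta = X_{max} C^k/(C^k+G^k)}.
#' The identity `A + B = Xmax` holds exactly.
#'
#' @inheritParams target_cumulative
#' @return List with numeric components `A` and `B` (mg).
#' @export
compartment_integrals <- function(G, G1, params) {
  if (any(!is.finite(G)) || any(G < 0)) stop("G must be non-negative and finite")
  Ck <- params$C^params$k
  gk <- .pospow(G, params$k)
  Xm <- storage_capacity(G1, params)
  list(A = Xm * gk / (Ck + gk), B = Xm * Ck / (Ck + gk))
}

## the common denominator of f~ and u1/u2:
## D(G) = f G^h (1 + C^k G^-k) - p9 (P0^h + G^h);
## strictly negative for all G > 0 whenever f < p9
.storage_denominator <- function(G, params) {
  gh <- .pospow(G, params$h)
  params$f * gh * (1 + params$C^params$k * .pospow(G, -params$k)) -
    params$p9 * (params$P0^params$h + gh)
}

#' Redistribution factor
#'
#' The glucose-dependent rate factor \eqn{\tilde f(G, G_1)} that reshuffles
#' stored packets toward the target distribution,
#' \deqn{\tilde f = \frac{-p_9 f C^k G^{h-k}}
#'   {X_{max}(G_1)\,[f G^h (1 + C^k G^{-k}) - p_9 (P_0^h + G^h)]}.}
#' It is constructed so that the storage capacity bound
#' \eqn{X_1 + X_2 \le X_{max}} holds in steady state. For `f < p9` the
#' bracketed denominator is strictly negative for every `G > 0`, so the
#' factor is finite and positive. Scales as `1/G1`.
#'
#' @param G glucose concentration(s), mg/100ml, strictly positive.
#' @param G1 cell count in G1 phase, strictly positive scalar.
#' @inheritParams provision_steady_state
#' @return Rate factor, 1/(mg min) scale.
#' @export
redistribution_factor <- function(G, G1, params) {
  if (any(!is.finite(G)) || any(G <= 0)) stop("G must be strictly positive")
  if (!is.finite(G1) || G1 <= 0) stop("G1 must be strictly positive")
  den <- storage_capacity(G1, params) * .storage_denominator(G, params)
  if (any(abs(den) < 1e-300))
    stop("redistribution factor denominator vanishes (is f < p9?)")
  -params$p9 * params$f * params$C^params$k * .pospow(G, params$h - params$k) /
    den
}

#' Transition functions of the storage model
#'
#' The four glucose-dependent transition functions in which the storage
#' dynamics can be written, given here in their closed forms. They satisfy
#' the identities `u1 = f~ * B`, `u2 = f~ * A` (independent of `G1`: the cell
#' count cancels), `u3 * G1 = f * A` and `u4 * G1 = f * B`, where `A`, `B`
#' are the [compartment_integrals()].
#'
#' @param G glucose concentration(s), mg/100ml, strictly positive.
#' @inheritParams provision_steady_state
#' @return List with numeric components `u1`, `u2`, `u3`, `u4`.
#' @export
transition_functions <- function(G, params) {
  if (any(!is.finite(G)) || any(G <= 0)) stop("G must be strictly positive")
  Ck <- params$C^params$k
  gk <- .pospow(G, params$k)
  den <- .storage_denominator(G, params) * (Ck + gk)
  pref <- -params$p9 * params$f
  list(
    u1 = pref * .pospow(G, params$h - params$k) * Ck * Ck / den,
    u2 = pref * .pospow(G, params$h) * Ck / den,
    u3 = params$f * params$p12 * gk / (Ck + gk),
    u4 = params$f * params$p12 * Ck / (Ck + gk)
  )
}
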