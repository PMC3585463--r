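---
title: "A coupled glucose–insulin and β-cell-cycle model: methods and numerical choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{A coupled glucose–insulin and β-cell-cycle model: methods and numerical choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(isletdyn)
```

## Scope

`isletdyn` simulates an eight-state ODE model of the glucose–insulin
regulatory system in which the pancreatic β-cell cycle, the blood
compartment, and a threshold-packet insulin storage are mechanistically
coupled. This vignette documents the model and its assumptions, the
meaning and defaults of every tunable parameter, the numerical choices
made in the implementation, and the limits of what the accompanying tests
demonstrate.

## The model

### β-cell cycle

The cell population is split into the growth phase `G1` (assumed to hold
the entire functioning, insulin-producing mass), the DNA-synthesis phase
`S`, and the combined premitosis/mitosis phase `G2M` (flow cytometry
cannot separate G2 from M, so they are modelled as one pool):

$$\dot G_1 = 2 p_3 G_{2M} - \bigl(p_1 (1 + p_5 G) + p_4\bigr) G_1,\quad
\dot S = p_1 (1 + p_5 G) G_1 - p_2 S,\quad
\dot G_{2M} = p_2 S - p_3 G_{2M}.$$

Glucose accelerates the G1→S checkpoint linearly — a deliberate
simplification of the dose–response of β-cell replication. The factor 2
encodes cell division on re-entry into G1, and `p4` lumps apoptosis and
necrosis into one constant loss rate (glucose-toxicity-dependent apoptosis
is deliberately out of scope). Replication balances loss exactly at the
glucose threshold

$$\hat G = \frac{p_4 - p_1}{p_1 p_5} \approx 79.82\ \mathrm{mg/100ml},$$

the single most interpretive quantity of the model: sustained glucose
above `Ĝ` grows the β-cell mass, below it the mass decays.

### Blood compartment

$$\dot G = p_6 - (p_7 + p_8 I)\, G, \qquad
\dot I = \frac{p_9}{bv} X_1 - p_{10} I.$$

`p6` is the net constant hepatic production (minus concentration-
independent uptake by nervous tissue), `p7` the insulin-independent
glucose effectiveness, `p8` the insulin sensitivity of muscle and fat
(the dial for type-2-like scenarios). Secretion empties the releasable
store `X1` at rate `p9`, diluted by the blood volume `bv`; the `1/bv`
factor is applied verbatim with `bv` in ml while concentrations are per
100 ml — the defaults were evidently tuned under this convention, and no
hidden unit conversion is introduced.

### Insulin storage

Following the classic threshold-packet (Grodsky) picture, stored insulin
sits in packets with individual glucose release thresholds θ, here
interpreted as β cells that are active or inactive. The target packet
density the storage relaxes toward is the derivative of a sigmoid
dose–response curve,

$$\xi^*(\theta) = X_{max}\, \frac{k C^k \theta^{k-1}}{(C^k + \theta^k)^2},
\qquad X_{max} = p_{12}\, G_1,$$

so the capacity scales with the current β-cell mass. Packets with
threshold below the current glucose form the releasable pool
$X_1 = \int_0^G \xi\,d\theta$, the rest the non-releasable pool `X2`. The
compartment dynamics are

$$\dot X_1 = X_1 \frac{\xi^*(G)}{A}\dot G - p_9 X_1
 + \tilde f (A X_2 - B X_1) + f A P,$$
$$\dot X_2 = -X_2 \frac{\xi^*(G)}{B}\dot G
 + \tilde f (B X_1 - A X_2) + f B P,\qquad
\dot P = p_{11}\bigl(P_\infty(G) - P\bigr),$$

with the closed-form integrals
$A = X_{max} G^k/(C^k + G^k)$, $B = X_{max} C^k/(C^k + G^k)$
(so $A + B = X_{max}$ exactly), the provision steady state
$P_\infty(G) = G^h/(P_0^h + G^h)$, and the redistribution factor

$$\tilde f(G, G_1) = \frac{-p_9 f C^k G^{h-k}}
 {X_{max}(G_1)\bigl[f G^h (1 + C^k G^{-k}) - p_9 (P_0^h + G^h)\bigr]},$$

constructed so that the capacity bound $X_1 + X_2 \le X_{max}$ holds in
steady state. For `f < p9` the bracket is strictly negative for every
positive glucose value, making `f̃` finite and positive; this is enforced
as a parameter invariant.

Two modelling caveats are accepted at face value. First, the provision
factor `P` is dimensionless (its steady state lies in `[0, 1]`) yet `f A P`
enters the mass balance as a rate; the implied time constant is absorbed
into `f`. Second, the two boundary terms (the $\dot G$ terms, which move
packets across the threshold as glucose sweeps the axis) are not
equal-and-opposite unless $X_1/A = X_2/B$, so the boundary exchange does
not conserve `X1 + X2` pointwise when glucose is moving. This is a
property of the reduction itself, not of the implementation, and is left
as printed; the redistribution terms, by contrast, conserve the total
exactly, which the tests assert.

### Equivalent formulations

The storage dynamics can equivalently be written through four transition
functions `u1 = f̃B`, `u2 = f̃A` (independent of `G1` — the cell mass
cancels) and `u3·G1 = fA`, `u4·G1 = fB`. The package treats the
compartment-balance form above, assembled from the closed-form integrals,
as canonical, and keeps the `u`-functions only as algebraic cross-checks
(`transition_functions()`, verified against the canonical quantities at
randomized inputs in the test suite). The reason is robustness: the
grouped `u`-form is easy to mistranscribe, while the balance form plus the
identity $A + B = X_{max}$ is unambiguous.

A practical consequence of the same algebra: all `G1`-dependent factors in
the right-hand side appear only in the cancelled combinations `f̃A`,
`f̃B`, `ξ*/A`, `ξ*/B`, which are independent of `G1`. The implementation
evaluates these cancelled forms, so the rates extend continuously to
`G1 = 0` and the trivial steady state evaluates to an exactly zero
right-hand side instead of `0/0`.

## Parameters

`islet_parameters()` returns the defaults; all rates are per minute,
concentrations in mg/100ml, masses in mg.

| field | default | meaning |
|---|---|---|
| p1, p2, p3 | 6.0594e-5, 4.9861e-3, 8.9444e-4 | cycle transitions G1→S, S→G2/M, G2/M→G1 |
| p4 | 3.3194e-4 | apoptosis (must exceed p1) |
| p5 | 0.0561 | glucose influence on the G1→S rate, 100ml/mg |
| p6 | 0.3 | net glucose production, mg/(100ml·min) |
| p7 | 0.003 | glucose effectiveness at zero insulin |
| p8 | 0.36 | insulin sensitivity, 100ml/(mg·min) |
| p9 | 0.622 | insulin secretion rate |
| p10 | 0.3 | insulin decay rate |
| p11 | 0.0337 | provision relaxation rate |
| p12 | Xbar_max/G1_0 | insulin per β cell, mg (see below) |
| bv | 3.33 | blood volume, ml (a ~35 g mouse) |
| f | 0.5 | provision proportionality factor (must stay below p9) |
| h, P0 | 5, 186.506 | Hill shape of the provision steady state |
| Xbar_max | 1.65e-3 | maximal stored insulin per pancreas, mg |
| k, C | 3.3, 149.78 | Hill shape of the packet distribution |
| G1_0 | 958000 | reference G1 count normalising the capacity |

`p12` is defined as insulin amount per β cell with the initial G1 count as
normalisation. The package recomputes it at construction as
`Xbar_max / G1_0` (≈ 1.7223e-9 mg, within 0.2 % of the rounded catalogue
value 1.72e-9) so that the storage capacity at the reference cell count
equals `Xbar_max` *exactly* and the target distribution integrates to the
stated pancreas maximum; `use_printed_p12 = TRUE` restores the rounded
value verbatim for users who want the catalogue numbers untouched.

One parameterisation caveat is inherited as-is: the blood volume is that
of a mouse while the infusion scenario mimics a rat experiment. The
defaults are used as stated, since the model is qualitative at that level.

## Steady states and stability

Setting the blood and provision equations to zero forces
`G* = Ĝ`, `I* = (p6 − p7 G*)/(p8 G*)`, `X1* = bv p10 I*/p9` and
`P* = P∞(G*)`. Requiring `d(X1+X2)/dt = 0` then fixes the cell mass,
`G1* = p9 X1*/(p12 f P*)`, the cycle ratios give `S*` and `G2M*`, and
`Ẋ1 = 0` gives `X2*`. Although these closed forms turn out to be an exact
fixed point, `nontrivial_steady_state()` treats them only as seeds for a
damped Newton iteration on the four non-pinned components (with a
long-horizon integration fallback): the converged residual of the full
right-hand side — required below `1e-8` in scaled norm — is the
authority, not the algebra. This guards against transcription errors in
exactly the place they would be hardest to notice.

The Jacobian is computed by central finite differences with per-component
steps `eps_rel · max(|x_i|, scale_i)`; the component scales are taken from
the closed-form seed, since the state spans ~14 orders of magnitude
between cell counts (1e8) and insulin masses (1e-3). For the eigensolve
the Jacobian is balanced by the same scales (a similarity transform, so
the spectrum is untouched) before `eigen()` is applied. Classification
uses a tolerance of `1e-12` times the spectral radius on the real parts;
the labels are invariant across `eps_rel` in `[1e-7, 1e-4]`, which the
tests check.

With the defaults, the trivial state (no β cells, glucose at
`p6/p7 = 100` mg/100ml) is unstable — its glucose level sits above `Ĝ`,
so any residual cell population grows — and the physiological state is
stable, with slowest eigenvalue ≈ `-1.5e-5`/min. That time constant
(~6.6e4 min, i.e. ~46 days) is the β-cell-mass adaptation scale and
matters for simulation horizons: from the default initial state, which
lies two orders of magnitude below the steady-state cell mass,
equilibration to sub-0.1 % accuracy takes on the order of `5e5`–`1e6`
minutes. The test suite verifies the approach in two steps: the glucose
gap to `G*` shrinks monotonically over the last decade of a `1e5`-minute
run, and a `1e6`-minute run lands within `1e-4` of the fixed point
component-wise.

## Positivity

Because all states are biological quantities, solutions started positive
must stay positive. The standard boundary condition — each component's
rate, evaluated where that component is zero and all others are positive,
must be positive — holds structurally for this model (e.g. the glucose
rate at `G = 0` is the constant production `p6`; the `X1` rate at
`X1 = 0` is `f̃AX2 + fAP > 0`). `check_positivity()` verifies it by seeded
Monte-Carlo sampling over documented ranges covering all simulated
regimes (cells 1–1e9, glucose 1–600 mg/100ml, insulin 1e-6–1 mg/100ml,
stored masses 1e-9–1e-2 mg, provision 1e-6–1; default seed 20121119,
1e4 samples in the acceptance suite). Positivity along every built-in
scenario trajectory is asserted separately.

## Time integration

`simulate_islet()` uses `deSolve`'s Dormand–Prince 4(5) pair
(`method = "ode45"`) with `rtol = 1e-8` and per-component absolute
tolerances (`1e-3` cells, `1e-10` concentrations, `1e-14` masses, `1e-12`
provision), sampling on a fixed output grid (1 min up to 24 h horizons,
10 min beyond) via dense output, so results do not depend on internal
stepping. `"lsoda"` is the recommended method for multi-week horizons.

Three guard rails apply. (1) Glucose at or below `1e-6` mg/100ml raises an
error: the boundary ratio `ξ*/A ~ k/G` is singular at zero glucose, and
biologically glucose stays positive under constant hepatic production.
(2) The solution is never clipped: any accepted output below `-1e-12`
fails the run, because positivity is a model property to be verified, not
enforced. (3) Trial stages of the adaptive integrator may transiently
overshoot a fast-decaying component below zero; the solver-facing wrapper
therefore evaluates the right-hand side on the continuous extension
`f(max(y, 0))`, which coincides with the model on the admissible region
and keeps such stages from aborting the run — rule (2) still applies to
everything the solver accepts.

Real-exponent powers (`k = 3.3`, `h = 5`) are evaluated through
`exp/log` for positive arguments and defined as 0 at the origin (valid
since `k > 1`), avoiding `NaN` from `pow` at `θ = 0`.

## The built-in scenarios

The four scenarios are the package's study conditions, fixed once:

* `physiological` — defaults, high initial glucose 200 mg/100ml, 120 min.
  Glucose falls monotonically and is still above `Ĝ` at 120 min; `X1` is
  biphasic (initial stored-release peak, minimum near 7 min,
  provision-driven maximum near 71 min); `X2` rises late; the cell cycle
  barely moves within two hours.
* `infusion` — production raised to `p6 = 8.6806` mg/(100ml·min) for 96 h,
  emulating a sustained high-glucose infusion; the β-cell mass expands
  under the persistent hyperglycemia.
* `type2` — insulin sensitivity cut to `p8 = 360e-5` for 120 min; glucose
  dominates the physiological curve pointwise.
* `type1` — apoptosis multiplied by 10 for 96 h. The multiplier is a
  modelling choice (any factor pushing the loss rate well past the
  replication rate gives the same qualitative decay) and is exposed as an
  argument.

On biphasic detection: the model's first-phase peak is the *initial* value
of `X1` — stored insulin begins discharging immediately — so it sits on
the boundary of the record rather than at an interior turning point.
`find_local_extrema()` therefore reports interior extrema by default and
offers `include_boundary = TRUE`, which the biphasic checks use; extrema
are filtered by topographic prominence relative to the series range.

## The distribution-level oracle

The two-compartment storage ODEs are a reduction of packet-density
dynamics over the threshold axis. At constant glucose the reduction is
exact, which yields a genuinely independent verification route:

1. `packet_grid()` discretizes the initial density on a uniform grid over
   `[0, 2000]` mg/100ml. The truncated tail carries a relative mass of
   `C^k/(C^k + θ_max^k) ≈ 1.9e-4`, asserted below `1e-3`.
2. `evolve_density()` integrates one linear ODE per node (secretion decay
   below the threshold, none above; provision forcing `f ξ₀ P(t)`;
   redistribution `−f̃ X̄max ξ + f̃ ξ₀ X∞(t)` with `X∞` the running
   quadrature), with the redistribution factor frozen at
   `f̃(G, G1_0)` and, by default, a provision input relaxing toward
   `P∞(G)` at rate `p11`.
3. `reduce_and_compare()` integrates the reduced two-compartment system
   with *analytic* (truncated) integrals of the initial density and
   reports the sup-norm relative discrepancy against the quadrature
   masses of the grid run.

Numerical choices: the glucose threshold is snapped to the nearest grid
node, and that node is duplicated into both sub-grids — the density
develops a jump at the threshold, and integrating each smooth piece
separately keeps the trapezoid quadrature second-order. The solvers run
at `rtol = 1e-12` with the internal step capped at 0.25 min, because the
Runge–Kutta dense-output interpolation would otherwise set an accuracy
floor above the discretization error. With those settings the measured
discrepancy at `G = 150` mg/100ml over 200 min is `1.2e-5` at 2000 nodes
and drops fourfold per node doubling — pure trapezoid behaviour, which is
what certifies that the compartment reduction and the density dynamics
agree.

The oracle deliberately covers only constant glucose. For moving glucose
the reduction relies on a separable solution form whose fidelity has no
distribution-level specification to test against; this is recorded as a
limitation, not a failure.

## What the tests do and do not show

The suite (and `scripts/acceptance.R`) verifies: the threshold value, the
closed-form structure and residuals of both steady states, the stability
labels, boundary positivity and positivity along all four scenarios, the
qualitative trajectory shapes above, oracle agreement with its
convergence rate, and the long-horizon attractor property. Problem sizes
were chosen for precision, not speed limits: 1e4 positivity samples,
2000/4000 oracle nodes over 200 min, and `1e5`/`1e6`-minute long runs
under `lsoda` at `rtol = 1e-10`.

What passing does *not* show: the model is qualitative. No trajectory is
fit to measured data; parameter values are a literature-derived
consistent set, units mix mouse and rat provenance, and several
structural simplifications (constant apoptosis, hyperplasia-only mass
adaptation, no meals or exogenous insulin, no Ca²⁺/cAMP exocytosis
machinery) bound the biological claims to shape-level statements.
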