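## Time integration, scenarios, trajectory features ---------------------------

.default_atol <- function() {
  c(G1 = 1e-3, S = 1e-3, G2M = 1e-3, G = 1e-10, I = 1e-10,
    X1 = 1e-14, X2 = 1e-14, P = 1e-12)
}

#' Integrate the complete model
#'
#' Solves the eight-state system with an adaptive explicit Runge--Kutta
#' method (Dormand--Prince 4(5), `deSolve` method `"ode45"`, the same family
#' as Matlab's ODE45) and samples the solution on a fixed output grid via
#' dense output, so the reported values do not depend on the internal
#' adaptive steps. Default absolute tolerances are per component: `1e-3`
#' for cell counts, `1e-10` for concentrations, `1e-14` for stored masses
#' and `1e-12` for the provision factor.
#'
#' The run fails (rather than silently continuing) if the solver's state
#' leaves the admissible region: any component below `-1e-12`, glucose at or
#' below the guard rail `1e-6` mg/100ml, or non-finite values.
#'
#' @param params an [islet_parameters()] object.
#' @param init initial state, see [islet_initial_state()].
#' @param duration simulation horizon in minutes, strictly positive.
#' @param grid_dt output grid spacing in minutes. Default: 1 min for
#'   horizons up to 24 h, 10 min beyond.
#' @param method `deSolve` integration method; `"ode45"` by default,
#'   `"lsoda"` is a sensible choice for very long horizons.
#' @param rtol relative tolerance.
#' @param atol absolute tolerance, scalar or per-component vector of
#'   length 8.
#' @param scenario optional scenario metadata to record on the trajectory.
#' @return An object of class `islet_trajectory`: list with fields `time`
#'   (minutes), `state` (matrix, one row per grid point, columns in
#'   [state_names()] order), `params`, `scenario` and `solver` (method and
#'   tolerances).
#' @examples
#' traj <- simulate_islet(duration = 10)
#' head(as.data.frame(traj))
#' @export
simulate_islet <- function(params = islet_parameters(),
                           init = islet_initial_state(),
                           duration = 120,
                           grid_dt = NULL,
                           method = "ode45",
                           rtol = 1e-8,
                           atol = .default_atol(),
                           scenario = NULL) {
  if (!is.numeric(duration) || length(duration) != 1L || !is.finite(duration) ||
      duration <= 0)
    stop("duration must be a strictly positive number of minutes")
  if (length(init) != 8L) stop("init must have 8 components")
  init <- stats::setNames(as.numeric(init), .state_names)
  if (is.null(grid_dt)) grid_dt <- if (duration <= 1440) 1 else 10
  times <- seq(0, duration, by = grid_dt)
  if (times[length(times)] < duration) times <- c(times, duration)
  if (length(atol) == 1L) atol <- rep(atol, 8L)
  sol <- deSolve::ode(y = init, times = times, func = .rhs_desolve,
                      parms = params, method = method,
                      rtol = rtol, atol = atol)
  if (attr(sol, "istate")[1L] < 0 || nrow(sol) < length(times))
    stop("integration failed before reaching the requested horizon")
  state <- unname(sol[, -1, drop = FALSE])
  colnames(state) <- .state_names
  if (any(!is.finite(state)))
    stop("integration produced non-finite state values")
  if (any(state < -1e-12))
    stop("integration produced negative state values beyond solver noise")
  if (any(state[, "G"] <= .G_min))
    stop("glucose fell to the guard rail during integration")
  structure(list(time = times, state = state, params = params,
                 scenario = scenario,
                 solver = list(method = method, rtol = rtol, atol = atol,
                               grid_dt = grid_dt)),
            class = "islet_trajectory")
}

#' Built-in simulation scenarios
#'
#' The four study conditions shipped with the model:
#' \describe{
#'   \item{`physiological`}{default parameters and initial state (high
#'     initial glucose of 200 mg/100ml after food intake), 120 min.}
#'   \item{`infusion`}{sustained high glucose infusion, modelled by raising
#'     the production rate to `p6 = 8.6806` mg/(100ml min); 96 h.}
#'   \item{`type2`}{insulin resistance: insulin sensitivity lowered to
#'     `p8 = 360e-5`; 120 min.}
#'   \item{`type1`}{autoimmune beta-cell loss: apoptosis rate `p4`
#'     multiplied by `p4_multiplier` (default 10; the magnitude is a
#'     modelling choice, any sufficiently large factor drives the cell mass
#'     down); 96 h.}
#' }
#'
#' @param name one of `"physiological"`, `"infusion"`, `"type2"`, `"type1"`.
#' @param p4_multiplier apoptosis-rate multiplier for the type-1 scenario.
#' @return An object of class `islet_scenario`: list with `name`,
#'   `overrides` (named parameter replacements), `duration` (min) and
#'   `grid_dt` (min).
#' @export
builtin_scenario <- function(name, p4_multiplier = 10) {
  scenarios <- c("physiological", "infusion", "type2", "type1")
  if (!is.character(name) || length(name) != 1L || !(name %in% scenarios))
    stop("unknown scenario '", paste(name, collapse = ","),
         "'; available scenarios: ", paste(scenarios, collapse = ", "))
  sc <- switch(name,
    physiological = list(overrides = list(), duration = 120, grid_dt = 1),
    infusion = list(overrides = list(p6 = 8.6806), duration = 5760,
                    grid_dt = 10),
    type2 = list(overrides = list(p8 = 360e-5), duration = 120, grid_dt = 1),
    type1 = list(overrides = list(p4 = p4_multiplier * 3.3194e-4),
                 duration = 5760, grid_dt = 10))
  structure(c(list(name = name), sc), class = "islet_scenario")
}

#' Run a built-in or custom scenario
#'
#' Applies a scenario's parameter overrides to a base parameter set and
#' integrates over the scenario horizon.
#'
#' @param scenario an `islet_scenario` object or a scenario name accepted by
#'   [builtin_scenario()].
#' @param params base parameter set the overrides are applied to.
#' @param init initial state.
#' @param ... further arguments passed to [simulate_islet()]
#'   (e.g. `method`, `rtol`, `duration` to override the scenario horizon).
#' @return An `islet_trajectory`.
#' @examples
#' traj <- run_scenario("physiological")
#' traj$state[nrow(traj$state), "G"]
#' @export
run_scenario <- function(scenario, params = islet_parameters(),
                         init = islet_initial_state(), ...) {
  if (is.character(scenario)) scenario <- builtin_scenario(scenario)
  stopifnot(inherits(scenario, "islet_scenario"))
  if (length(scenario$overrides))
    params <- do.call(islet_parameters,
                      utils::modifyList(as.list(unclass(params)),
                                        scenario$overrides))
  dots <- list(...)
  args <- utils::modifyList(
    list(params = params, init = init, duration = scenario$duration,
         grid_dt = scenario$grid_dt, scenario = scenario), dots)
  do.call(simulate_islet, args)
}

#' Local extrema of a trajectory component
#'
#' Finds local maxima and minima with a relative prominence filter. An
#' interior point is an extremum when the series changes direction there;
#' its prominence is the smaller height difference to the neighbouring
#' opposite extrema (or series ends), measured relative to the series range.
#' With `include_boundary = TRUE` the first and last samples are also
#' reported as boundary extrema; this captures, e.g., the first-phase
#' insulin release peak that sits at the start of the record. The default
#' reports interior extrema only, so a strictly monotone series yields an
#' empty result.
#'
#' @param x an `islet_trajectory` (then `component` selects the series) or a
#'   numeric vector.
#' @param component state component name, e.g. `"X1"`.
#' @param min_prominence_rel minimal prominence relative to the series
#'   range in `[0, 1]`.
#' @param time optional time vector when `x` is a plain numeric vector.
#' @param include_boundary report boundary extrema as well.
#' @return Data frame with columns `time`, `value`, `kind` (`"max"` or
#'   `"min"`), ordered by time; zero rows for monotone series when boundary
#'   extrema are excluded.
#' @examples
#' t <- seq(0, 4 * pi, by = 0.01)
#' find_local_extrema(sin(t), time = t, include_boundary = FALSE)
#' @export
find_local_extrema <- function(x, component = "X1",
                               min_prominence_rel = 0.01,
                               time = NULL, include_boundary = FALSE) {
  if (inherits(x, "islet_trajectory")) {
    time <- x$time
    x <- x$state[, component]
  } else {
    x <- as.numeric(x)
    if (is.null(time)) time <- seq_along(x) - 1
  }
  n <- length(x)
  if (n < 3L) stop("need at least 3 samples")
  rng <- diff(range(x))
  if (rng == 0) return(data.frame(time = numeric(), value = numeric(),
                                  kind = character()))
  ## collapse exact plateaus so sign changes are well defined
  keep <- c(TRUE, diff(x) != 0)
  xs <- x[keep]; ts <- time[keep]
  m <- length(xs)
  d <- sign(diff(xs))
  idx <- which(diff(d) != 0) + 1L           # interior turning points
  kind <- ifelse(d[idx - 1L] > 0, "max", "min")
  if (include_boundary && m >= 2L) {
    idx <- c(1L, idx, m)
    kind <- c(ifelse(d[1L] < 0, "max", "min"), kind,
              ifelse(d[m - 1L] > 0, "max", "min"))
  }
  if (!length(idx)) return(data.frame(time = numeric(), value = numeric(),
                                      kind = character()))
  vals <- xs[idx]
  ## topographic prominence: drop to the lowest point separating the
  ## extremum from the nearest higher terrain on either side (mirrored for
  ## minima); series ends count as open terrain
  prom_one <- function(i0, is_max) {
    v <- xs[i0]
    side <- function(ix) {
      if (!length(ix)) return(if (is_max) min(xs) else max(xs))
      ext <- v
      for (q in ix) {
        if (if (is_max) xs[q] > v else xs[q] < v) break
        ext <- if (is_max) min(ext, xs[q]) else max(ext, xs[q])
      }
      ext
    }
    lo <- side(rev(seq_len(i0 - 1L)))
    hi <- side(if (i0 < m) (i0 + 1L):m else integer())
    if (is_max) v - max(lo, hi) else min(lo, hi) - v
  }
  prom <- vapply(seq_along(idx),
                 function(i) prom_one(idx[i], kind[i] == "max"), numeric(1))
  ok <- prom / rng >= min_prominence_rel
  data.frame(time = ts[idx[ok]], value = vals[ok], kind = kind[ok])
}

#' Pointwise glucose dominance between two trajectories
#'
#' Compares the glucose curves of two trajectories on an identical time
#' grid: the fraction of grid points (excluding `t = 0`) where the first
#' trajectory's glucose is at least the second's, and the extreme signed
#' gaps.
#'
#' @param trajA,trajB `islet_trajectory` objects on the same time grid.
#' @param component state component to compare, `"G"` by default.
#' @return List with `fraction_ge` (fraction of `t > 0` grid points with
#'   `A >= B`), `max_gap` and `min_gap` (extremes of `A - B`).
#' @export
compare_glucose <- function(trajA, trajB, component = "G") {
  stopifnot(inherits(trajA, "islet_trajectory"),
            inherits(trajB, "islet_trajectory"))
  if (length(trajA$time) != length(trajB$time) ||
      any(trajA$time != trajB$time))
    stop("trajectories must share an identical time grid")
  a <- trajA$state[, component]
  b <- trajB$state[, component]
  pos <- trajA$time > 0
  gap <- a - b
  list(fraction_ge = mean(a[pos] >= b[pos]),
       max_gap = max(gap), min_gap = min(gap))
}

## ---- trajectory methods ----------------------------------------------------

#' @export
print.islet_trajectory <- function(x, ...) {
  sc <- if (!is.null(x$scenario)) x$scenario$name else "custom"
  cat(sprintf("islet trajectory: scenario '%s', %d samples over %.6g min (%s)\n",
              sc, length(x$time), max(x$time), x$solver$method))
  cat("final state:\n")
  print(signif(x$state[nrow(x$state), ], 6))
  invisible(x)
}

#' @export
summary.islet_trajectory <- function(object, ...) {
  st <- object$state
  out <- list(
    scenario = if (!is.null(object$scenario)) object$scenario$name else "custom",
    duration = max(object$time),
    end_state = st[nrow(st), ],
    G_range = range(st[, "G"]),
    X1_extrema = find_local_extrema(object, "X1"),
    I_extrema = find_local_extrema(object, "I"),
    solver = object$solver)
  class(out) <- "summary.islet_trajectory"
  out
}

#' @export
print.summary.islet_trajectory <- function(x, ...) {
  cat(sprintf("scenario '%s', %.6g min\n", x$scenario, x$duration))
  cat(sprintf("glucose range: [%.4g, %.4g] mg/100ml\n",
              x$G_range[1], x$G_range[2]))
  cat("end state:\n"); print(signif(x$end_state, 6))
  cat("X1 extrema:\n"); print(x$X1_extrema)
  invisible(x)
}

#' @export
as.data.frame.islet_trajectory <- function(x, ...) {
  data.frame(time_min = x$time, x$state)
}

#' Plot an islet trajectory
#'
#' Panel plot of the eight state components against time, base graphics.
#'
#' @param x an `islet_trajectory`.
#' @param components subset of [state_names()] to draw.
#' @param ... passed to [graphics::plot.default()].
#' @export
plot.islet_trajectory <- function(x, components = state_names(), ...) {
  old <- graphics::par(mfrow = grDevices::n2mfrow(length(components)),
                       mar = c(4, 4, 1.5, 0.5))
  on.exit(graphics::par(old))
  units <- c(G1 = "cells", S = "cells", G2M = "cells",
             G = "mg/100ml", I = "mg/100ml", X1 = "mg", X2 = "mg", P = "-")
  for (comp in components)
    graphics::plot(x$time, x$state[, comp], type = "l",
                   xlab = "time (min)",
                   ylab = sprintf("%s (%s)", comp, units[[comp]]),
                   main = comp, ...)
  invisible(x)
}
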