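## shared fixtures and small numeric oracles

default_params <- islet_parameters()

## trapezoid quadrature oracle on a fixed grid (independent of the package's
## closed-form integrals)
trap_quad <- function(f, lo, hi, n = 20001) {
  x <- seq(lo, hi, length.out = n)
  y <- f(x)
  h <- (hi - lo) / (n - 1)
  h * (sum(y) - (y[1] + y[n]) / 2)
}

## cache expensive trajectories across tests within a session
.traj_cache <- new.env(parent = emptyenv())
cached_scenario <- function(name, ...) {
  key <- paste0(name, "|", paste(c(...), collapse = ","))
  if (is.null(.traj_cache[[key]]))
    .traj_cache[[key]] <- run_scenario(name, ...)
  .traj_cache[[key]]
}
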