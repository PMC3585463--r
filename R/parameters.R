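## Parameter set and initial state -------------------------------------------

#' Model parameter set
#'
#' Constructs the parameter set of the coupled glucose--insulin--beta-cell-cycle
#' model. Called without arguments it returns the published default
#' parameterisation; individual fields can be overridden by name.
#'
#' The fields are:
#' \describe{
#'   \item{p1, p2, p3}{cell-cycle transition rates G1->S, S->G2/M, G2/M->G1
#'     (1/min).}
#'   \item{p4}{apoptosis rate (1/min). Must exceed `p1` so that the glucose
#'     threshold \eqn{\hat G = (p_4-p_1)/(p_1 p_5)} is positive.}
#'   \item{p5}{influence factor of glucose on the G1->S transition (100ml/mg).}
#'   \item{p6}{net glucose production rate (mg/(100ml min)).}
#'   \item{p7}{glucose effectiveness at zero insulin (1/min).}
#'   \item{p8}{insulin sensitivity (100ml/(mg min)).}
#'   \item{p9}{insulin secretion rate (1/min).}
#'   \item{p10}{insulin decay rate (1/min).}
#'   \item{p11}{rate of provision increase (1/min).}
#'   \item{p12}{insulin amount per beta cell (mg). By default recomputed as
#'     `Xbar_max / G1_0` so that the storage capacity at the reference cell
#'     count equals `Xbar_max` exactly; set `use_printed_p12 = TRUE` to use
#'     the rounded published value 1.72e-9 verbatim.}
#'   \item{bv}{blood volume (ml).}
#'   \item{f}{provision proportionality factor (dimensionless). Must be
#'     smaller than `p9`; this keeps the denominator of the redistribution
#'     factor strictly negative for all positive glucose values.}
#'   \item{h, P0}{Hill coefficient and Michaelis constant of the provision
#'     steady state \eqn{P_\infty(G)}.}
#'   \item{Xbar_max}{maximal amount of insulin per pancreas (mg).}
#'   \item{k, C}{Hill coefficient and Michaelis constant of the packet
#'     storage distribution.}
#'   \item{G1_0}{reference number of cells in G1 phase used as the
#'     normalisation of the storage capacity (cells).}
#' }
#'
#' @param ... named overrides of individual fields, e.g. `p6 = 8.6806`.
#'   Unknown names are an error.
#' @param use_printed_p12 logical; if `TRUE`, `p12` is fixed at the rounded
#'   published value `1.72e-9` mg instead of being recomputed from
#'   `Xbar_max / G1_0`. An explicit `p12 = ` override always wins.
#' @return An object of class `islet_parameters`: a named list of numeric
#'   scalars.
#' @seealso [validate_parameters()], [islet_initial_state()],
#'   [glucose_threshold()]
#' @examples
#' p <- islet_parameters()
#' p$p9
#' islet_parameters(p6 = 8.6806)$p6
#' @export
islet_parameters <- function(..., use_printed_p12 = FALSE) {
  defaults <- list(
    p1 = 6.0594e-5,   # 1/min, transition G1 -> S
    p2 = 4.9861e-3,   # 1/min, transition S -> G2/M
    p3 = 8.9444e-4,   # 1/min, transition G2/M -> G1
    p4 = 3.3194e-4,   # 1/min, apoptosis
    p5 = 0.0561,      # 100ml/mg, glucose influence on p1
    p6 = 0.3,         # mg/(100ml min), glucose production
    p7 = 0.003,       # 1/min, glucose effectiveness at zero insulin
    p8 = 360e-3,      # 100ml/(mg min), insulin sensitivity
    p9 = 0.622,       # 1/min, insulin secretion
    p10 = 0.3,        # 1/min, insulin decay
    p11 = 0.0337,     # 1/min, provision increase
    p12 = NA_real_,   # mg, insulin per beta cell (filled below)
    bv = 3.33,        # ml, blood volume
    f = 0.5,          # -, provision proportionality factor
    h = 5,            # -, Hill coefficient of P_inf
    P0 = 186.506,     # mg/100ml, Michaelis constant of P_inf
    Xbar_max = 1.65e-3, # mg, maximal insulin per pancreas
    k = 3.3,          # -, Hill coefficient of storage distribution
    C = 149.78,       # mg/100ml, Michaelis constant of storage distribution
    G1_0 = 958000     # cells, normalisation count for the storage capacity
  )
  overrides <- list(...)
  if (length(overrides)) {
    if (is.null(names(overrides)) || any(!nzchar(names(overrides))))
      stop("all parameter overrides must be named")
    unknown <- setdiff(names(overrides), names(defaults))
    if (length(unknown))
      stop("unknown parameter field(s): ", paste(unknown, collapse = ", "))
    for (nm in names(overrides)) {
      v <- overrides[[nm]]
      if (!is.numeric(v) || length(v) != 1L || !is.finite(v))
        stop("parameter '", nm, "' must be a finite numeric scalar")
      defaults[[nm]] <- as.numeric(v)
    }
  }
  if (is.na(defaults$p12)) {
    defaults$p12 <- if (use_printed_p12) 1.72e-9 else
      defaults$Xbar_max / defaults$G1_0
  }
  structure(defaults, class = "islet_parameters")
}

#' @export
print.islet_parameters <- function(x, ...) {
  cat("Glucose-insulin / beta-cell-cycle model parameters\n")
  df <- data.frame(value = unlist(x), row.names = names(x))
  print(format(df, digits = 6))
  cat(sprintf("glucose threshold Ghat = %.4f mg/100ml\n",
              (x$p4 - x$p1) / (x$p1 * x$p5)))
  invisible(x)
}

## canonical component order of the state vector; also the CSV column order
.state_names <- c("G1", "S", "G2M", "G", "I", "X1", "X2", "P")

#' State vector component names
#'
#' The fixed ordering of the eight dynamical variables used throughout the
#' package (state vectors, Jacobian rows/columns, trajectory and CSV columns):
#' `G1`, `S`, `G2M` (cell counts in the three cell-cycle phases), `G`, `I`
#' (blood glucose and insulin concentrations, mg/100ml), `X1`, `X2`
#' (releasable / non-releasable stored insulin, mg) and `P` (dimensionless
#' provision factor).
#'
#' @return Character vector of length 8.
#' @export
state_names <- function() .state_names

#' Initial state vector
#'
#' Returns the published default initial condition, optionally with named
#' overrides. The component order is fixed (see [state_names()]).
#'
#' @param ... named overrides, e.g. `G = 300`.
#' @return Named numeric vector of length 8.
#' @examples
#' islet_initial_state()
#' islet_initial_state(G = 300)[["G"]]
#' @export
islet_initial_state <- function(...) {
  y <- c(G1 = 958000, S = 14000, G2M = 28000,
         G = 200, I = 0.01, X1 = 0.0012, X2 = 0.0005, P = 0)
  overrides <- list(...)
  if (length(overrides)) {
    if (is.null(names(overrides)) || any(!nzchar(names(overrides))))
      stop("all state overrides must be named")
    unknown <- setdiff(names(overrides), .state_names)
    if (length(unknown))
      stop("unknown state component(s): ", paste(unknown, collapse = ", "))
    for (nm in names(overrides)) {
      v <- overrides[[nm]]
      if (!is.numeric(v) || length(v) != 1L || !is.finite(v))
        stop("state component '", nm, "' must be a finite numeric scalar")
      y[[nm]] <- as.numeric(v)
    }
  }
  y
}

#' Validate a parameter set
#'
#' Checks the structural constraints the model requires: strict positivity of
#' every field, `p4 > p1` (otherwise the glucose threshold
#' \eqn{\hat G = (p_4 - p_1)/(p_1 p_5)} degenerates to zero or goes negative)
#' and `f < p9` (otherwise the denominator of the redistribution factor
#' \eqn{\tilde f} changes sign at large glucose values and the factor blows
#' up). Violations are reported, not raised.
#'
#' @param params an [islet_parameters()] object.
#' @return A data frame with columns `field` and `message`; zero rows when all
#'   invariants hold.
#' @examples
#' nrow(validate_parameters(islet_parameters()))            # 0
#' validate_parameters(islet_parameters(f = 1.0))$message
#' @export
validate_parameters <- function(params) {
  stopifnot(inherits(params, "islet_parameters"))
  bad <- list()
  for (nm in names(params)) {
    v <- params[[nm]]
    if (!is.finite(v) || v <= 0)
      bad[[length(bad) + 1L]] <-
        data.frame(field = nm,
                   message = sprintf("%s must be strictly positive (is %g)",
                                     nm, v))
  }
  if (is.finite(params$p4) && is.finite(params$p1) && params$p4 <= params$p1)
    bad[[length(bad) + 1L]] <-
      data.frame(field = "p4",
                 message = "p4 > p1 required (glucose threshold Ghat would be <= 0)")
  if (is.finite(params$f) && is.finite(params$p9) && params$f >= params$p9)
    bad[[length(bad) + 1L]] <-
      data.frame(field = "f",
                 message = "f < p9 required (redistribution denominator changes sign)")
  if (length(bad)) do.call(rbind, bad) else
    data.frame(field = character(), message = character())
}
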