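## Configuration and trajectory I/O -------------------------------------------

#' Save a model configuration
#'
#' Writes parameters, initial state and an optional scenario record to a
#' JSON file with the schema
#' `{"parameters": {...}, "initial_state": {...}, "scenario":
#' {"name": ..., "duration_min": ..., "overrides": {...}}}`.
#' Numbers are written at full precision so that a save/load round trip is
#' exact for decimal-representable values.
#'
#' @param params an [islet_parameters()] object.
#' @param init initial state vector.
#' @param path output file path.
#' @param scenario optional `islet_scenario` or list with `name`,
#'   `duration_min`, `overrides`.
#' @return `path`, invisibly.
#' @export
save_config <- function(params, init = islet_initial_state(), path,
                        scenario = NULL) {
  stopifnot(inherits(params, "islet_parameters"))
  cfg <- list(parameters = as.list(unclass(params)),
              initial_state = as.list(init))
  if (!is.null(scenario)) {
    if (inherits(scenario, "islet_scenario"))
      scenario <- list(name = scenario$name,
                       duration_min = scenario$duration,
                       overrides = scenario$overrides)
    cfg$scenario <- scenario
  }
  jsonlite::write_json(cfg, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' Load a model configuration
#'
#' Reads a configuration written by [save_config()] (JSON, or YAML when the
#' file ends in `.yaml`/`.yml` and the `yaml` package is available). Unknown
#' field names and non-numeric values are errors, reported with their field
#' path; silent typos in parameter names are the main failure mode of
#' simulator configurations, so nothing is ignored.
#'
#' @param path configuration file path.
#' @return List with `parameters` (an [islet_parameters()] object),
#'   `initial_state` (full state vector) and `scenario` (list or `NULL`).
#' @export
load_config <- function(path) {
  if (!file.exists(path)) stop("configuration file not found: ", path)
  is_yaml <- grepl("\\.ya?ml$", path, ignore.case = TRUE)
  cfg <- if (is_yaml) {
    if (!requireNamespace("yaml", quietly = TRUE))
      stop("reading YAML configurations requires the 'yaml' package")
    yaml::read_yaml(path)
  } else {
    tryCatch(jsonlite::read_json(path, simplifyVector = TRUE),
             error = function(e)
               stop("failed to parse ", path, ": ", conditionMessage(e),
                    call. = FALSE))
  }
  known_top <- c("parameters", "initial_state", "scenario")
  unknown <- setdiff(names(cfg), known_top)
  if (length(unknown))
    stop("unknown top-level configuration field(s): ",
         paste(unknown, collapse = ", "))
  check_numeric <- function(lst, where) {
    for (nm in names(lst))
      if (!is.numeric(lst[[nm]]) || length(lst[[nm]]) != 1L)
        stop(sprintf("%s.%s must be a single number", where, nm))
  }
  pars <- as.list(cfg$parameters)
  check_numeric(pars, "parameters")
  params <- do.call(islet_parameters, pars)    # rejects unknown names
  init <- islet_initial_state()
  if (!is.null(cfg$initial_state)) {
    st <- as.list(cfg$initial_state)
    check_numeric(st, "initial_state")
    init <- do.call(islet_initial_state, st)   # rejects unknown names
  }
  scenario <- NULL
  if (!is.null(cfg$scenario)) {
    scenario <- cfg$scenario
    bad <- setdiff(names(scenario), c("name", "duration_min", "overrides"))
    if (length(bad))
      stop("unknown scenario field(s): ", paste(bad, collapse = ", "))
    if (!is.null(scenario$overrides)) {
      ov <- as.list(scenario$overrides)
      check_numeric(ov, "scenario.overrides")
      bad <- setdiff(names(ov), names(unclass(params)))
      if (length(bad))
        stop("scenario override(s) reference unknown parameter(s): ",
             paste(bad, collapse = ", "))
    }
  }
  list(parameters = params, initial_state = init, scenario = scenario)
}

#' Write a trajectory to CSV
#'
#' Fixed column order `time_min,G1,S,G2M,G,I,X1,X2,P`, one row per output
#' grid point, numbers in shortest round-trip (17 significant digit)
#' representation with a locale-independent decimal point, so a write/read
#' round trip is lossless.
#'
#' @param traj an `islet_trajectory`.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_trajectory_csv <- function(traj, path) {
  stopifnot(inherits(traj, "islet_trajectory"))
  m <- cbind(time_min = traj$time, traj$state)
  txt <- apply(m, 1, function(row)
    paste(formatC(row, format = "g", digits = 17), collapse = ","))
  writeLines(c(paste(colnames(m), collapse = ","), txt), path)
  invisible(path)
}

#' Read a trajectory from CSV
#'
#' Inverse of [write_trajectory_csv()]. The header must match the canonical
#' column order exactly. Parameter and scenario metadata are not stored in
#' the CSV and come back as `NULL`.
#'
#' @param path CSV file path.
#' @return An `islet_trajectory` (with empty metadata).
#' @export
read_trajectory_csv <- function(path) {
  if (!file.exists(path)) stop("trajectory file not found: ", path)
  expected <- c("time_min", .state_names)
  header <- strsplit(readLines(path, n = 1L), ",")[[1]]
  if (!identical(header, expected))
    stop("trajectory header mismatch: expected '",
         paste(expected, collapse = ","), "'")
  df <- utils::read.csv(path, colClasses = "numeric")
  if (nrow(df) == 0L) {
    warning("trajectory file contains no samples")
    state <- matrix(numeric(), 0, 8, dimnames = list(NULL, .state_names))
    return(structure(list(time = numeric(), state = state, params = NULL,
                          scenario = NULL, solver = NULL),
                     class = "islet_trajectory"))
  }
  state <- as.matrix(df[, .state_names])
  colnames(state) <- .state_names
  structure(list(time = df$time_min, state = state, params = NULL,
                 scenario = NULL, solver = NULL),
            class = "islet_trajectory")
}
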