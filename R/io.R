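#' Load a scenario from a JSON configuration file
#'
#' The configuration is a single JSON document. Dimensional values carry
#' mandatory unit suffixes (`"1 mM"`, `"1.45e7 /mL"`, `"40 min"`) or are bare
#' numbers already in internal SI units (mol/L, s, cells/L, L). Unknown keys
#' are rejected with their key path. Kinetic constants omitted from `params`
#' fall back to the package defaults.
#'
#' ```json
#' {
#'   "label": "my_run",
#'   "params": {"kdiff": 70},
#'   "strains": [{"label": "wt", "ahp_factor": 1, "cat_factor": 1,
#'                "n0": "1.45e7 /mL"}],
#'   "population": {"vout": "1 L", "growth_mode": "constant"},
#'   "stress_events": [{"time": "0 s", "amount": "1 mM"}],
#'   "t_end": "600 s"
#' }
#' ```
#'
#' @param path path to the JSON file.
#' @return a validated [scenario()].
#' @export
load_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path, call. = FALSE)
  cfg <- tryCatch(jsonlite::fromJSON(path, simplifyVector = FALSE),
                  error = function(e)
                    stop("cannot parse config ", path, ": ",
                         conditionMessage(e), call. = FALSE))
  known <- c("label", "params", "strains", "population", "stress_events",
             "t_end", "init_internal")
  reject_unknown(cfg, known, "")
  if (is.null(cfg$strains) || !length(cfg$strains))
    stop("config error at 'strains': at least one strain with a density ",
         "'n0' is required", call. = FALSE)
  if (is.null(cfg$t_end))
    stop("config error at 't_end': required", call. = FALSE)

  params <- do.call(kinetic_params, lapply(check_keys(
    cfg$params, names(formals(kinetic_params)), "params"), as.numeric))

  strains <- list(); densities <- numeric(0)
  for (i in seq_along(cfg$strains)) {
    s <- check_keys(cfg$strains[[i]],
                    c("label", "ahp_factor", "cat_factor", "has_membrane",
                      "endogenous_production", "n0"),
                    paste0("strains[", i, "]"))
    if (is.null(s$n0))
      stop("config error at 'strains[", i, "].n0': density required",
           call. = FALSE)
    densities <- c(densities, parse_quantity(s$n0, "density"))
    s$n0 <- NULL
    strains[[i]] <- do.call(strain_config, s)
  }

  popc <- check_keys(cfg$population,
                     c("vout", "growth_mode", "tau_d", "n_max",
                       "lag_duration"), "population")
  if (!is.null(popc$vout)) popc$vout <- parse_quantity(popc$vout, "volume")
  if (!is.null(popc$tau_d)) popc$tau_d <- parse_quantity(popc$tau_d, "time")
  if (!is.null(popc$n_max)) popc$n_max <- parse_quantity(popc$n_max, "density")
  if (!is.null(popc$lag_duration))
    popc$lag_duration <- parse_quantity(popc$lag_duration, "time")
  population <- do.call(population_model, popc)

  events <- NULL
  if (!is.null(cfg$stress_events) && length(cfg$stress_events)) {
    events <- do.call(rbind, lapply(seq_along(cfg$stress_events), function(i) {
      e <- check_keys(cfg$stress_events[[i]], c("time", "amount"),
                      paste0("stress_events[", i, "]"))
      data.frame(time = parse_quantity(e$time, "time"),
                 amount = parse_quantity(e$amount, "concentration"))
    }))
  }

  init <- cfg$init_internal
  if (is.null(init)) init <- "steady"
  else if (is.list(init)) init <- vapply(init, parse_quantity, numeric(1),
                                         kind = "concentration")

  tryCatch(
    scenario(params = params, strains = strains, densities = densities,
             population = population, stress_events = events,
             t_end = parse_quantity(cfg$t_end, "time"),
             init_internal = init,
             label = if (is.null(cfg$label)) basename(path) else cfg$label),
    error = function(e)
      stop("config validation error: ", conditionMessage(e), call. = FALSE))
}

reject_unknown <- function(x, known, where) {
  extra <- setdiff(names(x), known)
  if (length(extra))
    stop("config error at '", if (nzchar(where)) where else "<top level>",
         "': unknown key(s) ", paste0("'", extra, "'", collapse = ", "),
         call. = FALSE)
  invisible(x)
}

check_keys <- function(x, known, where) {
  if (is.null(x)) return(list())
  reject_unknown(x, known, where)
  x
}

#' Write / read a trajectory as TSV
#'
#' The TSV carries the same columns as the in-memory trajectory (`time_s`,
#' `h2o2_out_M`, then `h2o2_in_M.<label>`, `superoxide_M.<label>`,
#' `density_per_L.<label>` per strain); units are in the column names.
#' `read_trajectory()` reconstructs the object by header name, so column
#' order is irrelevant; a write/read round trip is exact to formatting
#' precision (15 significant digits).
#'
#' @param trajectory a `ros_trajectory`.
#' @param path file path.
#' @return `read_trajectory()` returns a `ros_trajectory`.
#' @export
write_trajectory <- function(trajectory, path) {
  stopifnot(inherits(trajectory, "ros_trajectory"))
  df <- as.data.frame(lapply(trajectory, function(col)
    formatC(col, digits = 15, format = "g")))
  names(df) <- names(trajectory)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_trajectory
#' @export
read_trajectory <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  df <- tryCatch(
    utils::read.delim(path, check.names = FALSE, colClasses = "numeric"),
    warning = function(w) stop("malformed trajectory TSV ", path, ": ",
                               conditionMessage(w), call. = FALSE),
    error = function(e) stop("malformed trajectory TSV ", path, ": ",
                             conditionMessage(e), call. = FALSE))
  if (anyNA(df))
    stop("malformed trajectory TSV ", path, ": non-numeric or missing ",
         "fields (first bad line ",
         min(which(rowSums(is.na(df)) > 0)) + 1L, ")", call. = FALSE)
  need <- c("time_s", "h2o2_out_M")
  if (!all(need %in% names(df)))
    stop("trajectory TSV lacks required columns ",
         paste(setdiff(need, names(df)), collapse = ", "), call. = FALSE)
  labels <- unique(sub("^h2o2_in_M\\.", "",
                       grep("^h2o2_in_M\\.", names(df), value = TRUE)))
  if (!length(labels))
    stop("trajectory TSV has no per-strain h2o2_in_M.<label> column",
         call. = FALSE)
  ord <- c("time_s", "h2o2_out_M",
           unlist(lapply(labels, function(l)
             paste0(c("h2o2_in_M.", "superoxide_M.", "density_per_L."), l))))
  missing_cols <- setdiff(ord, names(df))
  if (length(missing_cols))
    stop("trajectory TSV lacks columns ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  if (is.unsorted(df$time_s, strictly = TRUE))
    stop("trajectory TSV times are not strictly increasing", call. = FALSE)
  structure(df[, ord], class = c("ros_trajectory", "data.frame"),
            strain_labels = labels,
            meta = list(scenario = basename(path), rtol = NA, atol = NA,
                        quasi_steady = NA))
}

#' Derived-rate summary table for a configuration
#'
#' The quantities a practitioner wants at a glance for one strain at one
#' density: regime, lumped rates, exact eigenvalues, steady states, plateau,
#' peak time/height, external half-life and contribution fractions. This is
#' what the CLI `analytic` subcommand prints as TSV.
#'
#' @param params a [kinetic_params()].
#' @param strain a [strain_config()].
#' @param n cell density, cells/L.
#' @param external0 exogenous H2O2 step, mol/L (0 = unstressed; analytic
#'   stress quantities are then reported for the LOW regime formulas).
#' @param population a [population_model()].
#' @return data.frame with columns `quantity`, `value`, `unit`.
#' @export
analytic_summary <- function(params, strain = wild_type(), n, external0 = 0,
                             population = population_model()) {
  regime <- classify_regime(external0)
  rates <- derived_rates(params, strain, population, n)
  rows <- list(
    c("regime", regime, ""),
    c("kprod", rates$kprod, "mol/L/s"),
    c("kenz", rates$kenz, "/s"),
    c("kenz_prime", rates$kenz_prime, "/s"),
    c("kdiff", params$kdiff, "/s"),
    c("kdiff_prime", rates$kdiff_prime, "/s"),
    c("steady_state_linear", steady_state_linear(params, strain), "mol/L"),
    c("steady_state_nonlinear", steady_state_nonlinear(params, strain),
      "mol/L"),
    c("plateau", plateau_concentration(params, strain), "mol/L")
  )
  if (regime != "INTERMEDIATE" && external0 > 0) {
    sol <- solve_linear(params, strain, n, external0,
                        population = population, regime = regime)
    fr <- contribution_fractions(params, strain, regime)
    rows <- c(rows, list(
      c("lambda_slow", sol$lambda_slow, "/s"),
      c("lambda_fast", sol$lambda_fast, "/s"),
      c("tmax", tmax_analytic(sol), "s"),
      c("cmax", cmax_analytic(params, strain, external0, regime), "mol/L"),
      c("t_half_external",
        half_life_external(params, strain, n, regime, population), "s")),
      lapply(names(fr), function(nm)
        c(paste0("fraction_", nm), fr[[nm]], "")))
  }
  out <- as.data.frame(do.call(rbind, rows), stringsAsFactors = FALSE)
  names(out) <- c("quantity", "value", "unit")
  out
}
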