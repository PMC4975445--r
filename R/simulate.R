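#' Define a simulation scenario
#'
#' A scenario is everything one run needs: the kinetic constants, one or more
#' strains sharing a single medium with their initial densities, the
#' population/growth settings, a list of stress events (step additions of
#' exogenous H2O2), and the time horizon.
#'
#' @param params a [kinetic_params()].
#' @param strains list of [strain_config()] objects.
#' @param densities numeric vector of initial densities, cells/L, one per
#'   strain.
#' @param population a [population_model()].
#' @param stress_events `NULL`, or a data.frame with columns `time` (s) and
#'   `amount` (mol/L added to the medium).
#' @param t_end simulation horizon, s.
#' @param init_internal `"steady"` (pre-stress steady state, the default for
#'   stress experiments), `"zero"`, or a numeric vector of initial internal
#'   concentrations (mol/L) per strain.
#' @param label free-text scenario name.
#' @return an object of class `ros_scenario`.
#' @export
scenario <- function(params = kinetic_params(),
                     strains = list(wild_type()),
                     densities,
                     population = population_model(),
                     stress_events = NULL,
                     t_end,
                     init_internal = "steady",
                     label = "scenario") {
  if (!length(strains)) stop("need at least one strain", call. = FALSE)
  if (!all(vapply(strains, inherits, logical(1), "strain_config")))
    stop("strains must be strain_config objects", call. = FALSE)
  if (length(densities) != length(strains) || any(densities < 0))
    stop("densities must be non-negative, one per strain", call. = FALSE)
  if (!is.numeric(t_end) || t_end <= 0) stop("t_end must be > 0", call. = FALSE)
  check_cell_volume(sum(densities), params$vin, population$vout)
  if (!is.null(stress_events)) {
    stress_events <- as.data.frame(stress_events)
    if (!all(c("time", "amount") %in% names(stress_events)))
      stop("stress_events needs columns 'time' and 'amount'", call. = FALSE)
    if (any(stress_events$time < 0) || any(stress_events$time > t_end))
      stop("event times must lie within [0, t_end]", call. = FALSE)
    if (any(stress_events$amount < 0))
      stop("event amounts must be >= 0", call. = FALSE)
    stress_events <- stress_events[order(stress_events$time), , drop = FALSE]
  }
  labels <- make.unique(vapply(strains, `[[`, character(1), "label"))
  structure(list(params = params, strains = strains, densities = densities,
                 population = population, stress_events = stress_events,
                 t_end = t_end, init_internal = init_internal,
                 strain_labels = labels, label = label),
            class = "ros_scenario")
}

#' @export
print.ros_scenario <- function(x, ...) {
  cat("<ros_scenario> ", x$label, ": ", length(x$strains), " strain(s) [",
      paste(x$strain_labels, collapse = ", "), "], t_end ", x$t_end, " s, ",
      if (is.null(x$stress_events)) "no stress events"
      else paste0(nrow(x$stress_events), " stress event(s)"),
      "\n", sep = "")
  invisible(x)
}

# Logistic flow from density n0 over dt seconds.
verhulst_from <- function(n0, dt, tau_d, n_max) {
  if (dt <= 0) return(n0)
  e <- 2^(dt / tau_d)
  n0 * e / (1 + n0 / n_max * (e - 1))
}

#' Cell density under the growth law
#'
#' Constant mode returns `n0`. Logistic (Verhulst) mode follows
#' `n(t) = n0 e^{rt} / (1 + (n0/n_max)(e^{rt} - 1))` with `r = ln2 / tau_d`,
#' except that growth is frozen while the time since the last stress event
#' (`stress_clock`) is below `lag_duration`.
#'
#' @param population a [population_model()].
#' @param n0 density at `t = 0`, cells/L.
#' @param t elapsed time, s.
#' @param stress_clock time since the last stress event at `t = 0`, s
#'   (`Inf` = unstressed).
#' @return density at time `t`, cells/L.
#' @export
grow <- function(population, n0, t, stress_clock = Inf) {
  stopifnot(inherits(population, "population_model"), t >= 0)
  if (population$growth_mode == "constant") return(n0)
  frozen <- max(0, population$lag_duration - max(0, stress_clock))
  verhulst_from(n0, t - min(t, frozen), population$tau_d, population$n_max)
}

# log-spaced output times for one segment, resolving ms and minute scales
segment_times <- function(t0, t1, n_pts) {
  len <- t1 - t0
  if (len <= 1e-5) return(c(t0, t1))
  tt <- t0 + exp(seq(log(1e-5), log(len), length.out = n_pts))
  tt[n_pts] <- t1   # exp(log(len)) round-off must not move the boundary
  c(t0, tt)
}

#' Integrate the full nonlinear model
#'
#' Stiff integration (via [deSolve::ode()], `lsoda`) of the exact
#' Michaelis–Menten system defined by [ros_rhs()], for every strain of the
#' scenario sharing one medium. Stress events are applied as discontinuous
#' jumps in the external concentration with an integrator restart, and each
#' event restarts the growth-lag clock. The output grid is log-spaced from
#' 1e-5 s after each event so that both the millisecond internal peak and the
#' minute-scale medium decay are resolved.
#'
#' @param scn a [scenario()].
#' @param rtol,atol relative / absolute integration tolerances
#'   (defaults 1e-8 and 1e-15 mol/L).
#' @param quasi_steady replace the superoxide ODE by its steady state.
#' @param grid_points output points per inter-event segment.
#' @return a `ros_trajectory`: a data.frame with columns `time_s`,
#'   `h2o2_out_M` and, per strain label, `h2o2_in_M.<label>`,
#'   `superoxide_M.<label>`, `density_per_L.<label>`; attributes carry the
#'   strain labels and solver settings.
#' @examples
#' \donttest{
#' scn <- get_scenario("fig10")
#' traj <- simulate_scenario(scn)
#' peak(traj)
#' }
#' @export
simulate_scenario <- function(scn, rtol = 1e-8, atol = 1e-15,
                              quasi_steady = FALSE, grid_points = 400) {
  stopifnot(inherits(scn, "ros_scenario"))
  p <- scn$params; pop <- scn$population
  strains <- scn$strains; m <- length(strains)
  has_mem <- vapply(strains, `[[`, logical(1), "has_membrane")
  endog <- vapply(strains, `[[`, logical(1), "endogenous_production")
  va <- vapply(strains, function(s) s$ahp_factor * p$vmax_ahp, numeric(1))
  vc <- vapply(strains, function(s) s$cat_factor * p$vmax_cat, numeric(1))
  kenz <- va / p$km_ahp + vc / p$km_cat
  kprod <- ifelse(endog, p$k1_prime + p$k1 / 2, 0)

  # initial state
  init <- scn$init_internal
  if (identical(init, "steady")) {
    cin0 <- ifelse(kenz > 0, kprod / kenz, 0)
    o20 <- ifelse(endog, p$k1 / p$k2_sod, 0)
  } else if (identical(init, "zero")) {
    cin0 <- rep(0, m)
    o20 <- ifelse(endog & quasi_steady, p$k1 / p$k2_sod, 0)
  } else if (is.numeric(init) && length(init) == m) {
    cin0 <- init
    o20 <- ifelse(endog, p$k1 / p$k2_sod, 0)
  } else stop("init_internal must be 'steady', 'zero' or one value per strain",
              call. = FALSE)
  if (quasi_steady) o20 <- ifelse(endog, p$k1 / p$k2_sod, 0)
  cout0 <- 0

  ev <- scn$stress_events
  ev_times <- if (is.null(ev)) numeric(0) else ev$time
  lag_ends <- if (pop$growth_mode == "logistic" && length(ev_times))
    ev_times + pop$lag_duration else numeric(0)
  bounds <- sort(unique(c(0, ev_times, lag_ends, scn$t_end)))
  bounds <- bounds[bounds >= 0 & bounds <= scn$t_end]

  n_seg <- scn$densities
  last_event <- -Inf
  y <- c(cin0, o20, cout0)
  rows <- vector("list", length(bounds) - 1L)

  for (k in seq_len(length(bounds) - 1L)) {
    t0 <- bounds[k]; t1 <- bounds[k + 1L]
    if (length(ev_times) && any(abs(ev_times - t0) < 1e-12)) {
      amt <- sum(ev$amount[abs(ev$time - t0) < 1e-12])
      y[2L * m + 1L] <- y[2L * m + 1L] + amt
      y[seq_len(m)][!has_mem] <- y[2L * m + 1L]   # extract pool == medium
      last_event <- t0
    }
    growing <- pop$growth_mode == "logistic" &&
      !(t0 >= last_event && t0 < last_event + pop$lag_duration)

    dens_at <- function(t) {
      if (!growing) n_seg
      else vapply(n_seg, verhulst_from, numeric(1), dt = t - t0,
                  tau_d = pop$tau_d, n_max = pop$n_max)
    }
    func <- function(t, yy, parms) {
      cin <- yy[seq_len(m)]
      o2 <- yy[m + seq_len(m)]
      cout <- yy[2L * m + 1L]
      nn <- dens_at(t)
      vfree <- pop$vout - sum(nn) * p$vin
      frac <- nn * p$vin / vfree
      prod <- if (quasi_steady) kprod
              else ifelse(endog, p$k1_prime + 0.5 * p$k2_sod * o2, 0)
      scav_in <- va * cin / (cin + p$km_ahp) + vc * cin / (cin + p$km_cat)
      scav_out <- va * cout / (cout + p$km_ahp) + vc * cout / (cout + p$km_cat)
      dcin <- ifelse(has_mem,
                     prod - scav_in - p$kdiff * (cin - cout),
                     0)
      dcout <- sum(ifelse(has_mem,
                          p$kdiff * frac * (cin - cout),
                          frac * (prod - scav_out)))
      dcin[!has_mem] <- dcout
      do2 <- if (quasi_steady) rep(0, m)
             else ifelse(endog, p$k1 - p$k2_sod * o2, 0)
      list(c(dcin, do2, dcout))
    }

    tt <- segment_times(t0, t1, grid_points)
    out <- deSolve::ode(y = y, times = tt, func = func, parms = NULL,
                        method = "lsoda", rtol = rtol, atol = atol,
                        maxsteps = 5e5)
    if (nrow(out) < length(tt) || anyNA(out))
      stop("ODE solver failed in segment [", t0, ", ", t1, "] s; ",
           "last valid state: ",
           paste(signif(out[nrow(out), ], 4), collapse = " "), call. = FALSE)
    dens <- matrix(vapply(out[, 1], dens_at, numeric(m)),
                   ncol = m, byrow = TRUE)
    block <- cbind(out[, -1, drop = FALSE], dens)
    # drop the duplicated segment-start row except for the very first segment
    keep <- if (k == 1L) seq_len(nrow(out)) else -1L
    rows[[k]] <- cbind(time = out[keep, 1], block[keep, , drop = FALSE])
    y <- as.numeric(out[nrow(out), -1])
    n_seg <- dens[nrow(dens), ]
  }

  res <- do.call(rbind, rows)
  conc <- res[, 1L + seq_len(2L * m + 1L), drop = FALSE]
  lowest <- min(conc)
  if (lowest < -10 * atol)
    stop("negative concentration beyond solver tolerance: ", lowest,
         call. = FALSE)
  conc[conc < 0] <- 0
  lab <- scn$strain_labels
  df <- data.frame(time_s = res[, 1], h2o2_out_M = conc[, 2L * m + 1L])
  for (i in seq_len(m)) {
    df[[paste0("h2o2_in_M.", lab[i])]] <- conc[, i]
    df[[paste0("superoxide_M.", lab[i])]] <- conc[, m + i]
    df[[paste0("density_per_L.", lab[i])]] <- res[, 1L + 2L * m + 1L + i]
  }
  structure(df, class = c("ros_trajectory", "data.frame"),
            strain_labels = lab,
            meta = list(scenario = scn$label, rtol = rtol, atol = atol,
                        quasi_steady = quasi_steady))
}

#' @export
print.ros_trajectory <- function(x, ...) {
  lab <- attr(x, "strain_labels")
  cat("<ros_trajectory> ", attr(x, "meta")$scenario, ": ",
      nrow(x), " time points over [", signif(min(x$time_s), 3), ", ",
      signif(max(x$time_s), 3), "] s, strains: ",
      paste(lab, collapse = ", "), "\n", sep = "")
  utils::str(unclass(x)[seq_len(min(4, length(x)))], give.attr = FALSE)
  invisible(x)
}

# Resolve a strain identifier (index or label) to its label.
strain_label <- function(trajectory, strain) {
  lab <- attr(trajectory, "strain_labels")
  if (is.numeric(strain)) {
    if (strain < 1 || strain > length(lab))
      stop("strain index out of range", call. = FALSE)
    lab[strain]
  } else {
    if (!strain %in% lab)
      stop("unknown strain label '", strain, "'", call. = FALSE)
    strain
  }
}

#' Extract one series from a trajectory
#'
#' @param trajectory a `ros_trajectory`.
#' @param series one of `"h2o2_in"`, `"superoxide"`, `"density"`,
#'   `"h2o2_out"`.
#' @param strain strain index or label (ignored for `"h2o2_out"`).
#' @return numeric vector aligned with `trajectory$time_s`.
#' @export
trajectory_series <- function(trajectory,
                              series = c("h2o2_in", "superoxide", "density",
                                         "h2o2_out"),
                              strain = 1L) {
  series <- match.arg(series)
  if (series == "h2o2_out") return(trajectory$h2o2_out_M)
  lab <- strain_label(trajectory, strain)
  col <- switch(series,
                h2o2_in = paste0("h2o2_in_M.", lab),
                superoxide = paste0("superoxide_M.", lab),
                density = paste0("density_per_L.", lab))
  trajectory[[col]]
}
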