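#' Internal H2O2 peak of a simulated trajectory
#'
#' Maximum of the internal series with quadratic refinement: when the grid
#' maximum is interior, a parabola through the three bracketing samples
#' refines both the peak time and height. A monotone series returns its last
#' sample.
#'
#' @param trajectory a `ros_trajectory`.
#' @param strain strain index or label.
#' @return list with `cmax` (mol/L) and `tmax` (s).
#' @export
peak <- function(trajectory, strain = 1L) {
  y <- trajectory_series(trajectory, "h2o2_in", strain)
  t <- trajectory$time_s
  if (!length(y)) stop("empty trajectory", call. = FALSE)
  i <- which.max(y)
  if (i == 1L || i == length(y))
    return(list(cmax = y[i], tmax = t[i]))
  ti <- t[(i - 1):(i + 1)]; yi <- y[(i - 1):(i + 1)]
  fit <- stats::lm.fit(cbind(1, ti, ti^2), yi)$coefficients
  if (is.na(fit[3]) || fit[3] >= 0)          # degenerate: keep grid maximum
    return(list(cmax = y[i], tmax = t[i]))
  tv <- -fit[2] / (2 * fit[3])
  if (tv < ti[1] || tv > ti[3]) return(list(cmax = y[i], tmax = t[i]))
  list(cmax = unname(fit[1] + fit[2] * tv + fit[3] * tv^2), tmax = unname(tv))
}

#' Half-life of a concentration series
#'
#' First time the series crosses half of its reference value, with linear
#' interpolation between samples. The external series is referenced to its
#' initial value; the internal series to its peak (the decay after the
#' maximum is what the half-life describes). Returns `NA` when the series
#' never reaches half the reference within the trajectory (the "not reached"
#' signal, distinct from an error).
#'
#' @param trajectory a `ros_trajectory`.
#' @param species `"external"` or `"internal"`.
#' @param strain strain index or label (internal series).
#' @param reference `"initial"` or `"peak"`; defaults to `"initial"` for the
#'   external series and `"peak"` for the internal one.
#' @return time from the reference point to the crossing, s, or `NA`.
#' @export
half_life <- function(trajectory, species = c("external", "internal"),
                      strain = 1L, reference = NULL) {
  species <- match.arg(species)
  t <- trajectory$time_s
  if (species == "external") {
    y <- trajectory$h2o2_out_M
    if (is.null(reference)) reference <- "initial"
  } else {
    y <- trajectory_series(trajectory, "h2o2_in", strain)
    if (is.null(reference)) reference <- "peak"
  }
  if (reference == "initial") {
    i0 <- 1L
  } else if (reference == "peak") {
    i0 <- which.max(y)
  } else stop("reference must be 'initial' or 'peak'", call. = FALSE)
  ref <- y[i0]
  if (ref <= 0) return(NA_real_)
  target <- ref / 2
  yy <- y[i0:length(y)]; tt <- t[i0:length(t)]
  below <- which(yy <= target)
  if (!length(below)) return(NA_real_)
  j <- below[1]
  if (j == 1L) return(0)
  frac <- (yy[j - 1] - target) / (yy[j - 1] - yy[j])
  tt[j - 1] + frac * (tt[j] - tt[j - 1]) - tt[1]
}

#' Cumulative internal H2O2 exposure
#'
#' Trapezoidal time integral of the internal concentration over a window —
#' the concentration-time dose (mol/L * s) proposed as the determinant of
#' H2O2-mediated killing. Unlike the peak height, it depends strongly on
#' cell density, because denser populations clear the medium faster.
#'
#' @param trajectory a `ros_trajectory`.
#' @param strain strain index or label.
#' @param window length-2 numeric, integration window in s; defaults to the
#'   whole trajectory.
#' @return dose in mol/L * s; `as_uM_min = TRUE` reports µM·min instead.
#' @param as_uM_min report in µM·min (1 mol/L*s = 1e6/60 µM·min).
#' @export
cumulative_dose <- function(trajectory, strain = 1L, window = NULL,
                            as_uM_min = FALSE) {
  t <- trajectory$time_s
  y <- trajectory_series(trajectory, "h2o2_in", strain)
  if (is.null(window)) window <- range(t)
  if (window[1] < min(t) - 1e-9 || window[2] > max(t) + 1e-9)
    stop("window [", window[1], ", ", window[2],
         "] s lies outside the trajectory span", call. = FALSE)
  keep <- t > window[1] & t < window[2]
  tt <- c(window[1], t[keep], window[2])
  yy <- c(stats::approx(t, y, xout = window[1])$y, y[keep],
          stats::approx(t, y, xout = window[2])$y)
  dose <- sum(diff(tt) * (utils::head(yy, -1) + utils::tail(yy, -1)) / 2)
  if (as_uM_min) dose * 1e6 / 60 else dose
}

#' Medium decomposition rate versus external concentration
#'
#' For each external concentration the internal pool is assumed quasi-steady:
#' `kdiff (C_out - C) + k_prod = scavenging(C)` is solved for C by bracketed
#' root finding, and the medium decomposition rate
#' `kdiff' (C_out - C)` is returned. The classic mutant comparison plots the
#' Ahp-only strain (Cat-null) against the Cat-only strain (Ahp-null): Ahp
#' wins at micromolar concentrations, saturates, and Cat takes over around
#' ~17 µM.
#'
#' @param params a [kinetic_params()].
#' @param strain a [strain_config()].
#' @param external_range numeric vector of external concentrations, mol/L.
#' @param n cell density, cells/L.
#' @param population a [population_model()].
#' @return data.frame with columns `external_M`, `internal_M`,
#'   `rate_M_per_s`.
#' @export
decomposition_rate_curve <- function(params, strain = wild_type(),
                                     external_range, n,
                                     population = population_model()) {
  if (any(external_range <= 0))
    stop("external_range must be positive", call. = FALSE)
  rates <- derived_rates(params, strain, population, n)
  kprod <- rates$kprod
  internal <- vapply(external_range, function(cout) {
    f <- function(c) params$kdiff * (cout - c) + kprod -
      scavenging_flux(c, params, strain)
    upper <- cout + kprod / params$kdiff
    if (f(upper) >= 0) return(upper)     # no scavenging: pool equilibrates
    uniroot(f, c(0, upper), tol = upper * 1e-13)$root
  }, numeric(1))
  data.frame(external_M = external_range, internal_M = internal,
             rate_M_per_s = rates$kdiff_prime * (external_range - internal))
}

#' @rdname decomposition_rate_curve
#' @param ahp_factor,cat_factor enzyme levels used for the two single-enzyme
#'   strains being intersected (e.g. `cat_factor = 7` for induced Cat).
#' @param interval search interval for the crossover, mol/L.
#' @return `ahp_cat_crossover`: the external concentration (mol/L) where the
#'   Ahp-only and Cat-only decomposition curves intersect, or `NA` if they do
#'   not cross in `interval`.
#' @export
ahp_cat_crossover <- function(params, n, population = population_model(),
                              ahp_factor = 1, cat_factor = 1,
                              interval = c(1e-6, 1e-3)) {
  ahp_only <- strain_config("ahp_only", ahp_factor = ahp_factor,
                            cat_factor = 0)
  cat_only <- strain_config("cat_only", ahp_factor = 0,
                            cat_factor = cat_factor)
  gap <- function(lc) {
    cout <- 10^lc
    a <- decomposition_rate_curve(params, ahp_only, cout, n, population)
    b <- decomposition_rate_curve(params, cat_only, cout, n, population)
    a$rate_M_per_s - b$rate_M_per_s
  }
  lo <- log10(interval[1]); hi <- log10(interval[2])
  if (gap(lo) * gap(hi) > 0) return(NA_real_)
  10^uniroot(gap, c(lo, hi), tol = 1e-10)$root
}

#' All dose metrics for one strain of a trajectory
#'
#' Convenience wrapper collecting [peak()], [half_life()] and
#' [cumulative_dose()] into one row.
#'
#' @param trajectory a `ros_trajectory`.
#' @param strain strain index or label.
#' @return one-row data.frame with `strain`, `cmax_M`, `tmax_s`,
#'   `t_half_external_s`, `t_half_internal_s`, `cumulative_dose_M_s`.
#' @export
dose_metrics <- function(trajectory, strain = 1L) {
  pk <- peak(trajectory, strain)
  data.frame(
    strain = strain_label(trajectory, strain),
    cmax_M = pk$cmax,
    tmax_s = pk$tmax,
    t_half_external_s = half_life(trajectory, "external"),
    t_half_internal_s = half_life(trajectory, "internal", strain),
    cumulative_dose_M_s = cumulative_dose(trajectory, strain)
  )
}
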