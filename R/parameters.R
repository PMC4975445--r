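#' Kinetic parameter set for the H2O2 / superoxide model
#'
#' Bundles every rate constant and volume of the model. The defaults are the
#' published kinetic constants for exponentially growing *E. coli*:
#' superoxide production `k1`, the SOD dismutation pseudo-first-order constant
#' `k2_sod` (= k2\[SOD\]), direct endogenous H2O2 production `k1_prime`, the
#' lumped Michaelis–Menten capacities `vmax_ahp` (= kcat_Ahp\[Ahp\]) and
#' `vmax_cat` (= kcat_Kat\[Cat\]) with their Michaelis constants, the membrane
#' diffusion rate constant `kdiff`, and the single-cell volume `vin`.
#'
#' All quantities are SI-molar and seconds: mol/L, s, L. When `permeability`
#' (P, cm/s) and `area` (A, cm^2) are both supplied, `kdiff` must agree with
#' P·A/V within 1% (see [membrane_kdiff()]).
#'
#' @param k1 superoxide production rate, mol/L/s.
#' @param k2 SOD rate constant, /mol/L/s (informational; the model uses
#'   `k2_sod`).
#' @param k2_sod lumped SOD dismutation constant k2\[SOD\], /s.
#' @param k1_prime direct endogenous H2O2 production rate, mol/L/s.
#' @param vmax_ahp,km_ahp Ahp capacity (mol/L/s) and Michaelis constant (mol/L).
#' @param vmax_cat,km_cat Cat capacity (mol/L/s) and Michaelis constant (mol/L).
#' @param kdiff membrane diffusion rate constant, /s.
#' @param vin single-cell internal volume, L.
#' @param permeability optional membrane permeability P, cm/s.
#' @param area optional membrane surface area A, cm^2.
#' @return an object of class `kinetic_params`.
#' @examples
#' p <- kinetic_params()
#' effective_production(p) # 1.485e-05 mol/L/s
#' @export
kinetic_params <- function(k1 = 5.7e-6,
                           k2 = 1.5e9,
                           k2_sod = 2.8e4,
                           k1_prime = 12e-6,
                           vmax_ahp = 6.6e-4,
                           km_ahp = 1.2e-6,
                           vmax_cat = 4.9e-1,
                           km_cat = 5.9e-3,
                           kdiff = 70,
                           vin = 3.2e-15,
                           permeability = NULL,
                           area = NULL) {
  p <- list(k1 = k1, k2 = k2, k2_sod = k2_sod, k1_prime = k1_prime,
            vmax_ahp = vmax_ahp, km_ahp = km_ahp,
            vmax_cat = vmax_cat, km_cat = km_cat,
            kdiff = kdiff, vin = vin,
            permeability = permeability, area = area)
  num <- p[!vapply(p, is.null, logical(1))]
  bad <- names(num)[!vapply(num, function(v)
    is.numeric(v) && length(v) == 1L && is.finite(v) && v > 0, logical(1))]
  if (length(bad))
    stop("kinetic parameters must be single positive numbers: ",
         paste(bad, collapse = ", "), call. = FALSE)
  if (!is.null(permeability) && !is.null(area)) {
    kd <- membrane_kdiff(permeability, area, vin)
    if (abs(kd - kdiff) / kdiff > 0.01)
      stop("kdiff (", kdiff, " /s) disagrees with P*A/V (",
           signif(kd, 4), " /s) by more than 1%", call. = FALSE)
  }
  structure(p, class = "kinetic_params")
}

#' @export
print.kinetic_params <- function(x, ...) {
  cat("<kinetic_params>  (mol/L, s)\n")
  flds <- x[!vapply(x, is.null, logical(1))]
  cat(paste0("  ", format(names(flds), width = 13), signif(unlist(flds), 4),
             collapse = "\n"), "\n")
  invisible(x)
}

#' Membrane diffusion rate constant from permeability
#'
#' `kdiff = P * A / V`, with P in cm/s, A in cm^2 and V in litres
#' (1 cm^3 = 1e-3 L).
#'
#' @param permeability membrane permeability P, cm/s.
#' @param area membrane surface area A, cm^2.
#' @param vin cell volume, L.
#' @return first-order diffusion rate constant, /s.
#' @examples
#' membrane_kdiff(1.6e-3, 1.41e-7, 3.2e-15) # ~70.5 /s
#' @export
membrane_kdiff <- function(permeability, area, vin) {
  for (v in list(permeability, area, vin))
    if (!is.numeric(v) || length(v) != 1L || !is.finite(v) || v <= 0)
      stop("permeability, area and vin must be single positive numbers",
           call. = FALSE)
  permeability * area * 1e-3 / vin
}

#' Net endogenous H2O2 production rate
#'
#' Half of each dismutated superoxide ends up as H2O2, so at superoxide
#' quasi-steady state the net production is `k_prod = k1' + k1/2`.
#'
#' @param params a [kinetic_params()] object.
#' @return production rate, mol/L/s.
#' @export
effective_production <- function(params) {
  stopifnot(inherits(params, "kinetic_params"))
  params$k1_prime + params$k1 / 2
}

#' Superoxide steady state and relaxation time
#'
#' Superoxide balances production against SOD dismutation, relaxing
#' exponentially to `k1 / k2[SOD]` with time constant `1 / k2[SOD]`
#' (about 35 microseconds) — fast enough that the H2O2 equations may treat
#' it as a constant.
#'
#' @param params a [kinetic_params()] object.
#' @return steady-state concentration, mol/L.
#' @export
superoxide_steady_state <- function(params) {
  stopifnot(inherits(params, "kinetic_params"))
  params$k1 / params$k2_sod
}

#' @rdname superoxide_steady_state
#' @return `superoxide_relaxation_time`: relaxation time 1/k2\[SOD\], s.
#' @export
superoxide_relaxation_time <- function(params) {
  stopifnot(inherits(params, "kinetic_params"))
  1 / params$k2_sod
}

#' Strain genotype configuration
#'
#' Scales the wild-type enzyme capacities and toggles membrane and endogenous
#' metabolism. `ahp_factor`/`cat_factor` multiply `vmax_ahp`/`vmax_cat`
#' (0 = null mutant; 7 = the induced Cat level reported for Ahp-null cells).
#' `has_membrane = FALSE` models a cell extract whose enzymes sit directly in
#' the medium; `endogenous_production = FALSE` removes k1 and k1' (extracts
#' have no ROS-producing metabolism).
#'
#' @param label free-text strain label.
#' @param ahp_factor,cat_factor non-negative multipliers on enzyme capacity.
#' @param has_membrane logical; `FALSE` for cell extracts.
#' @param endogenous_production logical; `FALSE` disables k1 and k1'.
#' @return an object of class `strain_config`.
#' @export
strain_config <- function(label = "strain",
                          ahp_factor = 1,
                          cat_factor = 1,
                          has_membrane = TRUE,
                          endogenous_production = TRUE) {
  if (!is.numeric(ahp_factor) || ahp_factor < 0 ||
      !is.numeric(cat_factor) || cat_factor < 0)
    stop("enzyme factors must be >= 0", call. = FALSE)
  structure(list(label = as.character(label),
                 ahp_factor = ahp_factor, cat_factor = cat_factor,
                 has_membrane = isTRUE(has_membrane),
                 endogenous_production = isTRUE(endogenous_production)),
            class = "strain_config")
}

#' @rdname strain_config
#' @export
wild_type <- function(label = "wild_type") strain_config(label = label)

#' @rdname strain_config
#' @param cat_induction Cat multiplier for the Ahp-null strain (1 = basal,
#'   7 = induced level).
#' @export
ahp_null <- function(cat_induction = 1, label = "ahp_null")
  strain_config(label = label, ahp_factor = 0, cat_factor = cat_induction)

#' @rdname strain_config
#' @export
cat_null <- function(label = "cat_null")
  strain_config(label = label, cat_factor = 0)

#' @export
print.strain_config <- function(x, ...) {
  cat("<strain_config> ", x$label,
      "  Ahp x", x$ahp_factor, "  Cat x", x$cat_factor,
      if (!x$has_membrane) "  [extract]" else "",
      if (!x$endogenous_production) "  [no endogenous production]" else "",
      "\n", sep = "")
  invisible(x)
}

#' Population / medium configuration
#'
#' Describes the shared medium and the growth law. Growth is either constant
#' density or logistic (Verhulst) with rate `r = ln2 / tau_d`; after an
#' oxidative-stress event, growth is frozen for `lag_duration` (the ~40 min
#' lag observed after sub-lethal H2O2 additions).
#'
#' @param vout total medium volume, L.
#' @param growth_mode `"constant"` or `"logistic"`.
#' @param tau_d doubling time, s (logistic mode; default 20 min).
#' @param n_max carrying capacity, cells/L (default 5e9 cells/mL).
#' @param lag_duration post-stress growth freeze, s (default 40 min).
#' @param n0 optional default initial density, cells/L.
#' @return an object of class `population_model`.
#' @export
population_model <- function(vout = 1,
                             growth_mode = c("constant", "logistic"),
                             tau_d = 1200,
                             n_max = 5e12,
                             lag_duration = 2400,
                             n0 = NULL) {
  growth_mode <- match.arg(growth_mode)
  if (vout <= 0) stop("vout must be positive", call. = FALSE)
  if (tau_d <= 0 || n_max <= 0 || lag_duration < 0)
    stop("tau_d and n_max must be positive, lag_duration >= 0", call. = FALSE)
  if (!is.null(n0)) {
    if (n0 <= 0) stop("n0 must be positive", call. = FALSE)
    if (growth_mode == "logistic" && n0 > n_max)
      stop("n0 exceeds carrying capacity n_max", call. = FALSE)
  }
  structure(list(vout = vout, growth_mode = growth_mode, tau_d = tau_d,
                 n_max = n_max, lag_duration = lag_duration, n0 = n0),
            class = "population_model")
}

#' @export
print.population_model <- function(x, ...) {
  cat("<population_model> vout =", x$vout, "L, growth =", x$growth_mode)
  if (x$growth_mode == "logistic")
    cat(" (tau_d =", x$tau_d, "s, n_max =", format(x$n_max),
        "cells/L, lag =", x$lag_duration, "s)")
  cat("\n")
  invisible(x)
}

# Guard shared by every routine that scales kdiff by the cell volume fraction.
check_cell_volume <- function(n_total, vin, vout) {
  if (vout - n_total * vin <= 0)
    stop("invalid configuration: total cell volume (n*vin = ",
         signif(n_total * vin, 4), " L) must stay below the medium volume (",
         vout, " L)", call. = FALSE)
  invisible(TRUE)
}
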