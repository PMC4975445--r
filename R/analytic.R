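#' Classify the exogenous-stress regime
#'
#' The Michaelis–Menten system only linearises cleanly at the two ends of the
#' concentration range: below ~10 µM external H2O2, Ahp works in its linear
#' range (`LOW`); above ~30 µM, Ahp is saturated and only Cat remains linear
#' (`HIGH`). In between (`INTERMEDIATE`) no closed form applies and callers
#' must use the numerical simulator.
#'
#' @param external0 initial external H2O2 concentration, mol/L.
#' @param low_threshold,high_threshold regime boundaries, mol/L.
#' @return `"LOW"`, `"INTERMEDIATE"` or `"HIGH"`.
#' @examples
#' classify_regime(1.5e-6) # "LOW"
#' classify_regime(1e-3)   # "HIGH"
#' @export
classify_regime <- function(external0, low_threshold = 10e-6,
                            high_threshold = 30e-6) {
  if (low_threshold >= high_threshold)
    stop("low_threshold must be below high_threshold", call. = FALSE)
  if (external0 < 0) stop("external0 must be >= 0", call. = FALSE)
  if (external0 < low_threshold) "LOW"
  else if (external0 > high_threshold) "HIGH"
  else "INTERMEDIATE"
}

# Effective (kprod, kenz) pair for a regime, from the derived-rates bundle.
regime_rates <- function(rates, regime) {
  switch(regime,
    LOW = list(kprod_eff = rates$kprod, kenz_eff = rates$kenz),
    HIGH = list(kprod_eff = rates$kprod_prime, kenz_eff = rates$kenz_prime),
    stop("no closed-form solution in the INTERMEDIATE regime (10-30 uM); ",
         "use the numerical simulator", call. = FALSE)
  )
}

#' Closed-form solution of the linearised two-compartment system
#'
#' In a linear regime the internal/external pair obeys a 2x2 linear ODE whose
#' eigenvalues are the exact roots
#' \deqn{\lambda_{1,2} = \frac{-(k_{enz}+k_{diff}+k'_{diff}) \pm
#'   \sqrt{(k_{enz}+k_{diff}+k'_{diff})^2 - 4 k_{enz} k'_{diff}}}{2}}
#' and the trajectory is bi-exponential:
#' \deqn{[H2O2](t) = (k'_{diff}+\lambda_1) A e^{\lambda_1 t} +
#'   (k'_{diff}+\lambda_2) B e^{\lambda_2 t} + k_{prod}/k_{enz}.}
#' In the HIGH regime `kenz` and `kprod` are replaced by their Ahp-saturated
#' counterparts. Eigenvalues are always the exact quadratic roots; the
#' paper-style approximations are available from [lambda_approx()].
#'
#' @param params a [kinetic_params()].
#' @param strain a [strain_config()].
#' @param n cell density, cells/L (must be > 0).
#' @param external0 initial external H2O2 concentration, mol/L.
#' @param init_in initial internal concentration, mol/L; defaults to the
#'   pre-stress steady state `k_prod/k_enz`.
#' @param population a [population_model()].
#' @param regime override the regime classification (`"LOW"`/`"HIGH"`).
#' @return an object of class `linear_solution` with fields `regime`,
#'   `kprod_eff`, `kenz_eff`, `kdiff`, `kdiff_prime`, `lambda_slow`,
#'   `lambda_fast`, `coef_slow`, `coef_fast`, `init_in`, `init_out`,
#'   `steady_state`, and evaluator functions `internal(t)`, `external(t)`.
#' @export
solve_linear <- function(params, strain = wild_type(), n, external0,
                         init_in = NULL, population = population_model(),
                         regime = NULL) {
  if (n <= 0) stop("solve_linear needs a positive cell density", call. = FALSE)
  if (is.null(regime)) regime <- classify_regime(external0)
  rates <- derived_rates(params, strain, population, n)
  eff <- regime_rates(rates, regime)
  if (eff$kenz_eff <= 0)
    stop("effective scavenging constant is zero in this regime; ",
         "no linear steady state exists", call. = FALSE)
  kdiff <- params$kdiff
  kdp <- rates$kdiff_prime
  if (is.null(init_in)) {
    if (rates$kenz <= 0)
      stop("cannot take the default pre-stress steady state with zero ",
           "total scavenging; supply init_in", call. = FALSE)
    init_in <- rates$kprod / rates$kenz
  }

  S <- eff$kenz_eff + kdiff + kdp
  P <- eff$kenz_eff * kdp
  disc <- sqrt(S^2 - 4 * P)
  l2 <- (-S - disc) / 2     # fast eigenvalue
  l1 <- -P / abs(l2)        # slow root via Vieta: avoids cancellation in -S+disc
  cinf <- eff$kprod_eff / eff$kenz_eff
  a <- init_in - cinf
  b <- external0 - cinf
  A <- (a * kdp - b * (kdp + l2)) / ((l1 - l2) * kdp)
  B <- (a * kdp - b * (kdp + l1)) / ((l2 - l1) * kdp)

  sol <- list(
    regime = regime, kprod_eff = eff$kprod_eff, kenz_eff = eff$kenz_eff,
    kdiff = kdiff, kdiff_prime = kdp,
    lambda_slow = l1, lambda_fast = l2,
    coef_slow = A, coef_fast = B,
    init_in = init_in, init_out = external0, steady_state = cinf,
    internal = function(t)
      (kdp + l1) * A * exp(l1 * t) + (kdp + l2) * B * exp(l2 * t) + cinf,
    external = function(t)
      kdp * A * exp(l1 * t) + kdp * B * exp(l2 * t) + cinf
  )
  class(sol) <- "linear_solution"
  sol
}

#' @export
print.linear_solution <- function(x, ...) {
  cat("<linear_solution> regime", x$regime,
      "\n  lambda_slow ", signif(x$lambda_slow, 6), "/s",
      "  lambda_fast ", signif(x$lambda_fast, 6), "/s",
      "\n  steady state", signif(x$steady_state, 4), "mol/L\n")
  invisible(x)
}

#' Paper-style eigenvalue approximations
#'
#' The widely separated timescales admit the approximations
#' `lambda_slow ~ -kenz * kdiff' / (kenz + kdiff)` and
#' `lambda_fast ~ -(kenz + kdiff)` (regime-effective constants). Provided
#' separately so the exact roots used everywhere else can be checked against
#' them.
#'
#' @inheritParams solve_linear
#' @return list with `lambda_slow` and `lambda_fast`, /s.
#' @export
lambda_approx <- function(params, strain = wild_type(), n,
                          population = population_model(), regime = "LOW") {
  rates <- derived_rates(params, strain, population, n)
  eff <- regime_rates(rates, regime)
  list(lambda_slow = -eff$kenz_eff * rates$kdiff_prime /
         (eff$kenz_eff + params$kdiff),
       lambda_fast = -(eff$kenz_eff + params$kdiff))
}

#' Steady states and plateau of the unstressed cell
#'
#' `steady_state_linear()` is the linear-regime balance `k_prod / k_enz`
#' (~23.5 nM for the wild type; ~179 nM for an Ahp-null strain without Cat
#' induction). `plateau_concentration()` is the early quasi-plateau
#' `k_prod / (k_enz + k_diff)` reached before the medium fills (~21 nM).
#' `steady_state_nonlinear()` keeps the full Michaelis–Menten scavenging and
#' solves `k_prod = Vmax_Ahp C/(C+KM_Ahp) + Vmax_Cat C/(C+KM_Cat)` for C by
#' bracketed root finding (~23.9 nM for the wild type).
#'
#' @param params a [kinetic_params()].
#' @param strain a [strain_config()].
#' @return concentration, mol/L.
#' @export
steady_state_linear <- function(params, strain = wild_type()) {
  kenz <- strain$ahp_factor * params$vmax_ahp / params$km_ahp +
    strain$cat_factor * params$vmax_cat / params$km_cat
  if (kenz <= 0) stop("zero scavenging: no linear steady state", call. = FALSE)
  kprod <- if (strain$endogenous_production) effective_production(params) else 0
  kprod / kenz
}

#' @rdname steady_state_linear
#' @export
plateau_concentration <- function(params, strain = wild_type()) {
  kenz <- strain$ahp_factor * params$vmax_ahp / params$km_ahp +
    strain$cat_factor * params$vmax_cat / params$km_cat
  kprod <- if (strain$endogenous_production) effective_production(params) else 0
  kprod / (kenz + params$kdiff)
}

#' @rdname steady_state_linear
#' @export
steady_state_nonlinear <- function(params, strain = wild_type()) {
  kprod <- if (strain$endogenous_production) effective_production(params) else 0
  if (kprod == 0) return(0)
  vtot <- strain$ahp_factor * params$vmax_ahp +
    strain$cat_factor * params$vmax_cat
  if (vtot <= kprod)
    stop("production (", signif(kprod, 4), " mol/L/s) exceeds total ",
         "scavenging capacity (", signif(vtot, 4),
         " mol/L/s): no steady state", call. = FALSE)
  scale <- steady_state_linear(params, strain)  # lower bound on the root
  f <- function(c) scavenging_flux(c, params, strain) - kprod
  uniroot(f, interval = c(scale / 2, scale * 1e3), extendInt = "upX",
          tol = scale * 1e-13)$root
}

#' Time of the internal H2O2 peak
#'
#' After an exogenous step the internal concentration rises on the fast
#' eigenmode and decays on the slow one; the peak sits at
#' `t_max = ln(lambda1/lambda2) / (lambda2 - lambda1)` (exact eigenvalues).
#' About 18 ms at 1e7 cells/mL and weakly density-dependent.
#'
#' @param solution a [solve_linear()] result.
#' @return time of the peak, s.
#' @export
tmax_analytic <- function(solution) {
  stopifnot(inherits(solution, "linear_solution"))
  l1 <- solution$lambda_slow; l2 <- solution$lambda_fast
  log(l1 / l2) / (l2 - l1)
}

#' Maximal internal H2O2 concentration after an exogenous step
#'
#' The peak is set by the balance between diffusive influx and elimination:
#' `C_max ~ kdiff * C_out0 / (kdiff + kenz)` in the LOW regime (about one
#' tenth of the added concentration for the wild type) and
#' `C_max ~ kdiff * C_out0 / (kdiff + kenz')` in the HIGH regime (about half).
#' `corrected = TRUE` additionally carries the saturated Ahp flux and the
#' endogenous production through the quasi-steady balance
#' (`(kdiff*C_out0 + kprod - Vmax_Ahp)/(kdiff + kenz')`), which is what the
#' full simulation realises; the plain formula is the default.
#'
#' @inheritParams solve_linear
#' @param regime `"LOW"` or `"HIGH"`; classified from `external0` if `NULL`.
#' @param corrected HIGH regime only: subtract the saturated Ahp flux.
#' @return peak concentration, mol/L. The ratio to the added concentration is
#'   available as `cmax_ratio()`.
#' @export
cmax_analytic <- function(params, strain = wild_type(), external0,
                          regime = NULL, corrected = FALSE) {
  if (is.null(regime)) regime <- classify_regime(external0)
  kenz_eff <- switch(regime,
    LOW = strain$ahp_factor * params$vmax_ahp / params$km_ahp +
      strain$cat_factor * params$vmax_cat / params$km_cat,
    HIGH = strain$cat_factor * params$vmax_cat / params$km_cat,
    stop("no closed-form C_max in the INTERMEDIATE regime", call. = FALSE))
  if (corrected && regime == "HIGH") {
    kprod <- if (strain$endogenous_production) effective_production(params)
             else 0
    kprod_prime <- kprod - strain$ahp_factor * params$vmax_ahp
    (params$kdiff * external0 + kprod_prime) / (params$kdiff + kenz_eff)
  } else {
    params$kdiff * external0 / (params$kdiff + kenz_eff)
  }
}

#' @rdname cmax_analytic
#' @export
cmax_ratio <- function(params, strain = wild_type(), external0,
                       regime = NULL, corrected = FALSE) {
  cmax_analytic(params, strain, external0, regime, corrected) / external0
}

#' External H2O2 half-life in a linear regime
#'
#' Medium detoxification rides the slow eigenmode. In the LOW regime the
#' decay constant is `kdiff'` so `t_1/2 = ln2 / kdiff'` (210 s at 1.45e7
#' cells/mL, inversely proportional to density). In the HIGH regime the slow
#' eigenvalue is `-kenz' kdiff' / (kenz' + kdiff)`, giving
#' `t_1/2 = ln2 (kenz' + kdiff) / (kenz' kdiff')` (~6.5 min for 1 mM at
#' 1.45e7 cells/mL).
#'
#' @inheritParams solve_linear
#' @param regime `"LOW"` or `"HIGH"`.
#' @return half-life, s.
#' @export
half_life_external <- function(params, strain = wild_type(), n,
                               regime = "LOW",
                               population = population_model()) {
  if (n <= 0) stop("n must be positive", call. = FALSE)
  rates <- derived_rates(params, strain, population, n)
  switch(regime,
    LOW = log(2) / rates$kdiff_prime,
    HIGH = {
      if (rates$kenz_prime <= 0)
        stop("zero Cat activity: external H2O2 does not decay in the HIGH ",
             "regime", call. = FALSE)
      log(2) * (rates$kenz_prime + params$kdiff) /
        (rates$kenz_prime * rates$kdiff_prime)
    },
    stop("half_life_external is defined for LOW or HIGH regimes",
         call. = FALSE))
}

#' Detoxification speed-up from Cat induction
#'
#' A `fold`-times induction of Cat multiplies the slow HIGH-regime eigenvalue
#' by `fold * (kenz' + kdiff) / (fold * kenz' + kdiff)`: because membrane
#' diffusion rate-limits entry, a 10-fold induction only speeds medium
#' detoxification ~1.7-fold.
#'
#' @param params a [kinetic_params()].
#' @param fold Cat induction factor (> 0).
#' @return dimensionless speed-up ratio.
#' @export
induction_speedup <- function(params, fold) {
  if (fold <= 0) stop("fold must be positive", call. = FALSE)
  kenz_prime <- params$vmax_cat / params$km_cat
  fold * (kenz_prime + params$kdiff) / (fold * kenz_prime + params$kdiff)
}

#' Contribution of each elimination route to the internal peak
#'
#' In the LOW regime the three parallel first-order routes Ahp, Cat and
#' membrane export split the elimination as `Vmax_Ahp/KM_Ahp`,
#' `Vmax_Cat/KM_Cat` and `kdiff`, each over `kenz + kdiff`
#' (wild type: ~78% / 12% / 10%). In the HIGH regime Ahp is saturated and
#' only Cat and the membrane remain (~55% / 45%).
#'
#' @param params a [kinetic_params()].
#' @param strain a [strain_config()].
#' @param regime `"LOW"` or `"HIGH"`.
#' @return named numeric vector of fractions summing to 1.
#' @export
contribution_fractions <- function(params, strain = wild_type(),
                                   regime = "LOW") {
  va <- strain$ahp_factor * params$vmax_ahp / params$km_ahp
  vc <- strain$cat_factor * params$vmax_cat / params$km_cat
  switch(regime,
    LOW = c(Ahp = va, Cat = vc, membrane = params$kdiff) /
      (va + vc + params$kdiff),
    HIGH = c(Cat = vc, membrane = params$kdiff) / (vc + params$kdiff),
    stop("contribution_fractions is defined for LOW or HIGH regimes",
         call. = FALSE))
}
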