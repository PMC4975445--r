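#' Lumped first-order rates for one strain at one cell density
#'
#' Collapses the parameter set, strain multipliers and cell density into the
#' effective rate constants that drive both the linearised solutions and the
#' interpretation of full simulations:
#'
#' * `kdiff_prime` — external-pool drainage constant,
#'   `kdiff * n*vin / (vout - n*vin)`, /s;
#' * `kenz` — low-regime lumped scavenging, `vmax_ahp/km_ahp +
#'   vmax_cat/km_cat` (strain-scaled), /s;
#' * `kenz_prime` — high-regime (Ahp-saturated) scavenging, Cat term only, /s;
#' * `kprod` — net endogenous production `k1' + k1/2` (0 when the strain has
#'   no endogenous production), mol/L/s;
#' * `kprod_prime` — high-regime production `kprod - vmax_ahp` (production
#'   net of the saturated Ahp flux), mol/L/s.
#'
#' @param params a [kinetic_params()] object.
#' @param strain a [strain_config()] object.
#' @param population a [population_model()] object (supplies `vout`).
#' @param n cell density, cells/L.
#' @return a list with elements `kdiff_prime`, `kenz`, `kenz_prime`, `kprod`,
#'   `kprod_prime`.
#' @examples
#' derived_rates(kinetic_params(), wild_type(), population_model(), 1.45e10)
#' @export
derived_rates <- function(params, strain = wild_type(),
                          population = population_model(), n) {
  stopifnot(inherits(params, "kinetic_params"),
            inherits(strain, "strain_config"),
            inherits(population, "population_model"))
  if (!is.numeric(n) || length(n) != 1L || n < 0)
    stop("n must be a single non-negative density (cells/L)", call. = FALSE)
  check_cell_volume(n, params$vin, population$vout)
  vmax_ahp <- strain$ahp_factor * params$vmax_ahp
  vmax_cat <- strain$cat_factor * params$vmax_cat
  kprod <- if (strain$endogenous_production) effective_production(params) else 0
  list(
    kdiff_prime = params$kdiff * n * params$vin /
      (population$vout - n * params$vin),
    kenz = vmax_ahp / params$km_ahp + vmax_cat / params$km_cat,
    kenz_prime = vmax_cat / params$km_cat,
    kprod = kprod,
    kprod_prime = kprod - vmax_ahp
  )
}

# Michaelis-Menten scavenging flux at internal concentration c (mol/L/s).
scavenging_flux <- function(c, params, strain) {
  strain$ahp_factor * params$vmax_ahp * c / (c + params$km_ahp) +
    strain$cat_factor * params$vmax_cat * c / (c + params$km_cat)
}
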