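#' Instantaneous state of the coupled system
#'
#' One shared external H2O2 pool plus, per strain, an internal H2O2 pool,
#' a superoxide pool and a cell density. Concentrations are mol/L, densities
#' cells/L, time s.
#'
#' @param h2o2_in per-strain internal H2O2 concentrations, mol/L.
#' @param superoxide per-strain superoxide concentrations, mol/L.
#' @param h2o2_out shared external H2O2 concentration, mol/L.
#' @param densities per-strain cell densities, cells/L.
#' @param t time, s.
#' @return an object of class `system_state`.
#' @export
system_state <- function(h2o2_in, superoxide, h2o2_out, densities, t = 0) {
  m <- length(h2o2_in)
  if (length(superoxide) != m || length(densities) != m)
    stop("h2o2_in, superoxide and densities must have one entry per strain",
         call. = FALSE)
  if (length(h2o2_out) != 1L)
    stop("h2o2_out is a single shared concentration", call. = FALSE)
  vals <- c(h2o2_in, superoxide, h2o2_out, densities)
  if (any(!is.finite(vals)) || any(vals < 0))
    stop("state components must be finite and non-negative", call. = FALSE)
  structure(list(h2o2_in = h2o2_in, superoxide = superoxide,
                 h2o2_out = h2o2_out, densities = densities, t = t),
            class = "system_state")
}

#' Right-hand side of the full nonlinear model
#'
#' The exact Michaelis–Menten system. Per strain i (membrane-bound, with
#' endogenous metabolism):
#' \deqn{d[H2O2]_i/dt = k_1' + (1/2) k_2[SOD][O_2^-]_i
#'   - Vmax_{Ahp} C_i/(C_i + K_M^{Ahp}) - Vmax_{Cat} C_i/(C_i + K_M^{Cat})
#'   - k_{diff} (C_i - C_{out})}
#' \deqn{d[O_2^-]_i/dt = k_1 - k_2[SOD][O_2^-]_i}
#' and the shared medium balances every strain's membrane flux:
#' \deqn{d[H2O2]_{out}/dt = \sum_i k_{diff}
#'   \frac{n_i V_{in}}{V_{out} - \sum_j n_j V_{in}} (C_i - C_{out}).}
#' Cell-extract strains (`has_membrane = FALSE`) have no diffusion term:
#' their enzymes consume the external pool directly, scaled by the lysed-cell
#' volume fraction, and their internal concentration tracks the external one.
#' With `quasi_steady = TRUE` the superoxide equation is replaced by its
#' steady state, adding `k1/2` to H2O2 production (the `k_prod`
#' simplification).
#'
#' Density derivatives follow the logistic law (frozen inside the post-stress
#' lag window; see [grow()]).
#'
#' @param state a [system_state()].
#' @param params a [kinetic_params()].
#' @param strains list of [strain_config()], one per strain.
#' @param population a [population_model()].
#' @param quasi_steady substitute the superoxide steady state.
#' @param stress_clock time since the last stress event, s (`Inf` = never
#'   stressed); freezes growth while below `lag_duration`.
#' @return a list with derivative vectors `h2o2_in`, `superoxide`,
#'   `h2o2_out`, `densities`.
#' @export
ros_rhs <- function(state, params, strains, population,
                    quasi_steady = FALSE, stress_clock = Inf) {
  stopifnot(inherits(state, "system_state"))
  m <- length(state$h2o2_in)
  if (length(strains) != m)
    stop("need one strain_config per internal pool", call. = FALSE)
  n <- state$densities
  check_cell_volume(sum(n), params$vin, population$vout)
  vfree <- population$vout - sum(n) * params$vin

  dCin <- numeric(m); dO2 <- numeric(m); dCout <- 0
  cin <- state$h2o2_in; o2 <- state$superoxide; cout <- state$h2o2_out
  for (i in seq_len(m)) {
    s <- strains[[i]]
    prod <- if (!s$endogenous_production) 0
            else if (quasi_steady) params$k1_prime + params$k1 / 2
            else params$k1_prime + 0.5 * params$k2_sod * o2[i]
    dO2[i] <- if (!s$endogenous_production || quasi_steady) 0
              else params$k1 - params$k2_sod * o2[i]
    frac <- n[i] * params$vin / vfree
    if (s$has_membrane) {
      dCin[i] <- prod - scavenging_flux(cin[i], params, s) -
        params$kdiff * (cin[i] - cout)
      dCout <- dCout + params$kdiff * frac * (cin[i] - cout)
    } else {
      # extract: enzymes dispersed in the medium, internal pool == medium
      dCout <- dCout + frac * (prod - scavenging_flux(cout, params, s))
    }
  }
  for (i in seq_len(m))
    if (!strains[[i]]$has_membrane) dCin[i] <- dCout
  dN <- vapply(seq_len(m), function(i)
    growth_rate(n[i], population, stress_clock), numeric(1))
  list(h2o2_in = dCin, superoxide = dO2, h2o2_out = dCout, densities = dN)
}

# dn/dt under the growth law, honouring the post-stress lag.
growth_rate <- function(n, population, stress_clock = Inf) {
  if (population$growth_mode == "constant") return(0)
  if (stress_clock < population$lag_duration) return(0)
  r <- log(2) / population$tau_d
  r * n * (1 - n / population$n_max)
}
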