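---
title: "Modelling hydrogen peroxide stress in E. coli populations"
author: "peroxidyn"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling hydrogen peroxide stress in E. coli populations}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(peroxidyn)
```

## The model

`peroxidyn` describes hydrogen peroxide (H~2~O~2~) exchange between a
bacterial culture and its medium as a two-compartment kinetic system. Each
cell carries an internal H~2~O~2~ pool $C$ and a superoxide pool $S$; the
shared medium carries the external pool $C_{out}$. Per strain,

$$\frac{dC}{dt} = k_1' + \tfrac12 k_2[\mathrm{SOD}]\,S
  - \frac{V_{max}^{Ahp}\,C}{C + K_M^{Ahp}}
  - \frac{V_{max}^{Cat}\,C}{C + K_M^{Cat}}
  - k_{diff}\,(C - C_{out}),$$

$$\frac{dS}{dt} = k_1 - k_2[\mathrm{SOD}]\,S, \qquad
\frac{dC_{out}}{dt} = \sum_i k_{diff}\,
  \frac{n_i V_{in}}{V_{out} - \sum_j n_j V_{in}}\,(C_i - C_{out}),$$

with cell densities $n_i$ following either a constant or a logistic
(Verhulst) growth law, frozen for a lag (default 40 min) after each
oxidative-stress event. The assumptions inherited from this model family:

* **Well-mixed pools.** H~2~O~2~ diffuses inside a cell on microsecond
  timescales, far faster than any reaction here, so no intracellular spatial
  structure is resolved.
* **Constant enzyme levels within a run.** Ahp and Cat activities are fixed
  multipliers of the wild-type capacities (`strain_config()`); regulatory
  induction (OxyR) is represented only as a static factor (e.g. the 7×
  Cat level of Ahp-null cells), never as a dynamic response.
* **Two scavengers plus the membrane.** Hydroxyl-radical chemistry, Fenton
  reactions and downstream macromolecular damage are outside the model's
  scope; the Haber–Weiss reaction is kinetically negligible below ~0.1 M.
* **Superoxide is fast.** $S$ relaxes with time constant
  $1/k_2[\mathrm{SOD}] \approx 36\ \mu s$; an optional quasi-steady mode
  replaces the SOD term by its limit $k_1/2$ (the `quasi_steady` flag), and
  both modes agree on H~2~O~2~ trajectories to well under 0.5% beyond 1 ms.

## Parameters

All internal units are SI-molar and seconds; cell densities are cells/L.
The boundary (configuration files, `parse_quantity()`) accepts µM, mM,
minutes, cells/mL and converts once, which avoids silent factor-of-10³
errors between the litre- and millilitre-based conventions common in this
literature.

| parameter | default | unit | meaning |
|---|---|---|---|
| `k1` | 5.7e-6 | mol/L/s | superoxide production by metabolism |
| `k2_sod` | 2.8e4 | /s | lumped SOD dismutation constant $k_2[\mathrm{SOD}]$ |
| `k1_prime` | 1.2e-5 | mol/L/s | direct endogenous H~2~O~2~ production |
| `vmax_ahp` | 6.6e-4 | mol/L/s | Ahp capacity $k_{cat}^{Ahp}[\mathrm{Ahp}]$ |
| `km_ahp` | 1.2e-6 | mol/L | Ahp Michaelis constant |
| `vmax_cat` | 4.9e-1 | mol/L/s | Cat capacity $k_{cat}^{Kat}[\mathrm{Cat}]$ |
| `km_cat` | 5.9e-3 | mol/L | Cat Michaelis constant |
| `kdiff` | 70 | /s | membrane diffusion constant $P\,A/V_{in}$ |
| `vin` | 3.2e-15 | L | single-cell volume |

These defaults are the published constants for exponentially growing
*E. coli*; `kinetic_params()` cross-checks `kdiff` against $P\,A/V_{in}$
(70.5 /s from $P = 1.6\times10^{-3}$ cm/s, $A = 1.41\times10^{-7}$ cm²)
within 1% when permeability and area are supplied.

Derived constants do most of the analytic work: the net production
$k_{prod} = k_1' + k_1/2 = 1.485\times10^{-5}$ mol/L/s, the lumped linear
scavenging $k_{enz} = V_{max}^{Ahp}/K_M^{Ahp} + V_{max}^{Cat}/K_M^{Cat}
= 633$ /s, its Ahp-saturated counterpart $k_{enz}' = 83$ /s, and the
density-dependent drainage constant
$k_{diff}' = k_{diff}\, n V_{in}/(V_{out} - n V_{in})$.

## Concentration regimes and closed forms

The Michaelis–Menten terms linearise at the two ends of the stress range:

* **LOW** (external < 10 µM): both enzymes linear, effective pair
  $(k_{prod},\ k_{enz})$.
* **HIGH** (external > 30 µM): Ahp saturated, pair
  $(k_{prod} - V_{max}^{Ahp},\ k_{enz}')$.
* **INTERMEDIATE** (10–30 µM): no closed form exists; the analytic module
  *refuses* rather than interpolates, and callers fall back to the
  simulator. Inventing behaviour between the regimes would produce numbers
  with no model behind them.

In a linear regime the internal/external pair is a 2×2 linear ODE whose
trajectory is bi-exponential (`solve_linear()`). The eigenvalues are always
computed from the exact quadratic — the textbook approximations
$\lambda_1 \approx -k_{enz} k_{diff}'/(k_{enz}+k_{diff})$ and
$\lambda_2 \approx -(k_{enz}+k_{diff})$ are exposed separately in
`lambda_approx()` for comparison and hold to 1% whenever
$k_{diff}' \le k_{enz}/100$, which covers every realistic density here.
The slow root is evaluated as $\lambda_1 = -P/|\lambda_2|$ (Vieta) rather
than $(-S+\sqrt{S^2-4P})/2$: at $S \approx 700$ /s and $P \approx 2$ /s²
the subtractive form loses ~5 significant digits to cancellation.

From the solution follow the quantities a bench scientist quotes: the
steady state $k_{prod}/k_{enz} \approx 23.5$ nM, the early plateau
$k_{prod}/(k_{enz}+k_{diff}) \approx 21$ nM, the peak time
$t_{max} = \ln(\lambda_1/\lambda_2)/(\lambda_2-\lambda_1) \approx 18$ ms,
peak height $k_{diff} C_{out,0}/(k_{diff}+k_{enz})$ (one tenth of the
added amount in LOW, about half in HIGH), external half-lives
$\ln 2/k_{diff}'$ (LOW) and
$\ln2\,(k_{enz}'+k_{diff})/(k_{enz}' k_{diff}')$ (HIGH), the elimination
splits (78/12/10% Ahp/Cat/membrane in LOW; ~54/46% Cat/membrane in HIGH)
and the saturation of Cat induction against the membrane bottleneck
($10\times$ induction speeds medium detox only $1.7\times$).

The full Michaelis–Menten steady state is found by bracketed root finding
(`uniroot`, relative tolerance $10^{-13}$) starting from the linear value as
a guaranteed lower bound, since saturation can only raise the balance point:
23.9 nM wild type, 179 nM Ahp-null, 27.6 nM Cat-null.

## The simulator

`simulate_scenario()` integrates the exact system with `deSolve::ode`
(`lsoda`), relative tolerance $10^{-8}$ and absolute tolerance $10^{-15}$
mol/L by default. Choices worth knowing:

* **Events by stop-and-restart.** A stress addition is a genuine
  discontinuity in $C_{out}$; restarting the integrator at the jump
  preserves error control instead of forcing a stiff source term through it.
  Each event also restarts the growth-lag clock.
* **Log-spaced output.** Each inter-event segment is sampled on 400
  log-spaced points from $10^{-5}$ s, so the millisecond peak and the
  minute-scale decay are both resolved; `peak()` refines the grid maximum
  with a parabola through the three bracketing samples (falling back to the
  grid point when the fit degenerates or the vertex leaves the bracket).
* **Densities in closed form.** Growth follows the logistic flow evaluated
  analytically inside the right-hand side (segments are split at lag ends so
  each is wholly frozen or growing), keeping the stiff solver's Jacobian
  free of slow population states.
* **Cell extracts.** `has_membrane = FALSE` models lysed cells: the
  strain's enzymes act directly on the medium, scaled by the lysed-cell
  volume fraction, and the strain's "internal" series is defined equal to
  the external one. The packaged extract scenario also sets
  `endogenous_production = FALSE`, since the producing metabolism is
  destroyed with the cell.
* **Multi-strain coupling.** Every strain keeps its own internal pool; the
  external equation sums the per-strain membrane fluxes weighted by each
  strain's volume fraction, which reduces exactly to the single-strain
  equation for one strain — this is what lets the mixed Cat⁻/Cat⁺ rescue
  experiment run as one shared-medium simulation.
* **Output hygiene.** Concentrations are clipped to zero on output only if
  within $10\times$ the absolute tolerance of zero; anything more negative
  is an error, not data.

Tolerance halving changes reported peaks by well under 0.1%, and the
diffusion-only system conserves total H~2~O~2~ along full trajectories to
$10^{-6}$ relative — both are enforced in the test suite.

## Scenario registry and what it emulates

`get_scenario()` packages the canonical experiments: unstressed approach to
steady state at three densities, the 1.5 µM micromolar-stress pair at
OD 0.1, the 1 mM millimolar stress, the whole-cell versus cell-extract
comparison, and the six mixed-culture detoxification runs (dilute/dense ×
Cat⁻/Cat⁺/1:1 mixture, 1 mM). Registry choices that were genuinely open:

* The OD↔density conversion is OD 0.1 = 1.45×10⁷ cells/mL. One published
  density (2×10⁸ cells/mL for the same 1.5 µM experiment) is inconsistent
  with that conversion; both variants are registered (`fig9`, `fig9_od1`)
  rather than silently choosing.
* The extract comparison needs an exogenous concentration the sources do
  not state; the registry uses 10 µM, a representative value well below
  $K_M^{Cat}$, and the associated test asserts only the robust ordering
  (extracts detoxify faster than intact cells at equal enzyme content).
* Dilute mixed-culture runs use 10² cells/mL (the figure-caption value; a
  5×10² variant is numerically indistinguishable at 1 mM).
* Stress runs default to constant density, appropriate for ≤10-min
  horizons; logistic growth with the 40-min lag is exercised separately.

These scenarios emulate *in silico* experiments, not raw data: real
cultures induce defences over tens of minutes, deplete substrates, and die —
none of which is modelled. A passing suite therefore shows that the
implementation reproduces this kinetic model's behaviour, not that the model
captures every feature of a real H~2~O~2~ challenge.

## Dose metrics

`cumulative_dose()` integrates internal H~2~O~2~ over time (trapezoid;
exact for the piecewise-linear series it is applied to) in mol/L·s, with a
µM·min convenience scale. The internal half-life is measured from the peak
downward, the external one from its initial value. The decomposition-rate
curves solve the quasi-steady internal concentration from the flux balance
at fixed external concentration and locate the Ahp/Cat crossover
(~15 µM at basal enzyme levels, against the ~17 µM usually quoted; with
strongly induced Cat no crossover exists in the micromolar range and the
finder returns its "not found" signal). Because the induction state of the
single-enzyme mutants behind the classic crossover figure is not stated,
the finder takes the Cat level as an explicit argument.

The central scientific contrast the metrics expose: the *peak* internal
concentration is density-invariant (<2% over four decades of density)
because it is set by the per-cell balance of influx and elimination, while
the *cumulative* dose falls strictly with density because denser
populations clear the shared medium sooner. In the dense 1:1 mixture the
Cat⁻ cells reach the same peak as when alone but accumulate markedly less
dose — the kinetic signature of cross-protection through the medium.

## Known limitations

* Near stress peaks the exact system runs a little hotter than the
  regime-linearised formulas: at 1 mM the simulated peak is ~0.47 mM
  versus 0.457 mM linearised (Cat is ~7% sub-linear at that
  concentration), and at 1.5 µM the trajectory deviates from the
  bi-exponential by up to ~11% near the peak, where internal H~2~O~2~
  reaches $K_M^{Ahp}/6$. The agreement tightens below 3% at ten-fold lower
  stress. The test suite pins these deviations as measured properties; the
  optional `corrected` peak formula carries the saturated-Ahp flux but not
  the Cat curvature.
* Enzyme induction is static; trajectories longer than the regulatory
  response (~tens of minutes) overstate stress in wild-type cells.
* No survival model is included: cumulative dose is reported as a
  concentration-time integral and its link to killing is an interpretation,
  not a computed prediction.

## Problem sizes

The shipped tests and the acceptance script run single-strain or two-strain
scenarios over horizons of 100 s to 3×10⁴ s on 400-point output grids —
each a sub-second stiff integration — plus a five-decade density sweep of
the 1 mM stress; the whole suite completes in a few seconds on one core.
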