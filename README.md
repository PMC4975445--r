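# peroxidyn

Kinetic modelling of hydrogen peroxide stress in *Escherichia coli*
populations.

When H₂O₂ hits a bacterial culture, what each cell actually experiences is
set by three competing routes: scavenging by alkyl hydroperoxide reductase
(Ahp, high affinity but low capacity), scavenging by catalase (Cat, low
affinity but high capacity), and passive diffusion across the membrane.
`peroxidyn` implements the standard two-compartment kinetic model of this
system for people who want to ask quantitative questions about it —
microbiologists sizing an exposure experiment, and modellers who need a
tested reference implementation of the coupled internal/external dynamics.

## The model

Per strain *i* sharing one medium ($C$ internal, $S$ superoxide, $C_{out}$
external; mol/L and seconds throughout):

```
dC/dt     = k1' + ½ k2[SOD] S − Vmax_Ahp C/(C+KM_Ahp) − Vmax_Cat C/(C+KM_Cat)
            − kdiff (C − C_out)
dS/dt     = k1 − k2[SOD] S
dC_out/dt = Σ_i kdiff · n_i·Vin/(V_out − Σ_j n_j·Vin) · (C_i − C_out)
```

with constant or logistic cell growth (frozen for a 40-min lag after each
stress). Below ~10 µM external H₂O₂ both enzymes act linearly and the
system has a closed-form bi-exponential solution; above ~30 µM Ahp is
saturated and a second linearisation applies. The package provides

* the exact nonlinear right-hand side and a stiff integrator
  (`simulate_scenario()`, via deSolve/lsoda),
* the closed-form regime solutions: eigenvalues, steady states
  (`k_prod/k_enz` ≈ 23.5 nM for the wild type), plateaus, peak time and
  height, external half-lives, contribution fractions, induction speed-up
  (`solve_linear()`, `steady_state_nonlinear()`, `cmax_analytic()`, …),
* dose metrics: maximal internal concentration, half-lives and the
  cumulative internal dose (`peak()`, `half_life()`, `cumulative_dose()`),
* a registry of classic experiments (`list_scenarios()`), JSON scenario
  configs with explicit units (`load_config()`), TSV trajectory I/O, and a
  CLI (`inst/cli/peroxidyn`).

## Worked example

A wild-type culture at 1.45×10⁷ cells/mL (OD ≈ 0.1) hit with 1 mM H₂O₂:

```r
library(peroxidyn)
p <- kinetic_params()                      # published rate constants

round(steady_state_nonlinear(p) * 1e9, 1)  # unstressed steady state, nM
#> [1] 23.9

round(contribution_fractions(p), 2)        # who removes H2O2 at low stress
#>      Ahp      Cat membrane
#>     0.78     0.12     0.10

traj <- simulate_scenario(get_scenario("fig10"))   # 1 mM step, full model
print(dose_metrics(traj), digits = 3)
#>      strain   cmax_M tmax_s t_half_external_s t_half_internal_s cumulative_dose_M_s
#> 1 wild_type 0.000472 0.0799               399               383                0.25
```

Reading: the cell interior peaks at 0.47 mM — about half the external
concentration, because the membrane plus Cat absorb the rest (Ahp is
saturated and nearly irrelevant up here) — within ~80 ms of the stress.
The medium is then cleared with a ~6.6 min half-life, and the cumulative
internal exposure over the hour is 0.25 M·s (≈ 4200 µM·min). Unlike the
peak, that cumulative dose depends strongly on how many cells share the
medium, which is the model's explanation for density-dependent survival.

The same numbers from the shell:

```sh
inst/cli/peroxidyn metrics --scenario fig10
inst/cli/peroxidyn analytic --config inst/extdata/table1_defaults.json
inst/cli/peroxidyn simulate --scenario ma_eaton_dense_mixed --out traj.tsv
```

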