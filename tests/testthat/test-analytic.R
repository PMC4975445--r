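test_that("stress regime is classified by the external concentration", {
  expect_equal(classify_regime(1.5e-6), "LOW")
  expect_equal(classify_regime(1e-3), "HIGH")
  expect_equal(classify_regime(20e-6), "INTERMEDIATE")
  expect_error(classify_regime(1e-6, low_threshold = 40e-6), "below")
  expect_error(solve_linear(tab1, wild_type(), per_ml(1e7), 20e-6),
               "INTERMEDIATE")
})

test_that("bi-exponential solution honours its initial values and Vieta", {
  set.seed(7)
  for (rep in 1:20) {
    p <- kinetic_params(k1 = 5.7e-6 * runif(1, 0.2, 5),
                        k1_prime = 12e-6 * runif(1, 0.2, 5),
                        vmax_ahp = 6.6e-4 * runif(1, 0.2, 5),
                        vmax_cat = 4.9e-1 * runif(1, 0.2, 5),
                        kdiff = 70 * runif(1, 0.2, 5))
    n <- per_ml(10^runif(1, 5, 8.5))
    ext0 <- runif(1, 0, 9e-6)
    sol <- solve_linear(p, wild_type(), n, ext0, regime = "LOW")
    r <- derived_rates(p, wild_type(), pop1L, n)
    expect_lt(rel_dev(sol$lambda_slow * sol$lambda_fast,
                      sol$kenz_eff * r$kdiff_prime), 1e-10)
    expect_lt(rel_dev(sol$lambda_slow + sol$lambda_fast,
                      -(sol$kenz_eff + p$kdiff + r$kdiff_prime)), 1e-10)
    expect_lt(abs(sol$internal(0) - sol$init_in) /
                max(sol$init_in, 1e-12), 1e-12)
    expect_lt(abs(sol$external(0) - ext0) / max(ext0, 1e-12), 1e-12)
  }
})

test_that("exact eigenvalues agree with the two-timescale approximations", {
  # fast mode: -(kenz + kdiff) = -703/s, good to 0.5% at OD 0.1 densities
  sol <- solve_linear(tab1, wild_type(), per_ml(1.45e7), 1.5e-6)
  expect_lt(rel_dev(sol$lambda_fast, -703), 0.005)
  # slow mode approximation holds to 1% whenever kdiff' <= kenz/100
  set.seed(11)
  for (rep in 1:10) {
    n <- per_ml(10^runif(1, 5, 9))
    r <- derived_rates(tab1, wild_type(), pop1L, n)
    if (r$kdiff_prime > 1e-2 * r$kenz) next
    sol <- solve_linear(tab1, wild_type(), n, 1.5e-6)
    ap <- lambda_approx(tab1, wild_type(), n)
    expect_lt(rel_dev(sol$lambda_slow, ap$lambda_slow), 0.01)
    expect_lt(rel_dev(sol$lambda_fast, ap$lambda_fast), 0.01)
  }
})

test_that("bi-exponential matches a numerical solution of the linear system", {
  n <- per_ml(1.45e7)
  r <- derived_rates(tab1, wild_type(), pop1L, n)
  sol <- solve_linear(tab1, wild_type(), n, 1.5e-6)
  lin_rhs <- function(t, y, parms)
    list(c(r$kprod - (r$kenz + tab1$kdiff) * y[1] + tab1$kdiff * y[2],
           r$kdiff_prime * (y[1] - y[2])))
  tt <- c(0, 10^seq(-5, log10(600), length.out = 50))
  num <- deSolve::ode(c(sol$init_in, 1.5e-6), tt, lin_rhs, NULL,
                      method = "lsoda", rtol = 1e-12, atol = 1e-20)
  expect_lt(max(rel_dev(sol$internal(tt), num[, 2])), 1e-6)
  expect_lt(max(rel_dev(sol$external(tt), num[, 3])), 1e-6)
})

test_that("linear steady states and plateau match the closed forms", {
  expect_equal(round_nM1(steady_state_linear(tab1)), 23.5)
  expect_equal(round_nM(steady_state_linear(tab1, ahp_null())), 179)
  expect_equal(round_nM(plateau_concentration(tab1)), 21)
  expect_equal(round_nM(plateau_concentration(tab1, ahp_null())), 97)
  # doubling both capacities halves the steady state
  p2 <- kinetic_params(vmax_ahp = 2 * 6.6e-4, vmax_cat = 2 * 4.9e-1)
  expect_equal(steady_state_linear(p2), steady_state_linear(tab1) / 2)
  # without a membrane term the plateau reduces to the steady state
  p0 <- kinetic_params(kdiff = 1e-12)
  expect_equal(plateau_concentration(p0), steady_state_linear(p0),
               tolerance = 1e-9)
})

test_that("unstressed solution relaxes to the linear steady state", {
  sol <- solve_linear(tab1, wild_type(), per_ml(1e7), external0 = 0,
                      init_in = 0)
  expect_lt(rel_dev(sol$internal(1e6), steady_state_linear(tab1)), 1e-6)
})

test_that("Michaelis-Menten steady state is solved by root bracketing", {
  expect_equal(round_nM1(steady_state_nonlinear(tab1)), 23.9)
  expect_equal(round_nM(steady_state_nonlinear(tab1, cat_null())), 28)
  # closed form for a single saturable enzyme
  kprod <- effective_production(tab1)
  expect_lt(rel_dev(steady_state_nonlinear(tab1, cat_null()),
                    kprod * tab1$km_ahp / (6.6e-4 - kprod)), 1e-10)
  # Km -> infinity at fixed Vmax/Km reduces to the linear balance
  phuge <- kinetic_params(vmax_ahp = 6.6e-4 * 1e6, km_ahp = 1.2e-6 * 1e6,
                          vmax_cat = 4.9e-1 * 1e6, km_cat = 5.9e-3 * 1e6)
  expect_lt(rel_dev(steady_state_nonlinear(phuge),
                    steady_state_linear(phuge)), 1e-6)
  # production beyond total capacity has no steady state
  weak <- strain_config(ahp_factor = 1e-3, cat_factor = 1e-6)
  expect_error(steady_state_nonlinear(tab1, weak), "no steady state")
})

test_that("analytic peak time is ~18 ms and shrinks with density", {
  t7 <- tmax_analytic(solve_linear(tab1, wild_type(), per_ml(1e7), 1.5e-6))
  expect_equal(round(t7 * 1e3), 18)
  t9 <- tmax_analytic(solve_linear(tab1, wild_type(), per_ml(1e9), 1.5e-6))
  expect_lt(rel_dev(t9, 11e-3), 0.10)
  ns <- per_ml(10^seq(6, 9, length.out = 10))
  tm <- vapply(ns, function(n)
    tmax_analytic(solve_linear(tab1, wild_type(), n, 1.5e-6)), numeric(1))
  expect_true(all(diff(tm) < 0))
})

test_that("peak height formulas per regime", {
  # LOW: the membrane keeps the peak near a tenth of the added amount
  expect_equal(round(cmax_ratio(tab1, wild_type(), 1.5e-6), 2), 0.10)
  # HIGH at 1 mM: ~0.457 mM plain, ~0.453 with the saturated-Ahp correction
  expect_equal(round(cmax_analytic(tab1, wild_type(), 1e-3) * 1e3, 2), 0.46)
  expect_lt(rel_dev(cmax_analytic(tab1, wild_type(), 1e-3), 0.457e-3), 0.005)
  expect_lt(rel_dev(cmax_analytic(tab1, wild_type(), 1e-3, corrected = TRUE),
                    0.453e-3), 0.005)
  # a Cat-null strain has no HIGH-regime scavenging: peak = added amount
  expect_equal(cmax_ratio(tab1, cat_null(), 1e-3), 1)
})

test_that("external half-lives per regime and their density scaling", {
  expect_equal(signif(half_life_external(tab1, n = per_ml(1.45e7)), 2), 210)
  expect_equal(signif(half_life_external(tab1, n = per_ml(1.45e8)), 2), 21)
  th <- half_life_external(tab1, n = per_ml(1.45e7), regime = "HIGH")
  expect_equal(round(th / 60 * 2) / 2, 6.5)
  # ~1/n in the dilute limit: doubling n halves t1/2 to 0.1%
  t1 <- half_life_external(tab1, n = per_ml(1e7))
  t2 <- half_life_external(tab1, n = per_ml(2e7))
  expect_lt(abs(t1 / t2 - 2), 2e-3)
  expect_error(half_life_external(tab1, cat_null(), per_ml(1e7), "HIGH"),
               "zero Cat")
})

test_that("Cat induction speed-up saturates against the membrane", {
  expect_equal(round(induction_speedup(tab1, 10), 1), 1.7)
  expect_equal(induction_speedup(tab1, 1), 1)
  kenz_prime <- tab1$vmax_cat / tab1$km_cat
  expect_lt(rel_dev(induction_speedup(tab1, 1e12),
                    (kenz_prime + 70) / kenz_prime), 1e-6)
})

test_that("elimination-route fractions split as 78/12/10 and ~55/45", {
  lo <- contribution_fractions(tab1)
  expect_equal(unname(round(lo, 2)), c(0.78, 0.12, 0.10))
  hi <- contribution_fractions(tab1, regime = "HIGH")
  expect_lt(abs(hi[["Cat"]] - 0.55), 0.01)
  expect_lt(abs(hi[["membrane"]] - 0.45), 0.01)
  set.seed(3)
  for (rep in 1:5) {
    s <- strain_config(ahp_factor = runif(1, 0, 3), cat_factor = runif(1, 0, 3))
    expect_lt(abs(sum(contribution_fractions(tab1, s)) - 1), 1e-12)
    expect_lt(abs(sum(contribution_fractions(tab1, s, "HIGH")) - 1), 1e-12)
  }
})
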