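#' Scenario registry of classic experiments
#'
#' Named, ready-to-run scenarios for the canonical experiments the model
#' reproduces (all at Table-1-style default constants, 1 L of medium):
#'
#' * `fig1`, `fig2`, `fig3` — unstressed wild type at 1e7, 1e6 and 1e9
#'   cells/mL starting from zero H2O2: fast ~21 nM plateau then slow rise to
#'   the ~24 nM steady state.
#' * `fig6_whole`, `fig6_extract` — breakdown of 10 µM exogenous H2O2 by
#'   whole Ahp-null cells (7x induced Cat) versus the matching cell extract
#'   (no membrane, no endogenous production), 4e6 cells/mL.
#' * `fig7`, `fig8` — 1.5 µM step on the wild type at 1.45e7 cells/mL
#'   (OD ~0.1): micromolar-regime internal peak and 3.5 min external
#'   half-life.
#' * `fig9`, `fig9_od1` — the same 1.5 µM step at 2e8 cells/mL (figure
#'   caption density) and 1.45e8 cells/mL (the "OD 1" reading of the text);
#'   both are registered because the two sources disagree.
#' * `fig10` — 1 mM step on the wild type at 1.45e7 cells/mL: Ahp-saturated
#'   regime, internal peak ~0.45 mM.
#' * `ma_eaton_{dilute,dense}_{catminus,catplus,mixed}` — the mixed-culture
#'   detox experiment: 1 mM H2O2 with Cat-null cells, wild-type cells, or a
#'   1:1 mixture, at 1e2 (dilute) or 1e7 (dense) cells/mL.
#' * `table2_wildtype`, `table2_ahp_null`, `table2_cat_null` — unstressed
#'   steady-state runs for the three genotypes.
#'
#' @param name a registered scenario name.
#' @return `get_scenario()`: a [scenario()]; `list_scenarios()`: character
#'   vector of registered names.
#' @examples
#' list_scenarios()
#' get_scenario("fig7")
#' @export
get_scenario <- function(name) {
  reg <- scenario_registry()
  if (!name %in% names(reg))
    stop("unknown scenario '", name, "'; see list_scenarios()", call. = FALSE)
  reg[[name]]()
}

#' @rdname get_scenario
#' @export
list_scenarios <- function() names(scenario_registry())

per_ml <- function(x) x * 1e3  # cells/mL -> cells/L

scenario_registry <- function() {
  p <- kinetic_params()
  pop <- population_model(vout = 1)
  step1mM <- data.frame(time = 0, amount = 1e-3)
  nostress_wt <- function(label, n_per_ml, t_end)
    scenario(p, list(wild_type()), per_ml(n_per_ml), pop,
             t_end = t_end, init_internal = "zero", label = label)
  ma <- function(label, strains, dens)
    scenario(p, strains, per_ml(dens), pop, stress_events = step1mM,
             t_end = 1800, label = label)
  list(
    fig1 = function() nostress_wt("fig1", 1e7, 1e4),
    fig2 = function() nostress_wt("fig2", 1e6, 3e4),
    fig3 = function() nostress_wt("fig3", 1e9, 100),
    fig6_whole = function()
      scenario(p, list(ahp_null(cat_induction = 7, label = "whole_cells")),
               per_ml(4e6), pop,
               stress_events = data.frame(time = 0, amount = 10e-6),
               t_end = 7200, label = "fig6_whole"),
    fig6_extract = function()
      scenario(p, list(strain_config("extract", ahp_factor = 0,
                                     cat_factor = 7, has_membrane = FALSE,
                                     endogenous_production = FALSE)),
               per_ml(4e6), pop,
               stress_events = data.frame(time = 0, amount = 10e-6),
               t_end = 7200, init_internal = "zero", label = "fig6_extract"),
    fig7 = function()
      scenario(p, list(wild_type()), per_ml(1.45e7), pop,
               stress_events = data.frame(time = 0, amount = 1.5e-6),
               t_end = 1200, label = "fig7"),
    fig8 = function()
      scenario(p, list(wild_type()), per_ml(1.45e7), pop,
               stress_events = data.frame(time = 0, amount = 1.5e-6),
               t_end = 1200, label = "fig8"),
    fig9 = function()
      scenario(p, list(wild_type()), per_ml(2e8), pop,
               stress_events = data.frame(time = 0, amount = 1.5e-6),
               t_end = 300, label = "fig9"),
    fig9_od1 = function()
      scenario(p, list(wild_type()), per_ml(1.45e8), pop,
               stress_events = data.frame(time = 0, amount = 1.5e-6),
               t_end = 300, label = "fig9_od1"),
    fig10 = function()
      scenario(p, list(wild_type()), per_ml(1.45e7), pop,
               stress_events = step1mM, t_end = 3600, label = "fig10"),
    ma_eaton_dilute_catminus = function()
      ma("ma_eaton_dilute_catminus", list(cat_null("cat_minus")), 1e2),
    ma_eaton_dilute_catplus = function()
      ma("ma_eaton_dilute_catplus", list(wild_type("cat_plus")), 1e2),
    ma_eaton_dilute_mixed = function()
      ma("ma_eaton_dilute_mixed",
         list(cat_null("cat_minus"), wild_type("cat_plus")), c(1e2, 1e2)),
    ma_eaton_dense_catminus = function()
      ma("ma_eaton_dense_catminus", list(cat_null("cat_minus")), 1e7),
    ma_eaton_dense_catplus = function()
      ma("ma_eaton_dense_catplus", list(wild_type("cat_plus")), 1e7),
    ma_eaton_dense_mixed = function()
      ma("ma_eaton_dense_mixed",
         list(cat_null("cat_minus"), wild_type("cat_plus")), c(1e7, 1e7)),
    table2_wildtype = function()
      scenario(p, list(wild_type()), per_ml(1e7), pop, t_end = 1e4,
               init_internal = "zero", label = "table2_wildtype"),
    table2_ahp_null = function()
      scenario(p, list(ahp_null()), per_ml(1e7), pop, t_end = 1e4,
               init_internal = "zero", label = "table2_ahp_null"),
    table2_cat_null = function()
      scenario(p, list(cat_null()), per_ml(1e7), pop, t_end = 1e4,
               init_internal = "zero", label = "table2_cat_null")
  )
}

#' Run the mixed-culture medium-detoxification suite
#'
#' Simulates the six classic scenarios — dilute (1e2 cells/mL) and dense
#' (1e7 cells/mL) populations of Cat-null cells alone, wild-type (Cat+)
#' cells alone, and a 1:1 mixture — after a 1.0 mM exogenous H2O2 step.
#' Dilute populations cannot detoxify the medium regardless of genotype;
#' a dense Cat+ population halves the medium concentration within ~10 min,
#' and in the dense mixture the Cat+ partner rescues the Cat-null cells by
#' clearing the shared medium (lowering their cumulative internal dose, not
#' their peak).
#'
#' @param ... passed to [simulate_scenario()] (tolerances etc.).
#' @return named list of `ros_trajectory` objects.
#' @export
run_ma_eaton <- function(...) {
  nms <- grep("^ma_eaton_", list_scenarios(), value = TRUE)
  out <- lapply(nms, function(nm) simulate_scenario(get_scenario(nm), ...))
  names(out) <- nms
  out
}
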