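#' End-to-end pipeline: generate, classify, simulate, report
#'
#' Convenience driver chaining the whole analysis on a synthetic cohort:
#' [generate_cohort()] -> [classify_cohort()] -> [sim_states()] ->
#' [run_monte_carlo()] -> [summarize_prevalence()] / [stage_report()].
#' Every input patient is accounted for: the returned `accounting` vector
#' (included + no_valid_ldl + no_risk_category) sums to `spec$n_patients`,
#' and within the included patients the intolerant subgroup splits into
#' simulated + excluded-for-baseline-drug.
#'
#' @param spec A [cohort_spec()].
#' @param sim_config A [simulation_config()].
#' @param config,catalog,rules,risk_rules Passed to [classify_cohort()]
#'   (defaults as there); `config` defaults to `spec$selection`.
#' @return List with `cohort`, `labels`, `classified`, `states`,
#'   `simulation`, `prevalence`, `stages`, `accounting`.
#' @export
run_pipeline <- function(spec,
                         sim_config = simulation_config(),
                         config = spec$selection,
                         catalog = default_statin_catalog(),
                         rules = default_si_rules(),
                         risk_rules = default_risk_rules()) {
  gen <- generate_cohort(spec)
  classified <- classify_cohort(gen$cohort, config, catalog, rules,
                                risk_rules)
  states <- sim_states(classified)
  simulation <- if (nrow(states)) run_monte_carlo(states, sim_config)
  else NULL
  attrition <- attr(classified, "attrition")
  accounting <- c(attrition,
                  si_patients = attr(states, "n_si_cohort"),
                  si_simulated = nrow(states),
                  si_excluded_baseline_drug =
                    attr(states, "n_si_cohort") - nrow(states))
  list(cohort = gen$cohort, labels = gen$labels, classified = classified,
       states = states, simulation = simulation,
       prevalence = summarize_prevalence(classified),
       stages = if (!is.null(simulation)) stage_report(simulation),
       accounting = accounting)
}
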