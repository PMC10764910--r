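# Monte Carlo simulation of stepwise oral lipid-lowering-therapy
# escalation: ezetimibe first, then bempedoic acid stratified by baseline
# statin intensity.  Fractional LDL-C reductions are drawn from beta
# distributions fitted by the method of moments; results are aggregated
# across runs by the median (median-of-means LDL-C, median counts at
# target).

#' Fit beta shape parameters from a mean and standard deviation
#'
#' Method of moments on the `[0, 1]` fraction scale:
#' `nu = mean (1 - mean) / sd^2 - 1`, `alpha = mean nu`,
#' `beta = (1 - mean) nu`.  Feasibility requires
#' `sd^2 < mean (1 - mean)`.
#'
#' @param mean_fraction Mean fractional reduction, in (0, 1).
#' @param sd_fraction Standard deviation of the fraction, > 0.
#' @return Named numeric vector `c(alpha =, beta =)`.
#' @export
#' @examples
#' fit_beta_params(0.229, 0.148)
fit_beta_params <- function(mean_fraction, sd_fraction) {
  stopifnot(length(mean_fraction) == 1L, length(sd_fraction) == 1L)
  if (mean_fraction <= 0 || mean_fraction >= 1)
    stop("fit_beta_params: mean_fraction must lie in (0, 1)", call. = FALSE)
  bound <- mean_fraction * (1 - mean_fraction)
  if (sd_fraction <= 0 || sd_fraction^2 >= bound)
    stop("fit_beta_params: need 0 < sd_fraction^2 < mean*(1-mean) = ",
         signif(bound, 6), call. = FALSE)
  nu <- bound / sd_fraction^2 - 1
  c(alpha = mean_fraction * nu, beta = (1 - mean_fraction) * nu)
}

#' Beta effect model for one drug and statin stratum
#'
#' @param drug `"ezetimibe"` or `"bempedoic_acid"`.
#' @param stratum `"any"` (ezetimibe) or `"statin_moderate_or_high"` /
#'   `"statin_low_or_none"` (bempedoic acid).
#' @param mean_fraction,sd_fraction Target mean and SD of the fractional
#'   LDL-C reduction.  `sd_fraction = 0` selects the degenerate mode in
#'   which every draw equals `mean_fraction` (used for hand-checkable
#'   oracles).
#' @return List of class `effect_model` with the fitted `alpha`, `beta`
#'   (NA in degenerate mode).
#' @export
effect_model <- function(drug, stratum, mean_fraction, sd_fraction) {
  stopifnot(drug %in% c("ezetimibe", "bempedoic_acid"),
            stratum %in% c("any", "statin_moderate_or_high",
                           "statin_low_or_none"),
            mean_fraction > 0, mean_fraction < 1, sd_fraction >= 0)
  if (sd_fraction == 0) {
    ab <- c(alpha = NA_real_, beta = NA_real_)
  } else {
    ab <- fit_beta_params(mean_fraction, sd_fraction)
  }
  structure(list(drug = drug, stratum = stratum,
                 mean_fraction = mean_fraction, sd_fraction = sd_fraction,
                 alpha = unname(ab["alpha"]), beta = unname(ab["beta"])),
            class = "effect_model")
}

#' Default effect models
#'
#' Published fractional LDL-C reductions: ezetimibe mean 22.9% (SD 14.8%);
#' bempedoic acid on moderate- or high-intensity statin mean 16.7%
#' (SD 20.9%), on low-intensity or no statin mean 24.1% (SD 22.3%).
#'
#' @param degenerate If `TRUE`, zero-variance variants of the same means
#'   (for deterministic oracles).
#' @return Named list of three [effect_model()]s: `ezetimibe`,
#'   `ba_moderate_or_high`, `ba_low_or_none`.
#' @export
default_effect_models <- function(degenerate = FALSE) {
  s <- if (degenerate) c(0, 0, 0) else c(0.148, 0.209, 0.223)
  list(
    ezetimibe = effect_model("ezetimibe", "any", 0.229, s[1]),
    ba_moderate_or_high = effect_model("bempedoic_acid",
                                       "statin_moderate_or_high",
                                       0.167, s[2]),
    ba_low_or_none = effect_model("bempedoic_acid", "statin_low_or_none",
                                  0.241, s[3])
  )
}

#' Draw fractional reductions from an effect model
#'
#' @param model An [effect_model()].
#' @param n Number of draws.
#' @return `n` values in `[0, 1]`; all equal to the model mean in
#'   degenerate mode.
#' @export
sample_effects <- function(model, n) {
  stopifnot(inherits(model, "effect_model"), n >= 0)
  if (n == 0) return(numeric(0))
  if (model$sd_fraction == 0) return(rep(model$mean_fraction, n))
  stats::rbeta(n, model$alpha, model$beta)
}

#' Apply a fractional LDL-C reduction
#'
#' @param ldl_mg_dl Positive LDL-C value(s).
#' @param fraction Fractional reduction(s) in `[0, 1]`.
#' @return `ldl_mg_dl * (1 - fraction)`.
#' @export
#' @examples
#' apply_effect(100, 0.20)
apply_effect <- function(ldl_mg_dl, fraction) {
  if (any(fraction < 0 | fraction > 1))
    stop("apply_effect: fraction must lie in [0, 1]", call. = FALSE)
  if (any(ldl_mg_dl <= 0))
    stop("apply_effect: LDL-C must be positive", call. = FALSE)
  ldl_mg_dl * (1 - fraction)
}

#' Baseline simulation states from a classified cohort
#'
#' Restricts a classified cohort to the statin-intolerant patients,
#' excludes those already on bempedoic acid or a PCSK9 inhibitor at
#' baseline, and orders patients by `patient_id` (the order in which
#' random draws are consumed, making results independent of input row
#' order).
#'
#' @param classified An `si_cohort` from [classify_cohort()], or any data
#'   frame with the same columns.
#' @param si_only Keep only patients classified absolute/partial
#'   (default `TRUE`).
#' @return Data frame of class `sim_states` with attribute `n_si_cohort`
#'   (SI-cohort size before the baseline-drug exclusion).
#' @export
sim_states <- function(classified, si_only = TRUE) {
  df <- as.data.frame(classified)
  if (si_only) df <- df[df$si_category %in% c("absolute", "partial"), ,
                        drop = FALSE]
  n_si <- nrow(df)
  df <- df[!df$on_bempedoic_or_pcsk9, , drop = FALSE]
  df <- df[order(df$patient_id), , drop = FALSE]
  out <- data.frame(patient_id = df$patient_id,
                    baseline_ldl = df$ldl_mg_dl,
                    risk_category = df$risk_category,
                    ldl_target = df$ldl_target,
                    on_ezetimibe_baseline = df$on_ezetimibe,
                    baseline_statin_stratum = df$baseline_statin_stratum,
                    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  attr(out, "n_si_cohort") <- n_si
  class(out) <- c("sim_states", "data.frame")
  out
}

#' One simulation run of the escalation algorithm
#'
#' Stage 0: patients already below their risk-based target receive no
#' further treatment.  Stage 1: patients not at target and not on
#' ezetimibe at baseline receive one sampled ezetimibe effect; patients
#' already on ezetimibe pass through unchanged (their measured LDL-C
#' already reflects ezetimibe).  Stage 2: patients still not at target
#' receive one sampled bempedoic-acid effect from the model matching their
#' baseline statin stratum.  Effects multiply the current LDL-C.
#'
#' @param states A [sim_states()] frame (baseline-excluded patients
#'   already removed).
#' @param models Effect-model list as from [default_effect_models()].
#' @return List with `ldl` (matrix, patients x stages baseline /
#'   post_ezetimibe / post_bempedoic), `at_target` (logical matrix) and
#'   `counts` (patients at target per stage).
#' @export
simulate_run <- function(states, models = default_effect_models()) {
  need <- c("ezetimibe", "ba_moderate_or_high", "ba_low_or_none")
  if (!all(need %in% names(models)))
    stop("simulate_run: models must provide ",
         paste(need, collapse = ", "), call. = FALSE)
  n <- nrow(states)
  target <- states$ldl_target
  ldl0 <- states$baseline_ldl
  at0 <- ldl0 < target

  ldl1 <- ldl0
  need_eze <- !at0 & !states$on_ezetimibe_baseline
  ldl1[need_eze] <- ldl0[need_eze] *
    (1 - sample_effects(models$ezetimibe, sum(need_eze)))
  at1 <- ldl1 < target

  ldl2 <- ldl1
  need_ba <- !at1
  if (any(need_ba)) {
    mod_hi <- states$baseline_statin_stratum == "moderate_or_high"
    frac <- numeric(n)
    pick_hi <- need_ba & mod_hi
    pick_lo <- need_ba & !mod_hi
    frac[pick_hi] <- sample_effects(models$ba_moderate_or_high, sum(pick_hi))
    frac[pick_lo] <- sample_effects(models$ba_low_or_none, sum(pick_lo))
    ldl2[need_ba] <- ldl1[need_ba] * (1 - frac[need_ba])
  }
  at2 <- ldl2 < target

  ldl <- cbind(baseline = ldl0, post_ezetimibe = ldl1, post_bempedoic = ldl2)
  at <- cbind(baseline = at0, post_ezetimibe = at1, post_bempedoic = at2)
  list(ldl = ldl, at_target = at, counts = colSums(at))
}

#' Monte Carlo simulation configuration
#'
#' @param n_runs Number of independent runs (default 10000).
#' @param master_seed Integer master seed; each run gets its own substream
#'   seed derived from it, so identical master seeds give bit-identical
#'   results.
#' @param effect_models Effect-model list, see [default_effect_models()].
#' @return List of class `simulation_config`.
#' @export
simulation_config <- function(n_runs = 10000L, master_seed = 1L,
                              effect_models = default_effect_models()) {
  stopifnot(n_runs >= 1, is.finite(master_seed))
  need <- c("ezetimibe", "ba_moderate_or_high", "ba_low_or_none")
  if (!all(need %in% names(effect_models)))
    stop("simulation_config: effect_models must provide ",
         paste(need, collapse = ", "), call. = FALSE)
  structure(list(n_runs = as.integer(n_runs),
                 master_seed = as.integer(master_seed),
                 effect_models = effect_models),
            class = "simulation_config")
}

#' Run the full Monte Carlo simulation
#'
#' Executes `n_runs` independent [simulate_run()]s, each under its own
#' substream seed drawn (without replacement) from the master seed, and
#' aggregates across runs by the median: per stage, the median of within-
#' run mean LDL-C (median-of-means), the median of within-run median
#' LDL-C, and the median count of patients at target.  Attainment
#' proportions are the median counts divided by the SI-cohort size (the
#' denominator includes patients excluded for baseline bempedoic-acid /
#' PCSK9-inhibitor use); `prop_of_entering` divides by the simulated
#' population instead.
#'
#' @param states A [sim_states()] frame.
#' @param config A [simulation_config()].
#' @return Object of class `simulation_result`: list with `n_si_cohort`,
#'   `n_entering`, `n_runs`, `master_seed`, `stages` (data frame with
#'   per-stage `median_count_at_target`, `attainment`, `prop_of_entering`,
#'   `mean_ldl` (median-of-means), `median_ldl`,
#'   `relative_reduction_percent`) and `by_risk` (the same median counts
#'   and within-stratum attainment split by risk category).
#' @export
run_monte_carlo <- function(states, config = simulation_config()) {
  stopifnot(inherits(config, "simulation_config"))
  if (!nrow(states))
    stop("run_monte_carlo: empty cohort", call. = FALSE)
  n_runs <- config$n_runs
  run_seeds <- with_seed(config$master_seed,
                         sample.int(.Machine$integer.max - 1L, n_runs))
  means <- matrix(NA_real_, n_runs, 3)
  medians <- matrix(NA_real_, n_runs, 3)
  counts <- matrix(NA_real_, n_runs, 3)
  is_vh <- states$risk_category == "very_high"
  counts_vh <- matrix(NA_real_, n_runs, 3)
  for (r in seq_len(n_runs)) {
    res <- with_seed(run_seeds[r], simulate_run(states, config$effect_models))
    means[r, ] <- colMeans(res$ldl)
    medians[r, ] <- apply(res$ldl, 2, stats::median)
    counts[r, ] <- res$counts
    counts_vh[r, ] <- colSums(res$at_target[is_vh, , drop = FALSE])
  }
  stage_names <- c("baseline", "post_ezetimibe", "post_bempedoic")
  med_count <- apply(counts, 2, stats::median)
  med_mean <- apply(means, 2, stats::median)
  med_median <- apply(medians, 2, stats::median)
  n_si <- attr(states, "n_si_cohort") %||% nrow(states)
  stages <- data.frame(
    stage = stage_names,
    median_count_at_target = med_count,
    attainment = med_count / n_si,
    prop_of_entering = med_count / nrow(states),
    mean_ldl = med_mean,
    median_ldl = med_median,
    relative_reduction_percent = round_half_up(
      100 * (med_median[1] - med_median) / med_median[1], 1),
    row.names = NULL)
  med_vh <- apply(counts_vh, 2, stats::median)
  med_hi <- apply(counts - counts_vh, 2, stats::median)
  by_risk <- data.frame(
    stage = rep(stage_names, 2),
    risk_category = rep(c("very_high", "high"), each = 3),
    n = rep(c(sum(is_vh), sum(!is_vh)), each = 3),
    median_count_at_target = c(med_vh, med_hi),
    attainment = c(if (sum(is_vh)) med_vh / sum(is_vh) else rep(NA, 3),
                   if (sum(!is_vh)) med_hi / sum(!is_vh) else rep(NA, 3)),
    row.names = NULL)
  structure(list(n_si_cohort = n_si, n_entering = nrow(states),
                 n_runs = n_runs, master_seed = config$master_seed,
                 stages = stages, by_risk = by_risk,
                 per_run = list(means = means, medians = medians,
                                counts = counts)),
            class = "simulation_result")
}

#' @export
print.simulation_result <- function(x, ...) {
  cat("Monte Carlo LLT escalation: ", x$n_entering, " patients entering (of ",
      x$n_si_cohort, " SI), ", x$n_runs, " runs, master seed ",
      x$master_seed, "\n", sep = "")
  s <- x$stages
  for (i in seq_len(nrow(s))) {
    cat(sprintf("  %-15s at target %6.1f (%5.1f%%)  median LDL %6.1f  mean LDL %6.1f  rel. red. %5.1f%%\n",
                s$stage[i], s$median_count_at_target[i],
                100 * s$attainment[i], s$median_ldl[i], s$mean_ldl[i],
                s$relative_reduction_percent[i]))
  }
  invisible(x)
}

#' Write the per-stage simulation summary and provenance log
#'
#' @param result A `simulation_result`.
#' @param path CSV path for the stage summary.
#' @param log_path Optional YAML path for the machine-readable run log
#'   (seed, run count, effect-model parameters).
#' @return `path`, invisibly.
#' @export
write_simulation_result <- function(result, path, log_path = NULL) {
  utils::write.csv(result$stages, path, row.names = FALSE, quote = FALSE)
  if (!is.null(log_path)) {
    yaml::write_yaml(list(n_runs = result$n_runs,
                          master_seed = result$master_seed,
                          n_si_cohort = result$n_si_cohort,
                          n_entering = result$n_entering),
                     log_path)
  }
  invisible(path)
}
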