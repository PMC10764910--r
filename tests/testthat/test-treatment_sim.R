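# Monte Carlo escalation engine: beta fitting, effect sampling, staging,
# aggregation and reproducibility.

# minimal classified-cohort rows for driving the simulator directly
mini_cohort <- function(ldl, risk, on_eze = FALSE, on_ba = FALSE,
                        stratum = "low_or_none") {
  n <- length(ldl)
  data.frame(patient_id = sprintf("P%02d", seq_len(n)),
             ldl_mg_dl = ldl,
             risk_category = rep_len(risk, n),
             ldl_target = ldl_target(rep_len(risk, n)),
             si_category = "partial",
             on_ezetimibe = rep_len(on_eze, n),
             on_bempedoic_or_pcsk9 = rep_len(on_ba, n),
             baseline_statin_stratum = rep_len(stratum, n),
             stringsAsFactors = FALSE)
}

test_that("method-of-moments beta fit reproduces its inputs", {
  for (ms in list(c(0.229, 0.148), c(0.167, 0.209), c(0.241, 0.223),
                  c(0.5, 0.1))) {
    ab <- fit_beta_params(ms[1], ms[2])
    expect_true(all(ab > 0))
    a <- ab[["alpha"]]; b <- ab[["beta"]]
    expect_equal(a / (a + b), ms[1], tolerance = 1e-12)
    expect_equal(sqrt(a * b / ((a + b)^2 * (a + b + 1))), ms[2],
                 tolerance = 1e-9)
  }
  # the published ezetimibe moments give the known shape pair
  ab <- fit_beta_params(0.229, 0.148)
  expect_equal(unname(ab), c(1.61687, 5.44371), tolerance = 1e-4)
  # mean 1/2 with variance 1/12 is the uniform distribution
  expect_equal(unname(fit_beta_params(0.5, sqrt(1 / 12))), c(1, 1),
               tolerance = 1e-12)
  expect_error(fit_beta_params(0.5, 0.5), "sd_fraction")
  expect_error(fit_beta_params(1.2, 0.1), "mean_fraction")
})

test_that("effect draws live on [0,1] and match the configured moments", {
  models <- default_effect_models()
  set.seed(909)
  for (m in models) {
    x <- sample_effects(m, 1e5)
    expect_gte(min(x), 0); expect_lte(max(x), 1)
    se_mean <- m$sd_fraction / sqrt(1e5)
    expect_lt(abs(mean(x) - m$mean_fraction), 4 * se_mean)
    expect_lt(abs(sd(x) - m$sd_fraction), 4 * m$sd_fraction / sqrt(2e5))
  }
  deg <- default_effect_models(degenerate = TRUE)
  expect_equal(sample_effects(deg$ezetimibe, 5), rep(0.229, 5))
})

test_that("fractional reductions apply multiplicatively", {
  expect_equal(apply_effect(100, 0.20), 80)
  expect_equal(apply_effect(100, 0.38), 62)
  expect_equal(apply_effect(123.4, 0), 123.4)
  expect_error(apply_effect(100, 1.2), "fraction")
  expect_error(apply_effect(-5, 0.2), "positive")
})

test_that("a degenerate run matches the hand-computed five-patient sheet", {
  cl <- mini_cohort(ldl = c(50, 100, 100, 80, 69),
                    risk = c("very_high", "very_high", "very_high",
                             "high", "high"),
                    on_eze = c(FALSE, FALSE, TRUE, FALSE, FALSE),
                    stratum = c("low_or_none", "low_or_none", "low_or_none",
                                "moderate_or_high", "low_or_none"))
  st <- sim_states(cl)
  deg <- default_effect_models(degenerate = TRUE)
  run <- simulate_run(st, deg)
  # hand arithmetic: 100 * 0.771 = 77.1; 77.1 * 0.759 = 58.5189;
  # 100 (on ezetimibe) * 0.759 = 75.9; 80 * 0.771 = 61.68 (< 70, stops)
  expect_equal(unname(run$ldl[, "post_ezetimibe"]),
               c(50, 77.1, 100, 61.68, 69))
  expect_equal(unname(run$ldl[, "post_bempedoic"]),
               c(50, 58.5189, 75.9, 61.68, 69))
  expect_equal(unname(run$counts), c(2, 3, 3))
  expect_false(run$at_target[2, "post_bempedoic"])  # 58.5189 >= 55

  # with zero-variance effects the Monte Carlo equals the single run
  mc <- run_monte_carlo(st, simulation_config(n_runs = 50, master_seed = 3,
                                              effect_models = deg))
  expect_equal(mc$stages$median_count_at_target, c(2, 3, 3))
  expect_equal(mc$stages$mean_ldl,
               c(mean(c(50, 100, 100, 80, 69)),
                 mean(c(50, 77.1, 100, 61.68, 69)),
                 mean(c(50, 58.5189, 75.9, 61.68, 69))))
  expect_equal(mc$stages$median_ldl, c(80, 69, 61.68))

  # one-patient cohort: median-of-means equals that patient's stage value
  one <- sim_states(mini_cohort(100, "very_high"))
  mc1 <- run_monte_carlo(one, simulation_config(n_runs = 11, master_seed = 5,
                                                effect_models = deg))
  expect_equal(mc1$stages$mean_ldl, c(100, 77.1, 58.5189))
})

test_that("patients at target receive no simulated treatment", {
  cl <- mini_cohort(c(40, 50), "very_high")
  st <- sim_states(cl)
  run <- simulate_run(st, default_effect_models())
  expect_equal(unname(run$ldl[, "post_bempedoic"]), c(40, 50))
  expect_equal(unname(run$counts), c(2, 2, 2))
})

test_that("baseline bempedoic-acid / PCSK9 users are excluded up front", {
  cl <- mini_cohort(c(90, 95, 100), "very_high",
                    on_ba = c(FALSE, TRUE, FALSE))
  st <- sim_states(cl)
  expect_equal(nrow(st), 2L)
  expect_equal(attr(st, "n_si_cohort"), 3L)
  expect_false("P02" %in% st$patient_id)
})

test_that("identical master seeds are bit-identical; different seeds close", {
  cl <- mini_cohort(ldl = seq(60, 150, length.out = 40),
                    risk = rep(c("very_high", "high"), 20))
  st <- sim_states(cl)
  a <- run_monte_carlo(st, simulation_config(n_runs = 300, master_seed = 11))
  b <- run_monte_carlo(st, simulation_config(n_runs = 300, master_seed = 11))
  expect_identical(a, b)
  # input row order must not matter: draws go in patient_id order
  shuffled <- sim_states(cl[sample(nrow(cl)), ])
  c2 <- run_monte_carlo(shuffled, simulation_config(n_runs = 300,
                                                    master_seed = 11))
  expect_identical(a$stages, c2$stages)
})

test_that("attainment is monotone and LDL non-increasing in every run", {
  cl <- mini_cohort(ldl = exp(rnorm(30, log(100), 0.3)),
                    risk = rep(c("very_high", "high"), 15),
                    stratum = rep(c("moderate_or_high", "low_or_none"), 15))
  st <- sim_states(cl)
  set.seed(1010)
  for (i in 1:20) {
    run <- simulate_run(st, default_effect_models())
    expect_true(all(diff(run$counts) >= 0))
    expect_true(all(run$ldl[, 2] <= run$ldl[, 1] + 1e-12))
    expect_true(all(run$ldl[, 3] <= run$ldl[, 2] + 1e-12))
  }
  mc <- run_monte_carlo(st, simulation_config(n_runs = 200, master_seed = 7))
  expect_true(all(diff(mc$stages$attainment) >= 0))
  # median-of-means lies between the per-run extremes
  for (s in 1:3) {
    expect_gte(mc$stages$mean_ldl[s], min(mc$per_run$means[, s]))
    expect_lte(mc$stages$mean_ldl[s], max(mc$per_run$means[, s]))
  }
})

test_that("missing stratum models are a configuration error", {
  st <- sim_states(mini_cohort(100, "high"))
  expect_error(simulate_run(st, list(ezetimibe = default_effect_models()$ezetimibe)),
               "models must provide")
  expect_error(run_monte_carlo(st[0, ], simulation_config(n_runs = 2)),
               "empty cohort")
})
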