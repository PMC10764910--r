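# Signal detection and rule evaluation for statin-intolerance phenotyping.

idx <- as.Date("2021-05-01")
cfg <- selection_config()

signals_for <- function(rx, dx = no_dx) {
  tl <- build_llt_timeline(rx, idx, cfg)
  detect_signals(tl, dx, cfg)
}

test_that("switch with down-titration to a low regimen fires all three switch signals", {
  rx <- rbind(quarterly_rx(idx, -660, -390, molecule = "atorvastatin",
                           dose = 40),
              quarterly_rx(idx, -300, -30, molecule = "pravastatin",
                           dose = 20))
  expect_signals(signals_for(rx),
                 c("statin_switch", "down_titration_different_molecule",
                   "specific_switch_to_low", "low_dose_latest_statin"))
})

test_that("same-molecule dose reduction fires only the same-molecule variant", {
  rx <- rbind(quarterly_rx(idx, -660, -390, dose = 40),
              quarterly_rx(idx, -300, -30, dose = 10))
  expect_signals(signals_for(rx),
                 c("down_titration_same_molecule", "low_dose_latest_statin"))
})

test_that("intermittent dosing needs two mid-range supply gaps", {
  # gaps of 100 and 120 days between episodes, then continuous to index
  rx <- make_rx(idx - c(780, 590, 380, 290, 200, 110, 20), supply = 90L)
  sig <- signals_for(rx)
  expect_true(sig[["intermittent_dosing"]])
  expect_false(sig[["long_term_discontinued"]])

  # a single qualifying gap is not enough
  rx1 <- make_rx(idx - c(500, 310, 220, 130, 40), supply = 90L)
  expect_false(signals_for(rx1)[["intermittent_dosing"]])
  # two gaps of 60 days are refill noise, not intermittent dosing
  rx2 <- make_rx(idx - c(620, 470, 320, 230, 140, 50), supply = 90L)
  expect_false(signals_for(rx2)[["intermittent_dosing"]])
})

test_that("diagnosis-borne signals respect the look-back window", {
  rx <- quarterly_rx(idx, -660, -30)
  dx <- make_dx(idx - c(100, 200), c("documented_si_note", "sams"))
  sig <- signals_for(rx, dx)
  expect_true(sig[["documented_si_note"]])
  expect_true(sig[["sams_event"]])
  old <- make_dx(idx - 1200, "documented_si_note")  # outside 3-year window
  expect_false(signals_for(rx, old)[["documented_si_note"]])
})

test_that("prose definitions drive the category split", {
  # documented note + permanent discontinuation, now on ezetimibe only
  rx_abs <- rbind(make_rx(idx - c(690, 600, 510, 420)),
                  quarterly_rx(idx, -400, -40, class = "ezetimibe",
                               molecule = "ezetimibe", dose = 10))
  dx <- make_dx(idx - 250, "documented_si_note")
  tl <- build_llt_timeline(rx_abs, idx, cfg)
  cls <- classify_si(detect_signals(tl, dx, cfg), tl)
  expect_equal(cls$category, "absolute")
  expect_true("abs_documented_note" %in% cls$fired_rules)
  expect_equal(cls$stratum, "only_nonstatin_llt")

  # specific switch with continuous use: partial
  rx_par <- rbind(quarterly_rx(idx, -660, -390, molecule = "atorvastatin",
                               dose = 40),
                  quarterly_rx(idx, -300, -30, molecule = "rosuvastatin",
                               dose = 5))
  tl2 <- build_llt_timeline(rx_par, idx, cfg)
  cls2 <- classify_si(detect_signals(tl2, no_dx, cfg), tl2)
  expect_equal(cls2$category, "partial")
  expect_true("par_specific_switch" %in% cls2$fired_rules)
  expect_equal(cls2$stratum, "low_dose_latest")

  # stable moderate monotherapy: none, and no rules fired
  rx_none <- quarterly_rx(idx, -660, -30)
  tl3 <- build_llt_timeline(rx_none, idx, cfg)
  cls3 <- classify_si(detect_signals(tl3, no_dx, cfg), tl3)
  expect_equal(cls3$category, "none")
  expect_length(cls3$fired_rules, 0)
  expect_equal(cls3$stratum, "other")
})

test_that("absolute dominates when both rule families fire", {
  sig <- stats::setNames(rep(FALSE, length(statinsim:::SI_SIGNAL_NAMES)),
                         statinsim:::SI_SIGNAL_NAMES)
  sig[c("permanently_discontinued", "long_term_discontinued",
        "statin_free_at_index", "documented_si_note",
        "down_titration_different_molecule")] <- TRUE
  tl <- build_llt_timeline(no_rx, idx, cfg)
  cls <- classify_si(sig, tl)
  expect_equal(cls$category, "absolute")
})

test_that("statin-naive patients without events are none", {
  tl <- build_llt_timeline(no_rx, idx, cfg)
  cls <- classify_si(detect_signals(tl, no_dx, cfg), tl)
  expect_equal(cls$category, "none")
})

test_that("adding a documented note never demotes a category", {
  rank <- c(none = 0, partial = 1, absolute = 2)
  set.seed(404)
  for (i in 1:25) {
    rx <- random_rx(sample(2:20, 1), idx)
    tl <- build_llt_timeline(rx, idx, cfg)
    base <- classify_si(detect_signals(tl, no_dx, cfg), tl)
    noted <- classify_si(detect_signals(
      tl, make_dx(idx - 100, "documented_si_note"), cfg), tl)
    expect_gte(rank[[noted$category]], rank[[base$category]])
  }
})

test_that("every signal set maps to exactly one category and fired rules match", {
  set.seed(505)
  for (i in 1:25) {
    rx <- random_rx(sample(1:25, 1), idx)
    dx <- if (runif(1) < 0.3) make_dx(idx - 150, "sams") else no_dx
    tl <- build_llt_timeline(rx, idx, cfg)
    cls <- classify_si(detect_signals(tl, dx, cfg), tl)
    expect_true(cls$category %in% c("absolute", "partial", "none"))
    expect_identical(cls$category != "none", length(cls$fired_rules) > 0)
  }
})

test_that("rule configuration round-trips through the config file", {
  path <- withr::local_tempfile(fileext = ".yaml")
  write_config(list(selection = cfg, catalog = default_statin_catalog(),
                    si_rules = default_si_rules()), path)
  re <- read_config(path)
  expect_s3_class(re$si_rules, "si_rules")
  expect_equal(re$selection$discontinuation_gap_days, 180L)
  set.seed(606)
  for (i in 1:10) {
    rx <- random_rx(sample(2:20, 1), idx)
    tl <- build_llt_timeline(rx, idx, re$selection, re$catalog)
    sig <- detect_signals(tl, no_dx, re$selection)
    expect_identical(classify_si(sig, tl, re$si_rules),
                     classify_si(sig, tl, default_si_rules()))
  }
})

test_that("rules referencing unknown signals are rejected", {
  expect_error(si_rules(list(list(id = "bad", category = "absolute",
                                  expr = "permanently_discontinued & frobnicated"))),
               "unknown signal")
  expect_error(si_rules(list(list(id = "bad", category = "maybe",
                                  expr = "sams_event"))),
               "absolute/partial")
})
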