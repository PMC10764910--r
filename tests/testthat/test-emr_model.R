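# Domain model: cohort I/O, statin catalog, timeline construction,
# index-date selection, outlier trimming.

idx <- as.Date("2021-05-01")

test_that("cohort loading preserves counts, validates rows, round-trips", {
  dir <- withr::local_tempdir()
  patients <- data.frame(patient_id = c("P1", "P2", "P3"),
                         sex = c("female", "male", "female"),
                         age_years = c(70.1, 65.0, 59.9))
  rx <- rbind(make_rx(idx - c(300, 200, 100), patient = "P1"),
              make_rx(idx - c(250, 150), molecule = "atorvastatin",
                      dose = 20, patient = "P2"),
              make_rx(idx - c(90, 30), class = "ezetimibe",
                      molecule = "ezetimibe", dose = 10, patient = "P3"))
  labs <- make_labs(idx - 10, 95.5, patient = "P1")
  dx <- make_dx(idx - 400, "diabetes", patient = "P2")
  co <- emr_cohort(patients, rx, labs, dx)
  paths <- write_cohort(co, dir)
  re <- load_cohort(paths["patients"], paths["prescriptions"],
                    paths["labs"], paths["diagnoses"])
  expect_equal(nrow(re$patients), 3L)
  expect_equal(nrow(re$prescriptions), 7L)
  for (tbl in c("patients", "prescriptions", "labs", "diagnoses")) {
    a <- co[[tbl]]; b <- re[[tbl]]
    rownames(a) <- rownames(b) <- NULL
    expect_equal(a, b, label = tbl)
  }

  # header-only files give an empty cohort
  for (f in list.files(dir, full.names = TRUE))
    writeLines(readLines(f)[1], f)
  empty <- load_cohort(paths["patients"], paths["prescriptions"],
                       paths["labs"], paths["diagnoses"])
  expect_equal(nrow(empty$patients), 0L)
  expect_equal(nrow(empty$prescriptions), 0L)

  expect_error(load_cohort(file.path(dir, "missing.csv"),
                           paths["prescriptions"], paths["labs"],
                           paths["diagnoses"]),
               "no such file")
})

test_that("malformed rows are rejected with the offending row named", {
  patients <- data.frame(patient_id = "P1", sex = "male", age_years = 60)
  bad_rx <- make_rx(idx - 100)
  bad_rx$dose_mg <- -10
  expect_error(emr_cohort(patients, bad_rx, make_labs(idx, 100), no_dx),
               "row 1.*dose_mg")
  bad_rx2 <- make_rx(idx - 100)
  bad_rx2$date <- "not-a-date"
  expect_error(emr_cohort(patients, bad_rx2, make_labs(idx, 100), no_dx),
               "row 1.*date")
  bad_lab <- make_labs(idx, -5)
  expect_error(emr_cohort(patients, no_rx, bad_lab, no_dx),
               "row 1.*value_mg_dl")
  orphan <- make_dx(idx, "diabetes", patient = "P9")
  expect_error(emr_cohort(patients, no_rx, make_labs(idx, 100), orphan),
               "P9.*not in patients")
})

test_that("statin catalog lookups match the intensity table", {
  expect_equal(classify_statin_regimen("rosuvastatin", 5)[c("intensity", "is_low_dose")],
               list(intensity = "low", is_low_dose = TRUE))
  expect_equal(classify_statin_regimen("atorvastatin", 80)[c("intensity", "is_low_dose")],
               list(intensity = "high", is_low_dose = FALSE))
  expect_equal(classify_statin_regimen("simvastatin", 40)$intensity, "moderate")
  expect_equal(classify_statin_regimen("pravastatin", 40)$intensity, "low")
  expect_error(classify_statin_regimen("unobtanium", 10), "unknown statin")
  expect_error(statin_catalog(data.frame(molecule = "x", dose_min = c(0, 5),
                                         dose_max = c(10, 20),
                                         intensity = "low")),
               "overlapping")
})

test_that("continuous monthly use yields one episode and no flags", {
  rx <- make_rx(idx - seq(330, 0, by = -30), supply = 30L)
  tl <- build_llt_timeline(rx, idx)
  expect_equal(nrow(tl$episodes), 1L)
  expect_equal(nrow(tl$gaps), 0L)
  expect_false(tl$long_term_discontinued)
  expect_false(tl$permanently_discontinued)
  expect_false(tl$statin_free_at_index)
  expect_equal(tl$latest_statin$molecule, "simvastatin")
})

test_that("a 200-day terminal supply gap is permanent discontinuation", {
  # last supply ends 200 days before index, no statin afterwards
  rx <- make_rx(idx - c(470, 380, 290), supply = 90L)
  tl <- build_llt_timeline(rx, idx)
  expect_true(tl$long_term_discontinued)
  expect_true(tl$permanently_discontinued)
  expect_true(tl$statin_free_at_index)
  expect_equal(tl$gaps$length_days, 200L)
  expect_true(tl$gaps$terminal)

  # exactly 180 days is NOT discontinuation (strict inequality)
  rx2 <- make_rx(idx - c(450, 360, 270), supply = 90L)
  tl2 <- build_llt_timeline(rx2, idx)
  expect_false(tl2$long_term_discontinued)
  expect_false(tl2$permanently_discontinued)
  expect_true(tl2$statin_free_at_index)
})

test_that("same-day duplicate statins resolve to the higher intensity", {
  rx <- rbind(make_rx(idx - 60, molecule = "simvastatin", dose = 10),
              make_rx(idx - 60, molecule = "atorvastatin", dose = 80))
  tl <- build_llt_timeline(rx, idx)
  expect_equal(nrow(tl$episodes), 1L)
  expect_equal(tl$latest_statin$molecule, "atorvastatin")
  expect_equal(tl$latest_statin$intensity, "high")
})

test_that("restarting after a long gap is long-term but not permanent", {
  rx <- make_rx(idx - c(700, 400, 60), supply = 90L)  # 210-day mid gap
  tl <- build_llt_timeline(rx, idx)
  expect_true(tl$long_term_discontinued)
  expect_false(tl$permanently_discontinued)
  expect_false(tl$statin_free_at_index)
})

test_that("gap flags agree with a day-by-day coverage oracle", {
  cfg <- selection_config()
  set.seed(101)
  for (i in 1:40) {
    rx <- random_rx(sample(1:50, 1), idx)
    tl <- build_llt_timeline(rx, idx, cfg)
    oracle <- coverage_oracle(rx, idx, cfg$si_lookback_days,
                              cfg$discontinuation_gap_days)
    expect_identical(tl$long_term_discontinued, oracle$long_term,
                     label = paste("long_term case", i))
    expect_identical(tl$permanently_discontinued, oracle$permanent,
                     label = paste("permanent case", i))
    expect_identical(tl$statin_free_at_index, oracle$statin_free,
                     label = paste("statin_free case", i))
    expect_true(all(tl$gaps$length_days > 0))
    # permanent implies the weaker flags
    if (tl$permanently_discontinued) {
      expect_true(tl$long_term_discontinued)
      expect_true(tl$statin_free_at_index)
    }
  }
})

test_that("shrinking the discontinuation gap never un-discontinues", {
  set.seed(202)
  for (i in 1:15) {
    rx <- random_rx(sample(2:30, 1), idx)
    wide <- build_llt_timeline(rx, idx, selection_config(
      discontinuation_gap_days = 180))
    narrow <- build_llt_timeline(rx, idx, selection_config(
      discontinuation_gap_days = 90))
    if (wide$long_term_discontinued)
      expect_true(narrow$long_term_discontinued)
    if (wide$permanently_discontinued)
      expect_true(narrow$permanently_discontinued)
  }
})

test_that("index LDL-C selection takes the last valid measurement", {
  cfg <- selection_config()
  rx <- quarterly_rx(idx, -700, -10)
  labs <- make_labs(as.Date(c("2021-03-01", "2021-05-01")), c(98, 91))
  sel <- select_index_ldl(labs, rx, cfg)
  expect_equal(sel$date, as.Date("2021-05-01"))
  expect_equal(sel$value_mg_dl, 91)

  # drawn 10 days after a fresh statin start: not attributable, absent
  rx_new <- make_rx(as.Date("2021-04-21"))
  labs_new <- make_labs(as.Date("2021-05-01"), 85)
  expect_null(select_index_ldl(labs_new, rx_new, cfg))
  # but 28 days on therapy is enough
  rx_ok <- make_rx(as.Date("2021-04-03"))
  expect_null(select_index_ldl(make_labs(as.Date("2021-04-30"), 85),
                               rx_ok, cfg))
  expect_false(is.null(select_index_ldl(make_labs(as.Date("2021-05-01"), 85),
                                        rx_ok, cfg)))

  # no LLT at all: any measurement in the window is valid
  expect_equal(select_index_ldl(make_labs(idx, 150), no_rx, cfg)$value_mg_dl,
               150)
  # outside the selection window: absent
  expect_null(select_index_ldl(make_labs(as.Date("2020-01-01"), 150),
                               no_rx, cfg))
})

test_that("outlier trimming removes only true distribution tails", {
  x <- sample(1:1000)
  kept <- trim_outliers(x, 0.001)
  expect_equal(sort(setdiff(x, kept)), c(1, 1000))
  expect_equal(length(kept), 998L)

  expect_equal(trim_outliers(rep(7, 50), 0.001), rep(7, 50))
  expect_equal(sort(trim_outliers(c(5, 1, 9), 0.001)), c(1, 5, 9))
  expect_equal(trim_outliers(numeric(0), 0.1), numeric(0))
  n <- 500; f <- 0.01
  expect_gte(length(trim_outliers(rnorm(n), f)), ceiling(n * (1 - 2 * f)) - 2)
  expect_error(trim_outliers(1:10, 0.6))
})

test_that("episodes conserve prescriptions and bound their spans", {
  set.seed(303)
  for (i in 1:15) {
    rx <- random_rx(sample(2:40, 1), idx)
    tl <- build_llt_timeline(rx, idx)
    n_dedup <- length(unique(rx$date))  # same-day duplicates collapse
    expect_equal(sum(tl$episodes$n_rx), n_dedup)
    spans <- as.integer(tl$episodes$end - tl$episodes$start)
    expect_true(all(spans > 0))
    # an episode's span never exceeds its total prescribed supply plus the
    # mergeable gap slack between its prescriptions
    max_supply <- max(rx$supply_days)
    expect_true(all(spans <= tl$episodes$n_rx * (max_supply + 180L)))
  }
})
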