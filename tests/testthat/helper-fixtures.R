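# Shared fixture builders: tiny prescription/lab/diagnosis tables built in
# code, plus a brute-force day-coverage oracle for gap detection.

make_rx <- function(dates, molecule = "simvastatin", dose = 40,
                    class = "statin", supply = 90L, patient = "P1") {
  n <- length(dates)
  data.frame(patient_id = rep_len(patient, n), date = as.Date(dates),
             drug_class = rep_len(class, n),
             molecule = rep_len(molecule, n),
             dose_mg = rep_len(dose, n),
             supply_days = rep_len(as.integer(supply), n),
             stringsAsFactors = FALSE)
}

make_dx <- function(dates, category, patient = "P1") {
  n <- length(dates)
  data.frame(patient_id = rep_len(patient, n), date = as.Date(dates),
             category = rep_len(category, n), stringsAsFactors = FALSE)
}

make_labs <- function(dates, values, patient = "P1") {
  n <- length(dates)
  data.frame(patient_id = rep_len(patient, n), date = as.Date(dates),
             analyte = rep_len("ldl_c", n),
             value_mg_dl = rep_len(values, n),
             stringsAsFactors = FALSE)
}

no_rx <- make_rx(character(0))
no_dx <- make_dx(character(0), character(0))

# quarterly prescriptions from `from_rel` to `to_rel` days relative to index
quarterly_rx <- function(index, from_rel, to_rel, ...) {
  make_rx(index + seq(from_rel, to_rel, by = 90), ...)
}

# Brute-force oracle: day-by-day statin coverage scan over the look-back.
# Returns the same discontinuation flags as the timeline builder should.
coverage_oracle <- function(rx, index_date, lookback = 1095L,
                            gap_days = 180L) {
  rx <- rx[rx$drug_class == "statin", , drop = FALSE]
  rx <- rx[rx$date >= index_date - lookback & rx$date <= index_date, ,
           drop = FALSE]
  if (!nrow(rx))
    return(list(long_term = FALSE, permanent = FALSE, statin_free = TRUE))
  # supply covers the half-open interval [date, date + supply); gaps are
  # runs of uncovered days in [first coverage, index)
  days <- as.integer(index_date - lookback):(as.integer(index_date) - 1L)
  covered <- rep(FALSE, length(days))
  for (i in seq_len(nrow(rx))) {
    d0 <- as.integer(rx$date[i]); d1 <- d0 + rx$supply_days[i] - 1L
    covered[days >= d0 & days <= d1] <- TRUE
  }
  at_index <- any(rx$date <= index_date &
                    index_date < rx$date + rx$supply_days)
  first_cov <- which(covered)[1]
  runs <- rle(covered[first_cov:length(days)])
  uncov <- runs$lengths[!runs$values]
  trailing <- !covered[length(days)] && !at_index
  trailing_len <- if (trailing) runs$lengths[length(runs$lengths)] else 0L
  list(long_term = any(uncov > gap_days),
       permanent = trailing_len > gap_days,
       statin_free = !at_index)
}

# random statin timelines for property tests
random_rx <- function(n_rx, index, rng_molecules = c("simvastatin",
                                                     "atorvastatin")) {
  dates <- index - sort(sample.int(1000, n_rx))
  make_rx(dates,
          molecule = sample(rng_molecules, n_rx, replace = TRUE),
          dose = sample(c(10, 20, 40), n_rx, replace = TRUE),
          supply = sample(c(30L, 60L, 90L), n_rx, replace = TRUE))
}

expect_signals <- function(sig, on) {
  for (nm in names(sig)) {
    expect_identical(unname(sig[[nm]]), nm %in% on,
                     label = paste0("signal ", nm))
  }
}
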