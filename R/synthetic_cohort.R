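# Synthetic EMR cohort generator.
#
# Every statin-intolerant patient is built from the canonical prescription
# template of one classifier rule, with small date jitter that provably
# stays inside the rule's defining bounds, so planted labels are an exact
# oracle for the classifier.  Non-intolerant patients get continuous
# monotherapy / combination / no-therapy histories per the configured
# lipid-lowering-therapy mix.  LDL-C is log-normal per treatment stratum,
# solved from target arithmetic mean and SD.

# --- canonical rule templates ----------------------------------------------
# Relative days are offsets from the index date; jitter of +/- 10 days is
# applied per prescription, with design margins of >= 20 days to every rule
# boundary (60 / 180-day gaps, 28-day stability, 1095-day look-back).

template_registry <- function() {
  rx <- function(rel_day, class, molecule, dose)
    data.frame(rel_day = rel_day, drug_class = class, molecule = molecule,
               dose_mg = dose, stringsAsFactors = FALSE)
  dx <- function(rel_day, category)
    data.frame(rel_day = rel_day, category = category,
               stringsAsFactors = FALSE)
  cont <- seq(-660, -30, by = 90)          # continuous quarterly to index
  blockA <- seq(-660, -390, by = 90)       # first regimen
  blockB <- seq(-300, -30, by = 90)        # second regimen, continuous
  hist4 <- seq(-690, -420, by = 90)        # history ending > 180 d pre-index
  eze_cont <- seq(-400, -40, by = 90)
  no_dx <- dx(integer(0), character(0))

  list(
    # -- absolute: permanent discontinuation + intolerance evidence
    abs_documented_note = list(
      category = "absolute",
      rx = rx(hist4, "statin", "simvastatin", 40)
        |> rbind(rx(eze_cont, "ezetimibe", "ezetimibe", 10)),
      dx = dx(-250, "documented_si_note"), on_llt = TRUE),
    abs_sams = list(
      category = "absolute",
      rx = rx(hist4, "statin", "simvastatin", 40)
        |> rbind(rx(eze_cont, "ezetimibe", "ezetimibe", 10)),
      dx = dx(-250, "sams"), on_llt = TRUE),
    abs_other_event = list(
      category = "absolute",
      rx = rx(hist4, "statin", "simvastatin", 40),
      dx = dx(-250, "other_si_event"), on_llt = FALSE),
    abs_down_titration = list(
      category = "absolute",
      rx = rbind(rx(hist4[1:2], "statin", "simvastatin", 40),
                 rx(hist4[3:4], "statin", "simvastatin", 10)),
      dx = no_dx, on_llt = FALSE),
    abs_switch = list(
      category = "absolute",
      rx = rbind(rx(hist4[1:2], "statin", "simvastatin", 40),
                 rx(hist4[3:4], "statin", "pravastatin", 20)),
      dx = no_dx, on_llt = FALSE),
    abs_intermittent = list(
      category = "absolute",
      rx = rx(c(-780, -590, -380), "statin", "simvastatin", 40),
      dx = no_dx, on_llt = FALSE),
    abs_low_dose_latest = list(
      category = "absolute",
      rx = rx(hist4, "statin", "simvastatin", 10),
      dx = no_dx, on_llt = FALSE),

    # -- partial: continued statin use + tolerability-driven regimen signal
    par_specific_switch = list(
      category = "partial",
      rx = rbind(rx(blockA, "statin", "atorvastatin", 40),
                 rx(blockB, "statin", "rosuvastatin", 5)),
      dx = no_dx, on_llt = TRUE),
    par_down_titration_diff = list(
      category = "partial",
      rx = rbind(rx(blockA, "statin", "atorvastatin", 40),
                 rx(blockB, "statin", "simvastatin", 20)),
      dx = no_dx, on_llt = TRUE),
    par_documented_note = list(
      category = "partial",
      rx = rx(cont, "statin", "simvastatin", 40),
      dx = dx(-200, "documented_si_note"), on_llt = TRUE),
    par_down_same_with_switch = list(
      category = "partial",
      rx = rbind(rx(blockA, "statin", "simvastatin", 40),
                 rx(c(-300, -210), "statin", "simvastatin", 10),
                 rx(c(-120, -30), "statin", "rosuvastatin", 10)),
      dx = no_dx, on_llt = TRUE),
    par_low_dose_plus_nonstatin = list(
      category = "partial",
      rx = rbind(rx(cont, "statin", "simvastatin", 10),
                 rx(cont, "ezetimibe", "ezetimibe", 10)),
      dx = no_dx, on_llt = TRUE),

    # -- no intolerance: stable regimens per the LLT mix
    none_no_llt = list(category = "none",
                       rx = rx(integer(0), character(0), character(0),
                               numeric(0)),
                       dx = no_dx, on_llt = FALSE),
    none_statin_low = list(category = "none",
                           rx = rx(cont, "statin", "simvastatin", 10),
                           dx = no_dx, on_llt = TRUE),
    none_statin_moderate = list(category = "none",
                                rx = rx(cont, "statin", "simvastatin", 40),
                                dx = no_dx, on_llt = TRUE),
    none_statin_high = list(category = "none",
                            rx = rx(cont, "statin", "atorvastatin", 80),
                            dx = no_dx, on_llt = TRUE),
    none_ezetimibe_mono = list(category = "none",
                               rx = rx(cont, "ezetimibe", "ezetimibe", 10),
                               dx = no_dx, on_llt = TRUE),
    none_statin_plus_ezetimibe = list(
      category = "none",
      rx = rbind(rx(cont, "statin", "atorvastatin", 20),
                 rx(cont, "ezetimibe", "ezetimibe", 10)),
      dx = no_dx, on_llt = TRUE),
    none_other_llt = list(category = "none",
                          rx = rx(cont, "other_llt", "fenofibrate", 160),
                          dx = no_dx, on_llt = TRUE)
  )
}

#' Canonical rule template identifiers
#'
#' @param category Optional filter: `"absolute"`, `"partial"` or `"none"`.
#' @return Character vector of template ids; for absolute/partial these are
#'   exactly the classifier rule ids the template exercises.
#' @export
si_rule_templates <- function(category = NULL) {
  reg <- template_registry()
  cats <- vapply(reg, `[[`, character(1), "category")
  if (!is.null(category)) names(reg)[cats %in% category] else names(reg)
}

# --- cohort specification ---------------------------------------------------

#' Specification of a synthetic EMR cohort
#'
#' Defaults reproduce the structure of the study population: 1.8% absolute
#' and 6.8% partial statin intolerance; risk mix 66.1/33.9
#' very-high/high overall and 73.7/26.3 within the intolerant subgroup;
#' LDL-C log-normal per treatment stratum targeting mean 152.1 (SD 43.5)
#' mg/dL without lipid-lowering therapy and 92.1 (SD 31.5) mg/dL on
#' therapy; age mean 69.5 (SD 11.9) years, 45% female; 1.3% of intolerant
#' patients on bempedoic acid or a PCSK9 inhibitor at baseline.
#'
#' @param n_patients Cohort size.
#' @param seed Integer seed; generation is deterministic given the seed.
#' @param fraction_absolute_si,fraction_partial_si Planted intolerance
#'   fractions (sum may equal 1 for an all-intolerant cohort).
#' @param risk_mix,risk_mix_si Named fractions (`very_high`, `high`) for
#'   the overall cohort and within the intolerant subgroup.
#' @param llt_mix Named fractions over the non-intolerant history templates
#'   (`none_no_llt`, `none_statin_low`, `none_statin_moderate`,
#'   `none_statin_high`, `none_ezetimibe_mono`,
#'   `none_statin_plus_ezetimibe`, `none_other_llt`).
#' @param template_weights_absolute,template_weights_partial Named sampling
#'   weights over the rule templates (defaults: equal).
#' @param ldl_no_llt,ldl_on_llt Named `c(mean =, sd =)` arithmetic targets
#'   (mg/dL) per treatment stratum.
#' @param age Named `c(mean =, sd =)` in years.
#' @param fraction_female Fraction of female patients.
#' @param fraction_si_on_ba_pcsk9 Fraction of intolerant patients with
#'   baseline bempedoic acid (excluded from the simulation downstream).
#' @param diagnosis_prevalences Named per-category planting fractions for
#'   the non-risk-defining comorbidities.
#' @param selection A [selection_config()] (provides the selection window).
#' @return Validated list of class `cohort_spec`.
#' @export
cohort_spec <- function(n_patients,
                        seed = 1L,
                        fraction_absolute_si = 0.018,
                        fraction_partial_si = 0.068,
                        risk_mix = c(very_high = 0.661, high = 0.339),
                        risk_mix_si = c(very_high = 0.737, high = 0.263),
                        llt_mix = NULL,
                        template_weights_absolute = NULL,
                        template_weights_partial = NULL,
                        ldl_no_llt = c(mean = 152.1, sd = 43.5),
                        ldl_on_llt = c(mean = 92.1, sd = 31.5),
                        age = c(mean = 69.5, sd = 11.9),
                        fraction_female = 0.45,
                        fraction_si_on_ba_pcsk9 = 0.013,
                        diagnosis_prevalences = c(hypertension = 0.831,
                                                  smoking = 0.516,
                                                  diabetes = 0.501,
                                                  liver_disease = 0.0020,
                                                  gout = 0.0047,
                                                  hyperuricaemia = 0.0012),
                        selection = selection_config()) {
  if (is.null(llt_mix)) {
    # without-intolerance column mix, renormalised to sum exactly to 1
    llt_mix <- c(none_no_llt = 0.199, none_statin_low = 0.076,
                 none_statin_moderate = 0.449, none_statin_high = 0.192,
                 none_ezetimibe_mono = 0.008,
                 none_statin_plus_ezetimibe = 0.075, none_other_llt = 0.002)
    llt_mix <- llt_mix / sum(llt_mix)
  }
  if (is.null(template_weights_absolute)) {
    t_abs <- si_rule_templates("absolute")
    template_weights_absolute <- stats::setNames(rep(1, length(t_abs)), t_abs)
  }
  if (is.null(template_weights_partial)) {
    t_par <- si_rule_templates("partial")
    template_weights_partial <- stats::setNames(rep(1, length(t_par)), t_par)
  }
  spec <- list(n_patients = as.integer(n_patients), seed = as.integer(seed),
               fraction_absolute_si = fraction_absolute_si,
               fraction_partial_si = fraction_partial_si,
               risk_mix = risk_mix, risk_mix_si = risk_mix_si,
               llt_mix = llt_mix,
               template_weights_absolute = template_weights_absolute,
               template_weights_partial = template_weights_partial,
               ldl_no_llt = ldl_no_llt, ldl_on_llt = ldl_on_llt,
               age = age, fraction_female = fraction_female,
               fraction_si_on_ba_pcsk9 = fraction_si_on_ba_pcsk9,
               diagnosis_prevalences = diagnosis_prevalences,
               selection = selection)

  if (spec$n_patients < 1) stop("cohort_spec: n_patients must be >= 1",
                                call. = FALSE)
  fr <- c(spec$fraction_absolute_si, spec$fraction_partial_si,
          spec$fraction_female, spec$fraction_si_on_ba_pcsk9,
          spec$risk_mix, spec$risk_mix_si, spec$llt_mix,
          spec$diagnosis_prevalences)
  if (any(fr < 0 | fr > 1))
    stop("cohort_spec: all fractions must lie in [0, 1]", call. = FALSE)
  if (spec$fraction_absolute_si + spec$fraction_partial_si > 1)
    stop("cohort_spec: intolerance fractions exceed 1", call. = FALSE)
  for (w in list(spec$risk_mix, spec$risk_mix_si, spec$llt_mix))
    if (abs(sum(w) - 1) > 1e-9)
      stop("cohort_spec: mixture weights must sum to 1", call. = FALSE)
  reg <- template_registry()
  bad <- setdiff(c(names(spec$template_weights_absolute),
                   names(spec$template_weights_partial),
                   names(spec$llt_mix)), names(reg))
  if (length(bad))
    stop("cohort_spec: unknown template(s): ", paste(bad, collapse = ", "),
         call. = FALSE)
  structure(spec, class = "cohort_spec")
}

#' Draw LDL-C values for a treatment stratum
#'
#' Log-normal with shape/scale solved from the stratum's target arithmetic
#' mean m and SD s: `sigma^2 = log(1 + s^2/m^2)`,
#' `mu = log(m) - sigma^2/2`, giving exactly the target mean and SD.
#'
#' @param n Number of draws.
#' @param stratum `"no_llt"` or `"on_llt"`.
#' @param spec A [cohort_spec()].
#' @return Positive LDL-C values in mg/dL.
#' @export
sample_ldl <- function(n, stratum, spec) {
  par <- switch(stratum,
                no_llt = spec$ldl_no_llt,
                on_llt = spec$ldl_on_llt,
                stop("sample_ldl: unknown stratum '", stratum, "'",
                     call. = FALSE))
  m <- par[["mean"]]; s <- par[["sd"]]
  sigma2 <- log(1 + (s / m)^2)
  stats::rlnorm(n, meanlog = log(m) - sigma2 / 2, sdlog = sqrt(sigma2))
}

#' Specification of an all-intolerant cohort with the published structure
#'
#' Convenience calibration for studying the escalation simulation on its
#' natural population: every patient is statin-intolerant, split
#' absolute/partial as in the published cross-tab (2336/8950, i.e.
#' 20.7%/79.3%), risk mix 73.7/26.3 very-high/high, baseline LDL-C
#' mean 105.6 (SD 39.8) mg/dL in all strata, and rule-template weights
#' chosen so the latest-regimen mix approximates the intolerant column of
#' the baseline-characteristics table (low-intensity statin dominant,
#' ~13% statin+ezetimibe, ~6% ezetimibe only, ~12% no therapy).
#'
#' @param n_patients Cohort size.
#' @param seed Integer seed.
#' @return A [cohort_spec()].
#' @export
si_cohort_spec <- function(n_patients, seed = 1L) {
  cohort_spec(
    n_patients, seed = seed,
    fraction_absolute_si = 0.207, fraction_partial_si = 0.793,
    ldl_no_llt = c(mean = 105.6, sd = 39.8),
    ldl_on_llt = c(mean = 105.6, sd = 39.8),
    template_weights_partial = c(par_specific_switch = 0.59,
                                 par_down_titration_diff = 0.08,
                                 par_documented_note = 0.09,
                                 par_down_same_with_switch = 0.07,
                                 par_low_dose_plus_nonstatin = 0.17))
}

# --- generation -------------------------------------------------------------

#' Generate a synthetic EMR cohort with planted intolerance labels
#'
#' Deterministic given `spec$seed`.  Category counts follow
#' largest-remainder apportionment of the configured fractions; each
#' intolerant patient's history is the canonical template of one classifier
#' rule (dates jittered within the rule's bounds), each non-intolerant
#' patient a stable history per the therapy mix; risk-defining diagnoses
#' are planted to match the configured risk mixes and every patient gets
#' one valid LDL-C at the index date.
#'
#' @param spec A [cohort_spec()].
#' @return List with `cohort` (an [emr_cohort()]) and `labels` (data frame
#'   `patient_id`, `true_si_category`, `generating_rule`,
#'   `true_risk_category`).
#' @export
generate_cohort <- function(spec) {
  stopifnot(inherits(spec, "cohort_spec"))
  with_seed(spec$seed, generate_cohort_impl(spec))
}

generate_cohort_impl <- function(spec) {
  n <- spec$n_patients
  reg <- template_registry()
  sel <- spec$selection

  ids <- sprintf("P%06d", seq_len(n))
  cat_counts <- largest_remainder(n, c(
    absolute = spec$fraction_absolute_si,
    partial = spec$fraction_partial_si,
    none = 1 - spec$fraction_absolute_si - spec$fraction_partial_si))
  si_cat <- sample(rep(c("absolute", "partial", "none"), cat_counts))

  # template per patient
  pick <- function(weights, m) {
    if (m == 0) return(character(0))
    if (length(weights) == 1) return(rep(names(weights), m))
    sample(names(weights), m, replace = TRUE, prob = weights)
  }
  template <- character(n)
  template[si_cat == "absolute"] <-
    pick(spec$template_weights_absolute, sum(si_cat == "absolute"))
  template[si_cat == "partial"] <-
    pick(spec$template_weights_partial, sum(si_cat == "partial"))
  n_none <- sum(si_cat == "none")
  none_counts <- largest_remainder(n_none, spec$llt_mix)
  template[si_cat == "none"] <- sample(rep(names(none_counts), none_counts))

  # risk mix: within-intolerance mix, remainder chosen so the overall mix
  # hits its largest-remainder target
  n_si <- sum(si_cat != "none")
  si_risk_counts <- largest_remainder(n_si, spec$risk_mix_si)
  all_risk_counts <- largest_remainder(n, spec$risk_mix)
  none_vh <- min(max(all_risk_counts[["very_high"]] -
                       si_risk_counts[["very_high"]], 0L), n_none)
  risk <- character(n)
  risk[si_cat != "none"] <- sample(rep(c("very_high", "high"),
                                       si_risk_counts))
  risk[si_cat == "none"] <- sample(rep(c("very_high", "high"),
                                       c(none_vh, n_none - none_vh)))

  # baseline bempedoic-acid users among the intolerant
  on_ba <- rep(FALSE, n)
  si_idx <- which(si_cat != "none")
  n_ba <- largest_remainder(length(si_idx),
                            c(ba = spec$fraction_si_on_ba_pcsk9,
                              no = 1 - spec$fraction_si_on_ba_pcsk9))[["ba"]]
  if (n_ba > 0) on_ba[sample(si_idx, n_ba)] <- TRUE

  window_len <- as.integer(sel$selection_end - sel$selection_start) + 1L
  index_date <- sel$selection_start +
    sample.int(window_len, n, replace = TRUE) - 1L

  age <- round_half_up(pmin(pmax(stats::rnorm(
    n, spec$age[["mean"]], spec$age[["sd"]]), 30), 99), 1)
  sex <- ifelse(stats::runif(n) < spec$fraction_female, "female", "male")

  on_llt <- vapply(template, function(t) reg[[t]]$on_llt, logical(1)) | on_ba
  ldl <- numeric(n)
  ldl[!on_llt] <- sample_ldl(sum(!on_llt), "no_llt", spec)
  ldl[on_llt] <- sample_ldl(sum(on_llt), "on_llt", spec)
  ldl <- round_half_up(ldl, 1)

  # prescriptions, grouped by template for speed; jitter +/- 10 days per Rx
  rx_parts <- list()
  for (t in sort(unique(template))) {
    sched <- reg[[t]]$rx
    k <- nrow(sched)
    if (!k) next
    members <- which(template == t)
    m <- length(members)
    jit <- sample(-10:10, k * m, replace = TRUE)
    rx_parts[[t]] <- data.frame(
      patient_id = rep(ids[members], each = k),
      date = rep(index_date[members], each = k) + rep(sched$rel_day, m) + jit,
      drug_class = rep(sched$drug_class, m),
      molecule = rep(sched$molecule, m),
      dose_mg = rep(sched$dose_mg, m),
      supply_days = 90L,
      stringsAsFactors = FALSE)
  }
  ba_members <- which(on_ba)
  if (length(ba_members)) {
    sched <- c(-200L, -110L, -20L)
    m <- length(ba_members)
    jit <- sample(-10:10, 3L * m, replace = TRUE)
    rx_parts[["baseline_ba"]] <- data.frame(
      patient_id = rep(ids[ba_members], each = 3L),
      date = rep(index_date[ba_members], each = 3L) + rep(sched, m) + jit,
      drug_class = "bempedoic_acid", molecule = "bempedoic_acid",
      dose_mg = 180, supply_days = 90L, stringsAsFactors = FALSE)
  }
  prescriptions <- if (length(rx_parts)) do.call(rbind, rx_parts)
  else data.frame(patient_id = character(0), date = as.Date(character(0)),
                  drug_class = character(0), molecule = character(0),
                  dose_mg = numeric(0), supply_days = integer(0))

  # diagnoses: template-specific intolerance events
  dx_parts <- list()
  for (t in sort(unique(template))) {
    sched <- reg[[t]]$dx
    k <- nrow(sched)
    if (!k) next
    members <- which(template == t)
    m <- length(members)
    jit <- sample(-10:10, k * m, replace = TRUE)
    dx_parts[[t]] <- data.frame(
      patient_id = rep(ids[members], each = k),
      date = rep(index_date[members], each = k) + rep(sched$rel_day, m) + jit,
      category = rep(sched$category, m), stringsAsFactors = FALSE)
  }
  # risk-defining diagnoses: atherosclerotic disease for very-high,
  # diabetes for high (hypertension is planted freely; smoking only for
  # very-high patients so a planted high-risk patient cannot escalate)
  vh <- which(risk == "very_high")
  hi <- which(risk == "high")
  dx_parts[["risk_vh"]] <- data.frame(
    patient_id = ids[vh],
    date = index_date[vh] - sample(30:900, length(vh), replace = TRUE),
    category = "coronary_artery_disease", stringsAsFactors = FALSE)
  dx_parts[["risk_hi"]] <- data.frame(
    patient_id = ids[hi],
    date = index_date[hi] - sample(30:900, length(hi), replace = TRUE),
    category = "diabetes", stringsAsFactors = FALSE)
  prev <- spec$diagnosis_prevalences
  for (cat_name in names(prev)) {
    eligible <- if (cat_name == "smoking") vh else seq_len(n)
    if (cat_name == "diabetes") eligible <- vh  # high patients already have it
    drawn <- eligible[stats::runif(length(eligible)) < prev[[cat_name]]]
    if (!length(drawn)) next
    recent <- cat_name %in% c("hypertension", "smoking")
    offs <- if (recent) sample(30:300, length(drawn), replace = TRUE)
    else sample(30:900, length(drawn), replace = TRUE)
    dx_parts[[paste0("prev_", cat_name)]] <- data.frame(
      patient_id = ids[drawn], date = index_date[drawn] - offs,
      category = cat_name, stringsAsFactors = FALSE)
  }
  diagnoses <- do.call(rbind, dx_parts)

  patients <- data.frame(patient_id = ids, sex = sex, age_years = age,
                         stringsAsFactors = FALSE)
  labs <- data.frame(patient_id = ids, date = index_date, analyte = "ldl_c",
                     value_mg_dl = ldl, stringsAsFactors = FALSE)
  labels <- data.frame(patient_id = ids, true_si_category = si_cat,
                       generating_rule = template,
                       true_risk_category = risk, stringsAsFactors = FALSE)

  fmt <- function(df) { df$date <- format(df$date); df }
  cohort <- emr_cohort(patients, fmt(prescriptions), fmt(labs),
                       fmt(diagnoses))
  list(cohort = cohort, labels = labels[order(labels$patient_id), ])
}
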