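# Cardiovascular risk categorisation (2019 ESC/EAS reading) and LDL-C
# treatment targets.

ASCVD_CATEGORIES <- c("coronary_artery_disease", "cerebrovascular_disease",
                      "peripheral_artery_disease")

#' Default cardiovascular risk rule table
#'
#' A standard 2019 ESC/EAS reading restricted to the high / very-high
#' categories the analysis needs: documented atherosclerotic cardiovascular
#' disease or chronic kidney disease puts a patient at very-high risk, as
#' does diabetes accompanied by the configured number of additional risk
#' factors; diabetes alone, or the full risk-factor combination without
#' diabetes, is high risk.  Stored as a plain list so site-specific code
#' lists can be substituted.
#'
#' @return List with components `very_high_any` (categories individually
#'   sufficient for very-high), `risk_factors` (modifier categories),
#'   `diabetes_rf_needed` (risk factors needed to escalate diabetes to
#'   very-high) and `high_rf_needed` (risk factors that together make high
#'   risk without diabetes).
#' @export
default_risk_rules <- function() {
  list(very_high_any = c(ASCVD_CATEGORIES, "chronic_kidney_disease"),
       risk_factors = c("hypertension", "smoking"),
       diabetes_rf_needed = 2L,
       high_rf_needed = 2L)
}

# look-back in days for one diagnosis category (Inf = unrestricted)
risk_lookback_for <- function(category, config) {
  if (category %in% c("hypertension", "smoking"))
    config$risk_lookback_days
  else if (category == "chronic_kidney_disease")
    config$ckd_lookback_days
  else Inf
}

#' Assign the cardiovascular risk category of one patient
#'
#' Diagnoses are filtered by category-specific look-backs anchored at the
#' index date (12 months for risk factors, 60 months for chronic kidney
#' disease, unrestricted for atherosclerotic disease, diabetes and the
#' remaining chronic conditions), then the rule table decides the category.
#' Patients qualifying for neither category are outside the study
#' population and get `NULL`.
#'
#' @param diagnoses One patient's diagnosis table.
#' @param index_date The patient's index date.
#' @param config A [selection_config()].
#' @param risk_rules Rule table, see [default_risk_rules()].
#' @return List of class `risk_profile` with `category` (`"very_high"` or
#'   `"high"`), `ldl_target_mg_dl` and `qualifying_conditions`, or `NULL`.
#' @export
assign_risk <- function(diagnoses, index_date,
                        config = selection_config(),
                        risk_rules = default_risk_rules()) {
  index_date <- as.Date(index_date)
  present <- character(0)
  if (nrow(diagnoses)) {
    keep <- vapply(seq_len(nrow(diagnoses)), function(i) {
      lb <- risk_lookback_for(diagnoses$category[i], config)
      diagnoses$date[i] <= index_date &&
        (is.infinite(lb) || diagnoses$date[i] >= index_date - lb)
    }, logical(1))
    present <- unique(diagnoses$category[keep])
  }
  rf <- intersect(risk_rules$risk_factors, present)
  vh_hits <- intersect(risk_rules$very_high_any, present)
  diabetic <- "diabetes" %in% present

  if (length(vh_hits) ||
      (diabetic && length(rf) >= risk_rules$diabetes_rf_needed)) {
    qual <- unique(c(vh_hits, if (diabetic && length(rf) >=
                                  risk_rules$diabetes_rf_needed)
      c("diabetes", rf)))
    return(structure(list(category = "very_high", ldl_target_mg_dl = 55,
                          qualifying_conditions = qual),
                     class = "risk_profile"))
  }
  if (diabetic || length(rf) >= risk_rules$high_rf_needed) {
    qual <- unique(c(if (diabetic) "diabetes",
                     if (length(rf) >= risk_rules$high_rf_needed) rf))
    return(structure(list(category = "high", ldl_target_mg_dl = 70,
                          qualifying_conditions = qual),
                     class = "risk_profile"))
  }
  NULL
}

#' LDL-C treatment target for a risk category
#'
#' @param category `"very_high"` or `"high"`.
#' @return Target threshold in mg/dL (55 or 70); attainment is strict
#'   (`ldl < target`).
#' @export
#' @examples
#' ldl_target("very_high")
ldl_target <- function(category) {
  vapply(category, function(cc) switch(cc,
    very_high = 55,
    high = 70,
    stop("ldl_target: unknown risk category '", cc, "'", call. = FALSE)
  ), numeric(1), USE.NAMES = FALSE)
}

#' Is an LDL-C value at its risk-based target?
#'
#' Strict inequality: a value exactly at the threshold is not at target.
#'
#' @param ldl_mg_dl Positive LDL-C value(s) in mg/dL.
#' @param category Risk category (recycled against `ldl_mg_dl`).
#' @return Logical vector.
#' @export
#' @examples
#' at_target(c(54.9, 55), "very_high")
at_target <- function(ldl_mg_dl, category) {
  if (any(ldl_mg_dl <= 0))
    stop("at_target: LDL-C must be positive", call. = FALSE)
  ldl_mg_dl < ldl_target(category)
}
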