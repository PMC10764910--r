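# End-to-end per-patient classification: outlier trim, index LDL-C, risk
# category, timeline, intolerance signals and rules -- the table every
# downstream step (simulation, reporting) consumes.

#' Classify a whole cohort
#'
#' Runs the full phenotyping pipeline over an [emr_cohort()]:
#' cohort-wide LDL-C outlier trimming, per-patient index-date selection
#' (last valid LDL-C in the selection window), cardiovascular risk
#' assignment, lipid-lowering-therapy timeline construction, intolerance
#' signal detection and rule evaluation.  Patients without a valid index
#' LDL-C or without a high / very-high risk profile are excluded and
#' accounted for in the `exclusions` attribute, so every input patient is
#' traceable to exactly one of: included, no_valid_ldl, no_risk_category.
#'
#' @param cohort An `emr_cohort`.
#' @param config A [selection_config()].
#' @param catalog A [statin_catalog()].
#' @param rules An [si_rules()] rule set.
#' @param risk_rules See [default_risk_rules()].
#' @return Data frame of class `si_cohort` with one row per included
#'   patient: `patient_id`, `index_date`, `ldl_mg_dl`, `risk_category`,
#'   `ldl_target`, `si_category`, `fired_rules` (";"-collapsed), `stratum`,
#'   `on_ezetimibe`, `on_bempedoic_or_pcsk9`, `baseline_statin_stratum`
#'   (`"moderate_or_high"` / `"low_or_none"`, for the bempedoic-acid effect
#'   model).  Attributes: `exclusions` (patient_id, reason) and
#'   `attrition` (named counts summing to the input cohort size).
#' @export
classify_cohort <- function(cohort,
                            config = selection_config(),
                            catalog = default_statin_catalog(),
                            rules = default_si_rules(),
                            risk_rules = default_risk_rules()) {
  stopifnot(inherits(cohort, "emr_cohort"))

  labs <- cohort$labs
  ldl_all <- labs$value_mg_dl[labs$analyte == "ldl_c"]
  b <- trim_bounds(ldl_all, config$outlier_trim_fraction)
  keep <- labs$analyte != "ldl_c" |
    (labs$value_mg_dl >= b[1] & labs$value_mg_dl <= b[2])
  labs <- labs[keep, , drop = FALSE]

  ids <- cohort$patients$patient_id
  rx_by <- split(cohort$prescriptions, cohort$prescriptions$patient_id)
  lab_by <- split(labs, labs$patient_id)
  dx_by <- split(cohort$diagnoses, cohort$diagnoses$patient_id)
  none_rx <- cohort$prescriptions[0, , drop = FALSE]
  none_lab <- labs[0, , drop = FALSE]
  none_dx <- cohort$diagnoses[0, , drop = FALSE]

  rows <- vector("list", length(ids))
  excl <- vector("list", length(ids))
  for (k in seq_along(ids)) {
    pid <- ids[k]
    p_rx <- rx_by[[pid]] %||% none_rx
    p_lab <- lab_by[[pid]] %||% none_lab
    p_dx <- dx_by[[pid]] %||% none_dx

    idx <- select_index_ldl(p_lab, p_rx, config)
    if (is.null(idx)) {
      excl[[k]] <- data.frame(patient_id = pid, reason = "no_valid_ldl")
      next
    }
    risk <- assign_risk(p_dx, idx$date, config, risk_rules)
    if (is.null(risk)) {
      excl[[k]] <- data.frame(patient_id = pid, reason = "no_risk_category")
      next
    }
    tl <- build_llt_timeline(p_rx, idx$date, config, catalog)
    sig <- detect_signals(tl, p_dx, config)
    cls <- classify_si(sig, tl, rules)

    on_statin <- !tl$statin_free_at_index && !is.null(tl$latest_statin)
    stat_stratum <- if (on_statin && tl$latest_statin$intensity_rank >= 2L)
      "moderate_or_high" else "low_or_none"
    rows[[k]] <- data.frame(
      patient_id = pid,
      index_date = idx$date,
      ldl_mg_dl = idx$value_mg_dl,
      risk_category = risk$category,
      ldl_target = risk$ldl_target_mg_dl,
      si_category = cls$category,
      fired_rules = paste(cls$fired_rules, collapse = ";"),
      stratum = cls$stratum,
      on_ezetimibe = any(c("ezetimibe", "fixed_combination") %in%
                           tl$latest_llt_classes),
      on_bempedoic_or_pcsk9 = any(c("bempedoic_acid", "pcsk9_inhibitor")
                                  %in% tl$latest_llt_classes),
      baseline_statin_stratum = stat_stratum,
      stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows[!vapply(rows, is.null, logical(1))])
  if (is.null(out)) {
    out <- data.frame(patient_id = character(0), index_date = as.Date(character(0)),
                      ldl_mg_dl = numeric(0), risk_category = character(0),
                      ldl_target = numeric(0), si_category = character(0),
                      fired_rules = character(0), stratum = character(0),
                      on_ezetimibe = logical(0), on_bempedoic_or_pcsk9 = logical(0),
                      baseline_statin_stratum = character(0))
  }
  rownames(out) <- NULL
  exclusions <- do.call(rbind, excl[!vapply(excl, is.null, logical(1))])
  if (is.null(exclusions))
    exclusions <- data.frame(patient_id = character(0), reason = character(0))
  attr(out, "exclusions") <- exclusions
  attr(out, "attrition") <- c(
    n_patients = length(ids),
    no_valid_ldl = sum(exclusions$reason == "no_valid_ldl"),
    no_risk_category = sum(exclusions$reason == "no_risk_category"),
    included = nrow(out))
  class(out) <- c("si_cohort", "data.frame")
  out
}

#' Write the classifier output table
#'
#' @param classified An `si_cohort` from [classify_cohort()].
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_classification <- function(classified, path) {
  df <- as.data.frame(classified)
  df$index_date <- format(df$index_date)
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
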