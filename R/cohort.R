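# EMR cohort container and delimited-file I/O.
#
# A cohort is four ordinary data frames sharing a patient_id key:
#   patients(patient_id, sex, age_years)
#   prescriptions(patient_id, date, drug_class, molecule, dose_mg, supply_days)
#   labs(patient_id, date, analyte, value_mg_dl)
#   diagnoses(patient_id, date, category)
# Dates are ISO-8601; files are comma-separated UTF-8 with a header row.

DRUG_CLASSES <- c("statin", "ezetimibe", "bempedoic_acid", "pcsk9_inhibitor",
                  "other_llt", "fixed_combination")

DIAGNOSIS_CATEGORIES <- c(
  "coronary_artery_disease", "cerebrovascular_disease",
  "peripheral_artery_disease", "diabetes", "hypertension", "smoking",
  "chronic_kidney_disease", "liver_disease", "gout", "hyperuricaemia",
  "documented_si_note", "sams", "other_si_event"
)

#' Assemble and validate an EMR cohort
#'
#' Bundles the four event tables into a validated `emr_cohort` object.
#' Event tables are sorted by patient and date; malformed rows (unparseable
#' dates, non-positive doses or lab values, unknown enums, events for
#' patients absent from the patient table) are rejected with an error that
#' names the offending row.
#'
#' @param patients,prescriptions,labs,diagnoses Data frames following the
#'   column schema above.
#' @return An object of class `emr_cohort`: a list with the four tables,
#'   dates converted to `Date`, rows sorted by `patient_id` then `date`.
#' @seealso [load_cohort()], [write_cohort()]
#' @export
emr_cohort <- function(patients, prescriptions, labs, diagnoses) {
  check_cols <- function(df, cols, what) {
    missing <- setdiff(cols, names(df))
    if (length(missing))
      stop("emr_cohort: ", what, " table lacks column(s) ",
           paste(missing, collapse = ", "), call. = FALSE)
  }
  check_cols(patients, c("patient_id", "sex", "age_years"), "patients")
  check_cols(prescriptions,
             c("patient_id", "date", "drug_class", "molecule", "dose_mg",
               "supply_days"), "prescriptions")
  check_cols(labs, c("patient_id", "date", "analyte", "value_mg_dl"), "labs")
  check_cols(diagnoses, c("patient_id", "date", "category"), "diagnoses")

  patients$patient_id <- as.character(patients$patient_id)
  if (anyDuplicated(patients$patient_id))
    stop("emr_cohort: duplicated patient_id in patients table", call. = FALSE)
  bad_sex <- which(!patients$sex %in% c("female", "male"))
  if (length(bad_sex))
    stop("emr_cohort: patients row ", bad_sex[1], ": sex must be female/male",
         call. = FALSE)

  fix_events <- function(df, what, checks) {
    df$patient_id <- as.character(df$patient_id)
    d <- parse_iso_date(df$date)
    bad <- which(is.na(d))
    if (length(bad))
      stop("emr_cohort: ", what, " row ", bad[1], ": unparseable date '",
           df$date[bad[1]], "'", call. = FALSE)
    df$date <- d
    unknown <- which(!df$patient_id %in% patients$patient_id)
    if (length(unknown))
      stop("emr_cohort: ", what, " row ", unknown[1],
           ": patient_id '", df$patient_id[unknown[1]],
           "' not in patients table", call. = FALSE)
    checks(df)
    df[order(df$patient_id, df$date), , drop = FALSE]
  }

  prescriptions <- fix_events(prescriptions, "prescriptions", function(df) {
    df$dose_mg <- suppressWarnings(as.numeric(df$dose_mg))
    bad <- which(is.na(df$dose_mg) | df$dose_mg <= 0)
    if (length(bad))
      stop("emr_cohort: prescriptions row ", bad[1],
           ": dose_mg must be a positive number", call. = FALSE)
    bad <- which(!df$drug_class %in% DRUG_CLASSES)
    if (length(bad))
      stop("emr_cohort: prescriptions row ", bad[1],
           ": unknown drug_class '", df$drug_class[bad[1]], "'",
           call. = FALSE)
    sup <- suppressWarnings(as.integer(df$supply_days))
    bad <- which(!is.na(df$supply_days) & (is.na(sup) | sup <= 0))
    if (length(bad))
      stop("emr_cohort: prescriptions row ", bad[1],
           ": supply_days must be a positive integer or empty",
           call. = FALSE)
  })
  # re-coerce after validation (fix_events works on a copy inside checks)
  prescriptions$dose_mg <- as.numeric(prescriptions$dose_mg)
  prescriptions$supply_days <- suppressWarnings(as.integer(prescriptions$supply_days))

  labs <- fix_events(labs, "labs", function(df) {
    v <- suppressWarnings(as.numeric(df$value_mg_dl))
    bad <- which(is.na(v) | v <= 0)
    if (length(bad))
      stop("emr_cohort: labs row ", bad[1],
           ": value_mg_dl must be a positive number", call. = FALSE)
    bad <- which(df$analyte != "ldl_c")
    if (length(bad))
      stop("emr_cohort: labs row ", bad[1], ": unknown analyte '",
           df$analyte[bad[1]], "'", call. = FALSE)
  })
  labs$value_mg_dl <- as.numeric(labs$value_mg_dl)

  diagnoses <- fix_events(diagnoses, "diagnoses", function(df) {
    bad <- which(!df$category %in% DIAGNOSIS_CATEGORIES)
    if (length(bad))
      stop("emr_cohort: diagnoses row ", bad[1], ": unknown category '",
           df$category[bad[1]], "'", call. = FALSE)
  })

  structure(list(patients = patients, prescriptions = prescriptions,
                 labs = labs, diagnoses = diagnoses),
            class = "emr_cohort")
}

#' Load an EMR cohort from delimited files
#'
#' Reads the four comma-separated tables and validates them via
#' [emr_cohort()].
#'
#' @param patients_path,prescriptions_path,labs_path,diagnoses_path CSV file
#'   paths.
#' @return An `emr_cohort`.
#' @export
load_cohort <- function(patients_path, prescriptions_path, labs_path,
                        diagnoses_path) {
  paths <- c(patients_path, prescriptions_path, labs_path, diagnoses_path)
  for (p in paths)
    if (!file.exists(p)) stop("load_cohort: no such file: ", p, call. = FALSE)
  rd <- function(p) utils::read.csv(p, colClasses = "character",
                                    stringsAsFactors = FALSE)
  pat <- rd(patients_path)
  if (nrow(pat)) pat$age_years <- as.numeric(pat$age_years)
  else pat$age_years <- numeric(0)
  emr_cohort(pat, rd(prescriptions_path), rd(labs_path), rd(diagnoses_path))
}

#' Write an EMR cohort to delimited files
#'
#' Emits `patients.csv`, `prescriptions.csv`, `labs.csv`, `diagnoses.csv`
#' under `dir`.  [load_cohort()] on the result reproduces the cohort
#' field-for-field.
#'
#' @param cohort An `emr_cohort`.
#' @param dir Output directory (created if needed).
#' @return Named character vector of the four paths, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  stopifnot(inherits(cohort, "emr_cohort"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- c(patients = file.path(dir, "patients.csv"),
             prescriptions = file.path(dir, "prescriptions.csv"),
             labs = file.path(dir, "labs.csv"),
             diagnoses = file.path(dir, "diagnoses.csv"))
  wr <- function(df, p) {
    for (col in names(df)) if (inherits(df[[col]], "Date"))
      df[[col]] <- format(df[[col]])
    utils::write.csv(df, p, row.names = FALSE, quote = FALSE, na = "")
  }
  wr(cohort$patients, paths["patients"])
  wr(cohort$prescriptions, paths["prescriptions"])
  wr(cohort$labs, paths["labs"])
  wr(cohort$diagnoses, paths["diagnoses"])
  invisible(paths)
}

#' @export
print.emr_cohort <- function(x, ...) {
  cat("EMR cohort: ", nrow(x$patients), " patients, ",
      nrow(x$prescriptions), " prescriptions, ",
      nrow(x$labs), " lab values, ",
      nrow(x$diagnoses), " diagnosis events\n", sep = "")
  invisible(x)
}

#' Extract one patient's record
#'
#' @param cohort An `emr_cohort`.
#' @param patient_id Patient identifier.
#' @return List with `patient` (one-row data frame), `prescriptions`,
#'   `labs`, `diagnoses` restricted to that patient.
#' @export
patient_record <- function(cohort, patient_id) {
  stopifnot(inherits(cohort, "emr_cohort"))
  if (!patient_id %in% cohort$patients$patient_id)
    stop("patient_record: unknown patient_id '", patient_id, "'",
         call. = FALSE)
  pick <- function(df) df[df$patient_id == patient_id, , drop = FALSE]
  list(patient = pick(cohort$patients),
       prescriptions = pick(cohort$prescriptions),
       labs = pick(cohort$labs),
       diagnoses = pick(cohort$diagnoses))
}
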