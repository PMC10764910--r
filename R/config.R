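#' Cohort selection and timeline configuration
#'
#' Bundles the windows and thresholds that anchor the whole analysis: the
#' selection period within which the index LDL-C is sought, the look-back
#' horizons for intolerance events, cardiovascular risk factors and chronic
#' kidney disease, the minimum time a lipid-lowering regimen must have been
#' in place for an LDL-C value to be attributable to it, and the
#' prescription-gap length that counts as discontinuation.
#'
#' @param selection_start,selection_end Calendar dates delimiting the
#'   selection window (defaults July 2020 -- June 2021); the index date is
#'   the last valid LDL-C measurement inside this window.
#' @param si_lookback_days Look-back before the index date for intolerance
#'   signals (default 1095, i.e. three years).
#' @param risk_lookback_days Look-back for cardiovascular risk factors such
#'   as hypertension and smoking (default 365).
#' @param ckd_lookback_days Look-back for chronic kidney disease
#'   (default 1825, i.e. 60 months).
#' @param llt_stability_days Minimum days a lipid-lowering regimen must
#'   precede an LDL-C draw for the value to count (default 28).
#' @param discontinuation_gap_days Statin-free gap, measured from end of
#'   supply, beyond which use counts as discontinued (default 180; the gap
#'   must strictly exceed this).
#' @param intermittent_min_gap_days Lower bound (exclusive) of the gap range
#'   scored as intermittent dosing; gaps in
#'   `(intermittent_min_gap_days, discontinuation_gap_days]` qualify
#'   (default 60).
#' @param outlier_trim_fraction Fraction trimmed per tail of the pooled
#'   LDL-C distribution (default 0.001).
#' @param default_supply_days Supply duration assumed for prescriptions that
#'   carry none (default 90 days, typical quarterly prescribing).
#' @return An object of class `selection_config` (a validated list).
#' @export
#' @examples
#' cfg <- selection_config()
#' cfg$discontinuation_gap_days
selection_config <- function(selection_start = as.Date("2020-07-01"),
                             selection_end = as.Date("2021-06-30"),
                             si_lookback_days = 1095L,
                             risk_lookback_days = 365L,
                             ckd_lookback_days = 1825L,
                             llt_stability_days = 28L,
                             discontinuation_gap_days = 180L,
                             intermittent_min_gap_days = 60L,
                             outlier_trim_fraction = 0.001,
                             default_supply_days = 90L) {
  cfg <- list(
    selection_start = as.Date(selection_start),
    selection_end = as.Date(selection_end),
    si_lookback_days = as.integer(si_lookback_days),
    risk_lookback_days = as.integer(risk_lookback_days),
    ckd_lookback_days = as.integer(ckd_lookback_days),
    llt_stability_days = as.integer(llt_stability_days),
    discontinuation_gap_days = as.integer(discontinuation_gap_days),
    intermittent_min_gap_days = as.integer(intermittent_min_gap_days),
    outlier_trim_fraction = as.numeric(outlier_trim_fraction),
    default_supply_days = as.integer(default_supply_days)
  )
  day_fields <- c("si_lookback_days", "risk_lookback_days",
                  "ckd_lookback_days", "llt_stability_days",
                  "discontinuation_gap_days", "intermittent_min_gap_days",
                  "default_supply_days")
  for (f in day_fields) {
    if (is.na(cfg[[f]]) || cfg[[f]] <= 0L)
      stop("selection_config: '", f, "' must be a positive integer",
           call. = FALSE)
  }
  if (is.na(cfg$selection_start) || is.na(cfg$selection_end) ||
      cfg$selection_start > cfg$selection_end)
    stop("selection_config: selection window is empty", call. = FALSE)
  if (cfg$outlier_trim_fraction < 0 || cfg$outlier_trim_fraction >= 0.5)
    stop("selection_config: outlier_trim_fraction must be in [0, 0.5)",
         call. = FALSE)
  if (cfg$intermittent_min_gap_days >= cfg$discontinuation_gap_days)
    stop("selection_config: intermittent_min_gap_days must be below ",
         "discontinuation_gap_days", call. = FALSE)
  structure(cfg, class = "selection_config")
}

#' @export
print.selection_config <- function(x, ...) {
  cat("Cohort selection configuration\n")
  cat("  selection window: ", format(x$selection_start), " .. ",
      format(x$selection_end), "\n", sep = "")
  cat("  look-backs (days): SI ", x$si_lookback_days,
      ", risk ", x$risk_lookback_days, ", CKD ", x$ckd_lookback_days,
      "\n", sep = "")
  cat("  LLT stability ", x$llt_stability_days,
      " d, discontinuation gap > ", x$discontinuation_gap_days,
      " d, intermittent gaps (", x$intermittent_min_gap_days, ", ",
      x$discontinuation_gap_days, "] d\n", sep = "")
  cat("  outlier trim ", x$outlier_trim_fraction, " per tail, default supply ",
      x$default_supply_days, " d\n", sep = "")
  invisible(x)
}

# ---------------------------------------------------------------------------
# Statin intensity catalog

#' Default statin intensity catalog
#'
#' Maps each statin molecule and dose band (mg/day, inclusive bounds) to a
#' treatment intensity (low / moderate / high).  `is_low_dose` equates
#' low-dose with low-intensity.  The catalog is an ordinary data frame so a
#' site-specific table can be swapped in wherever a `catalog` argument is
#' accepted; [read_config()]/[write_config()] round-trip it.
#'
#' @return A data frame of class `statin_catalog` with columns `molecule`,
#'   `dose_min`, `dose_max`, `intensity`, `intensity_rank`, `is_low_dose`.
#' @export
#' @examples
#' default_statin_catalog()
default_statin_catalog <- function() {
  entries <- rbind(
    data.frame(molecule = "simvastatin",  dose_min = 0,  dose_max = 10,  intensity = "low"),
    data.frame(molecule = "simvastatin",  dose_min = 20, dose_max = 40,  intensity = "moderate"),
    data.frame(molecule = "simvastatin",  dose_min = 80, dose_max = 80,  intensity = "high"),
    data.frame(molecule = "pravastatin",  dose_min = 0,  dose_max = Inf, intensity = "low"),
    data.frame(molecule = "fluvastatin",  dose_min = 0,  dose_max = Inf, intensity = "low"),
    data.frame(molecule = "lovastatin",   dose_min = 0,  dose_max = 20,  intensity = "low"),
    data.frame(molecule = "lovastatin",   dose_min = 40, dose_max = 40,  intensity = "moderate"),
    data.frame(molecule = "rosuvastatin", dose_min = 5,  dose_max = 5,   intensity = "low"),
    data.frame(molecule = "rosuvastatin", dose_min = 10, dose_max = 10,  intensity = "moderate"),
    data.frame(molecule = "rosuvastatin", dose_min = 20, dose_max = 40,  intensity = "high"),
    data.frame(molecule = "atorvastatin", dose_min = 0,  dose_max = 5,   intensity = "low"),
    data.frame(molecule = "atorvastatin", dose_min = 10, dose_max = 20,  intensity = "moderate"),
    data.frame(molecule = "atorvastatin", dose_min = 40, dose_max = 80,  intensity = "high")
  )
  statin_catalog(entries)
}

#' Construct and validate a statin catalog
#'
#' @param entries Data frame with columns `molecule`, `dose_min`,
#'   `dose_max`, `intensity`.  Dose bands of one molecule must not overlap.
#' @return The validated catalog with derived `intensity_rank` and
#'   `is_low_dose` columns.
#' @export
statin_catalog <- function(entries) {
  need <- c("molecule", "dose_min", "dose_max", "intensity")
  if (!all(need %in% names(entries)))
    stop("statin_catalog: entries need columns ",
         paste(need, collapse = ", "), call. = FALSE)
  ranks <- c(low = 1L, moderate = 2L, high = 3L)
  if (!all(entries$intensity %in% names(ranks)))
    stop("statin_catalog: intensity must be low/moderate/high", call. = FALSE)
  if (any(entries$dose_min > entries$dose_max))
    stop("statin_catalog: dose_min > dose_max", call. = FALSE)
  for (mol in unique(entries$molecule)) {
    b <- entries[entries$molecule == mol, , drop = FALSE]
    b <- b[order(b$dose_min), , drop = FALSE]
    if (nrow(b) > 1 && any(b$dose_min[-1] <= b$dose_max[-nrow(b)]))
      stop("statin_catalog: overlapping dose bands for ", mol, call. = FALSE)
  }
  entries$intensity_rank <- ranks[entries$intensity]
  entries$is_low_dose <- entries$intensity == "low"
  class(entries) <- c("statin_catalog", "data.frame")
  entries
}

#' Classify a statin prescription by intensity
#'
#' Deterministic look-up of a molecule/dose pair in the intensity catalog.
#'
#' @param molecule Statin molecule name (lower case).
#' @param dose_mg Daily dose in mg.
#' @param catalog A [statin_catalog()]; defaults to
#'   [default_statin_catalog()].
#' @return List with `intensity` ("low"/"moderate"/"high"),
#'   `intensity_rank` (1--3) and `is_low_dose`.
#' @export
#' @examples
#' classify_statin_regimen("rosuvastatin", 5)
#' classify_statin_regimen("atorvastatin", 80)
classify_statin_regimen <- function(molecule, dose_mg,
                                    catalog = default_statin_catalog()) {
  stopifnot(length(molecule) == 1L, length(dose_mg) == 1L, dose_mg > 0)
  hit <- catalog$molecule == molecule &
    catalog$dose_min <= dose_mg & dose_mg <= catalog$dose_max
  if (!any(hit)) {
    if (!molecule %in% catalog$molecule)
      stop("classify_statin_regimen: unknown statin molecule '", molecule,
           "'", call. = FALSE)
    stop("classify_statin_regimen: dose ", dose_mg,
         " mg outside configured bands for ", molecule, call. = FALSE)
  }
  row <- catalog[which(hit)[1], ]
  list(intensity = row$intensity,
       intensity_rank = unname(row$intensity_rank),
       is_low_dose = row$is_low_dose)
}

# Vectorised internal variant used by the timeline builder.
statin_intensity_rank <- function(molecule, dose_mg, catalog) {
  vapply(seq_along(molecule), function(i)
    classify_statin_regimen(molecule[i], dose_mg[i], catalog)$intensity_rank,
    integer(1))
}

# ---------------------------------------------------------------------------
# Whole-analysis configuration file (YAML)

#' Read / write the analysis configuration
#'
#' One structured YAML file carries every tunable of the pipeline: the
#' selection configuration, the statin catalog, the intolerance rule set,
#' the risk rules and the simulation section.  `write_config()` followed by
#' `read_config()` reproduces identical behaviour on any cohort.
#'
#' @param path File path.
#' @param config Named list with any of the components `selection`,
#'   `catalog`, `si_rules`, `risk_rules`, `simulation`.
#' @return `read_config()` returns the named list with components restored
#'   to their native classes; `write_config()` returns `path` invisibly.
#' @export
read_config <- function(path) {
  if (!file.exists(path))
    stop("read_config: no such file: ", path, call. = FALSE)
  raw <- yaml::read_yaml(path)
  out <- list()
  if (!is.null(raw$selection))
    out$selection <- do.call(selection_config, raw$selection)
  if (!is.null(raw$catalog))
    out$catalog <- statin_catalog(do.call(rbind, lapply(raw$catalog, function(e) {
      data.frame(molecule = e$molecule, dose_min = e$dose_min,
                 dose_max = if (identical(e$dose_max, "Inf")) Inf else e$dose_max,
                 intensity = e$intensity)
    })))
  if (!is.null(raw$si_rules))
    out$si_rules <- si_rules(raw$si_rules)
  if (!is.null(raw$risk_rules))
    out$risk_rules <- raw$risk_rules
  if (!is.null(raw$simulation))
    out$simulation <- raw$simulation
  out
}

#' @rdname read_config
#' @export
write_config <- function(config, path) {
  raw <- list()
  if (!is.null(config$selection)) {
    s <- unclass(config$selection)
    s$selection_start <- format(s$selection_start)
    s$selection_end <- format(s$selection_end)
    raw$selection <- s
  }
  if (!is.null(config$catalog)) {
    cat_df <- as.data.frame(config$catalog)
    raw$catalog <- lapply(seq_len(nrow(cat_df)), function(i) {
      list(molecule = cat_df$molecule[i],
           dose_min = cat_df$dose_min[i],
           dose_max = if (is.infinite(cat_df$dose_max[i])) "Inf" else cat_df$dose_max[i],
           intensity = cat_df$intensity[i])
    })
  }
  if (!is.null(config$si_rules)) raw$si_rules <- unclass(config$si_rules)
  if (!is.null(config$risk_rules)) raw$risk_rules <- config$risk_rules
  if (!is.null(config$simulation)) raw$simulation <- config$simulation
  yaml::write_yaml(raw, path)
  invisible(path)
}
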