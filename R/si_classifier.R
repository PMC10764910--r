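# Statin-intolerance phenotyping: prescription-pattern signals and the
# declarative rule set that maps them to absolute / partial / none.

SI_SIGNAL_NAMES <- c(
  "down_titration_same_molecule", "down_titration_different_molecule",
  "statin_switch", "specific_switch_to_low", "documented_si_note",
  "sams_event", "other_si_event", "intermittent_dosing",
  "low_dose_latest_statin", "nonstatin_llt_present",
  "discontinued_latest_statin", "long_term_discontinued",
  "permanently_discontinued", "statin_free_at_index"
)

NONSTATIN_CLASSES <- c("ezetimibe", "bempedoic_acid", "pcsk9_inhibitor",
                       "other_llt", "fixed_combination")

#' Detect statin-intolerance signals on a patient timeline
#'
#' Scans the statin episode sequence and the diagnosis stream for the
#' prescription-pattern signals the intolerance rules are written over:
#'
#' * *down-titration*: a later statin episode with strictly lower intensity
#'   rank than an earlier one (same- and different-molecule variants);
#' * *statin switch*: a molecule change between consecutive episodes;
#' * *specific switch to low*: atorvastatin or simvastatin at any dose
#'   followed by 5 mg rosuvastatin or any dose of pravastatin/fluvastatin;
#' * *intermittent dosing*: at least two supply gaps each in
#'   `(intermittent_min_gap_days, discontinuation_gap_days]`;
#' * documented intolerance notes, statin-associated muscle symptoms and
#'   other intolerance events taken from diagnosis categories within the
#'   look-back;
#' * regimen-state flags copied from the timeline (low-dose latest statin,
#'   non-statin therapy at index, discontinuation flags).
#'
#' @param timeline An [build_llt_timeline()] result.
#' @param diagnoses The patient's diagnosis table.
#' @param config A [selection_config()].
#' @return Named logical vector of class `si_signals`.
#' @export
detect_signals <- function(timeline, diagnoses,
                           config = selection_config()) {
  stopifnot(inherits(timeline, "llt_timeline"))
  sig <- stats::setNames(rep(FALSE, length(SI_SIGNAL_NAMES)), SI_SIGNAL_NAMES)
  eps <- timeline$episodes
  n <- nrow(eps)
  if (n >= 2) {
    for (j in 2:n) {
      lower <- eps$intensity_rank[j] < eps$intensity_rank[seq_len(j - 1)]
      same <- eps$molecule[j] == eps$molecule[seq_len(j - 1)]
      if (any(lower & same)) sig["down_titration_same_molecule"] <- TRUE
      if (any(lower & !same)) sig["down_titration_different_molecule"] <- TRUE
    }
    consec_switch <- eps$molecule[-1] != eps$molecule[-n]
    sig["statin_switch"] <- any(consec_switch)
    from_as <- eps$molecule[-n] %in% c("atorvastatin", "simvastatin")
    to_low <- (eps$molecule[-1] == "rosuvastatin" & eps$dose_mg[-1] == 5) |
      eps$molecule[-1] %in% c("pravastatin", "fluvastatin")
    sig["specific_switch_to_low"] <- any(from_as & to_low)
  }
  inter <- timeline$gaps[!timeline$gaps$terminal, , drop = FALSE]
  qualifying <- inter$length_days > config$intermittent_min_gap_days &
    inter$length_days <= config$discontinuation_gap_days
  sig["intermittent_dosing"] <- sum(qualifying) >= 2

  if (nrow(diagnoses)) {
    lb_start <- timeline$index_date - config$si_lookback_days
    in_window <- diagnoses$date >= lb_start &
      diagnoses$date <= timeline$index_date
    cats <- diagnoses$category[in_window]
    sig["documented_si_note"] <- "documented_si_note" %in% cats
    sig["sams_event"] <- "sams" %in% cats
    sig["other_si_event"] <- "other_si_event" %in% cats
  }

  latest <- timeline$latest_statin
  sig["low_dose_latest_statin"] <- !is.null(latest) && nrow(latest) == 1 &&
    latest$intensity_rank == 1L
  sig["nonstatin_llt_present"] <-
    any(timeline$latest_llt_classes %in% NONSTATIN_CLASSES)
  sig["discontinued_latest_statin"] <- n >= 1 && timeline$statin_free_at_index
  sig["long_term_discontinued"] <- timeline$long_term_discontinued
  sig["permanently_discontinued"] <- timeline$permanently_discontinued
  sig["statin_free_at_index"] <- timeline$statin_free_at_index
  class(sig) <- c("si_signals", class(sig))
  sig
}

#' Statin-intolerance rule set
#'
#' The classifier is driven by named boolean expressions over the signal
#' names of [detect_signals()], grouped into `absolute` and `partial`
#' rules.  `si_rules()` validates a rule list (each element `id`,
#' `category`, `expr`); [default_si_rules()] returns the default reading:
#' absolute intolerance requires permanent statin discontinuation together
#' with any intolerance evidence, partial intolerance requires continued
#' statin use (no long-term gap, statin supply active at index) together
#' with a tolerability-driven regimen signal.
#'
#' @param rules List of rules, each a list with character fields `id`,
#'   `category` (`"absolute"` or `"partial"`) and `expr` (an R boolean
#'   expression over signal names, using only `!`, `&`, `|`, parentheses).
#' @return Validated list of class `si_rules`.
#' @export
si_rules <- function(rules) {
  allowed_ops <- c("(", "!", "&", "|", "&&", "||")
  for (r in rules) {
    if (!all(c("id", "category", "expr") %in% names(r)))
      stop("si_rules: each rule needs id, category, expr", call. = FALSE)
    if (!r$category %in% c("absolute", "partial"))
      stop("si_rules: rule '", r$id, "': category must be absolute/partial",
           call. = FALSE)
    syms <- setdiff(all.names(parse(text = r$expr)[[1]]), allowed_ops)
    unknown <- setdiff(syms, SI_SIGNAL_NAMES)
    if (length(unknown))
      stop("si_rules: rule '", r$id, "' references unknown signal(s): ",
           paste(unknown, collapse = ", "), call. = FALSE)
  }
  ids <- vapply(rules, `[[`, character(1), "id")
  if (anyDuplicated(ids))
    stop("si_rules: duplicated rule id", call. = FALSE)
  structure(rules, class = "si_rules")
}

#' @rdname si_rules
#' @export
default_si_rules <- function() {
  rule <- function(id, category, expr)
    list(id = id, category = category, expr = expr)
  continued <- "!long_term_discontinued & !statin_free_at_index & "
  si_rules(list(
    rule("abs_documented_note", "absolute",
         "permanently_discontinued & documented_si_note"),
    rule("abs_sams", "absolute",
         "permanently_discontinued & sams_event"),
    rule("abs_other_event", "absolute",
         "permanently_discontinued & other_si_event"),
    rule("abs_down_titration", "absolute",
         paste0("permanently_discontinued & (down_titration_same_molecule",
                " | down_titration_different_molecule)")),
    rule("abs_switch", "absolute",
         "permanently_discontinued & statin_switch"),
    rule("abs_intermittent", "absolute",
         "permanently_discontinued & intermittent_dosing"),
    rule("abs_low_dose_latest", "absolute",
         "permanently_discontinued & low_dose_latest_statin"),
    rule("par_specific_switch", "partial",
         paste0(continued, "specific_switch_to_low")),
    rule("par_down_titration_diff", "partial",
         paste0(continued, "down_titration_different_molecule")),
    rule("par_documented_note", "partial",
         paste0(continued, "documented_si_note")),
    rule("par_down_same_with_switch", "partial",
         paste0(continued, "down_titration_same_molecule & statin_switch")),
    rule("par_low_dose_plus_nonstatin", "partial",
         paste0(continued, "low_dose_latest_statin & nonstatin_llt_present"))
  ))
}

#' Classify a patient's statin-intolerance status
#'
#' Evaluates the rule expressions on the signal set.  Absolute rules are
#' evaluated first and dominate: a patient satisfying both an absolute and
#' a partial rule is absolute (permanent discontinuation dominates
#' clinically).  A patient firing no rule is `none`.
#'
#' @param signals An `si_signals` vector from [detect_signals()].
#' @param timeline The matching `llt_timeline` (used for the
#'   latest-regimen stratum).
#' @param rules An [si_rules()] list; default [default_si_rules()].
#' @return List of class `si_classification` with `category`
#'   (`"absolute"`, `"partial"`, `"none"`), `fired_rules` (ids, empty iff
#'   `none`) and `stratum` (`"only_nonstatin_llt"`, `"low_dose_latest"`,
#'   `"other"`).
#' @export
classify_si <- function(signals, timeline, rules = default_si_rules()) {
  stopifnot(inherits(rules, "si_rules"))
  env <- as.list(signals)
  fired <- vapply(rules, function(r)
    isTRUE(eval(parse(text = r$expr)[[1]], env)), logical(1))
  cats <- vapply(rules, `[[`, character(1), "category")
  ids <- vapply(rules, `[[`, character(1), "id")
  category <- if (any(fired & cats == "absolute")) "absolute"
  else if (any(fired & cats == "partial")) "partial"
  else "none"
  fired_rules <- if (category == "none") character(0)
  else ids[fired & cats == category]
  stratum <- if (signals[["statin_free_at_index"]] &&
                 signals[["nonstatin_llt_present"]]) "only_nonstatin_llt"
  else if (signals[["low_dose_latest_statin"]]) "low_dose_latest"
  else "other"
  structure(list(category = category, fired_rules = fired_rules,
                 stratum = stratum),
            class = "si_classification")
}

#' @export
print.si_classification <- function(x, ...) {
  cat("SI classification: ", x$category, sep = "")
  if (length(x$fired_rules))
    cat(" (", paste(x$fired_rules, collapse = ", "), ")", sep = "")
  cat(" | stratum: ", x$stratum, "\n", sep = "")
  invisible(x)
}
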