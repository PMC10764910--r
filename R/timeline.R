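# Prescription timeline algebra: supply coverage, gap detection, episode
# merging, index-date selection and cohort-wide outlier trimming.
#
# All interval arithmetic is in whole days on half-open intervals
# [start, end): a prescription on day d with s supply days covers
# d, d+1, ..., d+s-1.

#' Trim distribution tails from a vector of laboratory values
#'
#' Removes values strictly below the `trim_fraction` quantile and strictly
#' above the `1 - trim_fraction` quantile (type-6 quantiles, clamped to the
#' sample range, so small samples lose nothing).  Applied cohort-wide to
#' pooled LDL-C before index selection.
#'
#' @param values Numeric vector.
#' @param trim_fraction Fraction per tail in `[0, 0.5)`.
#' @return The retained values, order preserved.
#' @export
#' @examples
#' length(trim_outliers(1:1000, 0.001))  # 998: single min and max removed
trim_outliers <- function(values, trim_fraction) {
  stopifnot(trim_fraction >= 0, trim_fraction < 0.5)
  if (!length(values)) return(values)
  b <- trim_bounds(values, trim_fraction)
  values[values >= b[1] & values <= b[2]]
}

trim_bounds <- function(values, trim_fraction) {
  if (!length(values) || trim_fraction == 0)
    return(c(-Inf, Inf))
  stats::quantile(values, c(trim_fraction, 1 - trim_fraction),
                  type = 6, names = FALSE)
}

# Fill absent supply_days with the configured default.
fill_supply <- function(rx, config) {
  s <- rx$supply_days
  s[is.na(s)] <- config$default_supply_days
  rx$supply_days <- as.integer(s)
  rx
}

# Merge prescriptions of one patient into regimen episodes
# (drug_class, molecule, dose_mg), splitting when the regimen changes or
# the supply gap strictly exceeds max_gap_days.  Returns a data frame with
# one row per episode: start, end (end of last supply), plus regimen fields.
merge_episodes <- function(rx, max_gap_days) {
  if (!nrow(rx)) {
    return(data.frame(drug_class = character(0), molecule = character(0),
                      dose_mg = numeric(0), start = as.Date(character(0)),
                      end = as.Date(character(0)), n_rx = integer(0)))
  }
  rx <- rx[order(rx$date), , drop = FALSE]
  regimen <- paste(rx$drug_class, rx$molecule, rx$dose_mg)
  cov_end <- as.Date(cummax(as.integer(rx$date + rx$supply_days)),
                     origin = "1970-01-01")
  n <- nrow(rx)
  new_ep <- c(TRUE, regimen[-1] != regimen[-n] |
                as.integer(rx$date[-1] - cov_end[-n]) > max_gap_days)
  ep_id <- cumsum(new_ep)
  starts <- tapply(as.integer(rx$date), ep_id, min)
  ends <- tapply(as.integer(rx$date + rx$supply_days), ep_id, max)
  first <- which(new_ep)
  data.frame(drug_class = rx$drug_class[first],
             molecule = rx$molecule[first],
             dose_mg = rx$dose_mg[first],
             start = as.Date(as.integer(starts), origin = "1970-01-01"),
             end = as.Date(as.integer(ends), origin = "1970-01-01"),
             n_rx = as.integer(tabulate(ep_id)),
             row.names = NULL)
}

# Like merge_episodes, but merging each regimen stream separately so that
# date-interleaved prescriptions of co-medications (e.g. a statin plus
# ezetimibe) do not fragment each other's episodes.  Used for the
# LLT-stability validity check of LDL-C measurements.
stream_episodes <- function(rx, max_gap_days) {
  key <- paste(rx$drug_class, rx$molecule, rx$dose_mg)
  parts <- lapply(split(rx, key), merge_episodes, max_gap_days = max_gap_days)
  out <- do.call(rbind, parts)
  if (is.null(out)) out <- merge_episodes(rx[0, , drop = FALSE], max_gap_days)
  rownames(out) <- NULL
  out[order(out$start), , drop = FALSE]
}

#' Build a lipid-lowering-therapy timeline for one patient
#'
#' Restricts prescriptions to the intolerance look-back window before the
#' index date, resolves same-day duplicate statins to the higher intensity,
#' merges consecutive same-regimen statin prescriptions into episodes, and
#' derives supply gaps and discontinuation flags.  A gap is the positive
#' distance between the end of cumulative statin supply and the next statin
#' prescription (or the index date); a gap strictly longer than
#' `config$discontinuation_gap_days` marks long-term discontinuation, and a
#' terminal such gap (no statin afterwards up to the index) marks permanent
#' discontinuation.
#'
#' @param prescriptions One patient's prescription table (any drug classes).
#' @param index_date The patient's index date.
#' @param config A [selection_config()].
#' @param catalog A [statin_catalog()].
#' @return An object of class `llt_timeline`: list with `index_date`,
#'   `episodes` (statin episodes with intensity), `gaps`
#'   (`start`, `end`, `length_days`, `terminal`), `latest_statin` (one-row
#'   data frame or `NULL`), `latest_llt_classes` (drug classes with supply
#'   active at index), and the logical flags `long_term_discontinued`,
#'   `permanently_discontinued`, `statin_free_at_index`.
#' @export
build_llt_timeline <- function(prescriptions, index_date,
                               config = selection_config(),
                               catalog = default_statin_catalog()) {
  index_date <- as.Date(index_date)
  rx <- fill_supply(prescriptions, config)
  window_start <- index_date - config$si_lookback_days
  rx <- rx[rx$date >= window_start & rx$date <= index_date, , drop = FALSE]

  empty <- function() {
    structure(list(index_date = index_date,
                   episodes = merge_episodes(rx[0, , drop = FALSE], 0),
                   gaps = data.frame(start = as.Date(character(0)),
                                     end = as.Date(character(0)),
                                     length_days = integer(0),
                                     terminal = logical(0)),
                   latest_statin = NULL,
                   latest_llt_classes = active_classes(rx, index_date),
                   long_term_discontinued = FALSE,
                   permanently_discontinued = FALSE,
                   statin_free_at_index = TRUE),
              class = "llt_timeline")
  }

  st <- rx[rx$drug_class == "statin", , drop = FALSE]
  if (!nrow(st)) return(empty())

  # same-day duplicates: keep the higher-intensity regimen for that day
  st$rank <- statin_intensity_rank(st$molecule, st$dose_mg, catalog)
  st <- st[order(st$date, -st$rank, -st$dose_mg, st$molecule), , drop = FALSE]
  st <- st[!duplicated(st$date), , drop = FALSE]

  # supply gaps on the pooled statin stream
  cov_end <- as.Date(cummax(as.integer(st$date + st$supply_days)),
                     origin = "1970-01-01")
  n <- nrow(st)
  gap_start <- cov_end[-n]
  gap_end <- st$date[-1]
  gl <- as.integer(gap_end - gap_start)
  keep <- which(gl > 0)
  gaps <- data.frame(start = gap_start[keep], end = gap_end[keep],
                     length_days = gl[keep],
                     terminal = rep(FALSE, length(keep)))
  term_len <- as.integer(index_date - cov_end[n])
  if (term_len > 0) {
    gaps <- rbind(gaps, data.frame(start = cov_end[n], end = index_date,
                                   length_days = term_len, terminal = TRUE))
  }

  episodes <- merge_episodes(st, config$discontinuation_gap_days)
  episodes$intensity_rank <- statin_intensity_rank(episodes$molecule,
                                                   episodes$dose_mg, catalog)
  episodes$intensity <- c("low", "moderate", "high")[episodes$intensity_rank]

  long_term <- any(gaps$length_days > config$discontinuation_gap_days)
  permanent <- term_len > config$discontinuation_gap_days
  statin_free <- term_len >= 0  # supply interval [date, date+supply) open at index

  structure(list(index_date = index_date,
                 episodes = episodes,
                 gaps = gaps,
                 latest_statin = episodes[nrow(episodes), , drop = FALSE],
                 latest_llt_classes = active_classes(rx, index_date),
                 long_term_discontinued = long_term,
                 permanently_discontinued = permanent,
                 statin_free_at_index = statin_free),
            class = "llt_timeline")
}

# Drug classes with supply covering the index date.
active_classes <- function(rx, index_date) {
  if (!nrow(rx)) return(character(0))
  act <- rx$date <= index_date & (rx$date + rx$supply_days) > index_date
  sort(unique(rx$drug_class[act]))
}

#' @export
print.llt_timeline <- function(x, ...) {
  cat("LLT timeline to index ", format(x$index_date), ": ",
      nrow(x$episodes), " statin episode(s), ", nrow(x$gaps),
      " supply gap(s)\n", sep = "")
  if (x$permanently_discontinued) cat("  permanently discontinued\n")
  else if (x$long_term_discontinued) cat("  long-term discontinuation\n")
  else if (x$statin_free_at_index && nrow(x$episodes))
    cat("  statin supply exhausted at index\n")
  invisible(x)
}

#' Select the index LDL-C measurement for one patient
#'
#' The index measurement is the last valid LDL-C within the selection
#' window.  A measurement is valid if the patient is on no lipid-lowering
#' therapy on that day, or every regimen episode covering that day started
#' at least `config$llt_stability_days` before it (a value drawn shortly
#' after a regimen change does not reflect the regimen).
#'
#' @param labs One patient's lab table (already outlier-trimmed if the
#'   cohort-wide trim is wanted; see [classify_cohort()]).
#' @param prescriptions The same patient's prescription table.
#' @param config A [selection_config()].
#' @return One-row data frame (`date`, `value_mg_dl`) or `NULL` when no
#'   valid measurement exists -- a legal outcome that excludes the patient.
#' @export
select_index_ldl <- function(labs, prescriptions,
                             config = selection_config()) {
  ldl <- labs[labs$analyte == "ldl_c" &
                labs$date >= config$selection_start &
                labs$date <= config$selection_end, , drop = FALSE]
  if (!nrow(ldl)) return(NULL)
  rx <- fill_supply(prescriptions, config)
  eps <- stream_episodes(rx, config$discontinuation_gap_days)
  ok <- vapply(seq_len(nrow(ldl)), function(i) {
    d <- ldl$date[i]
    covering <- eps$start <= d & d < eps$end
    all(as.integer(d - eps$start[covering]) >= config$llt_stability_days)
  }, logical(1))
  ldl <- ldl[ok, , drop = FALSE]
  if (!nrow(ldl)) return(NULL)
  last <- which.max(as.integer(ldl$date))
  data.frame(date = ldl$date[last], value_mg_dl = ldl$value_mg_dl[last])
}
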