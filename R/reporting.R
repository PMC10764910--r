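# Cohort summary tables and arithmetic helpers.  All percentages use
# one-decimal round-half-up, recomputed from the table's own counts.

#' Prevalence of statin intolerance stratified by cardiovascular risk
#'
#' Cross-tabulates intolerance category (all / absolute / partial / none)
#' against risk category with counts and one-decimal percentages of the
#' total cohort.
#'
#' @param classified An `si_cohort` from [classify_cohort()] (or any data
#'   frame with `si_category` and `risk_category`); every row must carry
#'   both fields.
#' @return Data frame of class `prevalence_table`: rows `all`,
#'   `absolute_si`, `partial_si`, `no_si`; columns `n`, `pct`,
#'   `n_very_high`, `pct_very_high`, `n_high`, `pct_high`.
#' @export
summarize_prevalence <- function(classified) {
  df <- as.data.frame(classified)
  if (nrow(df) && (any(is.na(df$si_category)) || any(is.na(df$risk_category))))
    stop("summarize_prevalence: every patient needs a classification and ",
         "a risk category", call. = FALSE)
  n_all <- nrow(df)
  count <- function(si, risk = NULL) {
    keep <- if (is.null(si)) rep(TRUE, nrow(df)) else df$si_category %in% si
    if (!is.null(risk)) keep <- keep & df$risk_category == risk
    sum(keep)
  }
  pct <- function(k) if (n_all == 0) 0 else round_half_up(100 * k / n_all, 1)
  rows <- list(all = NULL, absolute_si = "absolute", partial_si = "partial",
               no_si = "none")
  out <- do.call(rbind, lapply(names(rows), function(rn) {
    k <- count(rows[[rn]]); kv <- count(rows[[rn]], "very_high")
    kh <- count(rows[[rn]], "high")
    data.frame(row = rn, n = k, pct = pct(k),
               n_very_high = kv, pct_very_high = pct(kv),
               n_high = kh, pct_high = pct(kh), stringsAsFactors = FALSE)
  }))
  class(out) <- c("prevalence_table", "data.frame")
  out
}

#' Percentage within an arbitrary denominator
#'
#' One-decimal round-half-up percentage, the convention of every reported
#' figure.
#'
#' @param count,total Non-negative counts, `total > 0`.
#' @return Percentage to one decimal.
#' @export
#' @examples
#' percent_of(11286, 130778)  # 8.6
percent_of <- function(count, total) {
  stopifnot(total > 0, count >= 0)
  round_half_up(100 * count / total, 1)
}

#' Relative LDL-C reduction between two medians
#'
#' @param baseline_mg_dl,post_mg_dl Positive values with
#'   `post_mg_dl <= baseline_mg_dl`.
#' @return `100 * (baseline - post) / baseline`, one decimal,
#'   round-half-up.
#' @export
#' @examples
#' relative_reduction(100, 80)  # 20.0
relative_reduction <- function(baseline_mg_dl, post_mg_dl) {
  if (any(baseline_mg_dl <= 0))
    stop("relative_reduction: baseline must be positive", call. = FALSE)
  if (any(post_mg_dl > baseline_mg_dl))
    stop("relative_reduction: post value exceeds baseline", call. = FALSE)
  round_half_up(100 * (baseline_mg_dl - post_mg_dl) / baseline_mg_dl, 1)
}

#' Bonferroni-corrected significance threshold
#'
#' @param alpha Family-wise level in (0, 1).
#' @param n_comparisons Number of comparisons (>= 1).
#' @return `alpha / n_comparisons`, truncated to 5 decimals (truncation
#'   keeps the reported threshold conservative: it never exceeds the exact
#'   corrected level).
#' @export
#' @examples
#' bonferroni_threshold(0.05, 13)  # 0.00384
bonferroni_threshold <- function(alpha, n_comparisons) {
  stopifnot(alpha > 0, alpha < 1)
  if (length(n_comparisons) != 1L || n_comparisons < 1)
    stop("bonferroni_threshold: n_comparisons must be >= 1", call. = FALSE)
  floor(1e5 * alpha / n_comparisons) / 1e5
}

#' Per-stage attainment report with both denominator conventions
#'
#' Re-expresses a [run_monte_carlo()] result with attainment both
#' cumulative over the intolerant cohort and relative to the prior step of
#' the escalation algorithm (patients entering each stage).
#'
#' @param result A `simulation_result`.
#' @return Data frame with per-stage `median_count_at_target`,
#'   `pct_of_si_cohort`, `pct_of_prior_step`, `median_ldl`, `mean_ldl`,
#'   `relative_reduction_percent`.
#' @export
stage_report <- function(result) {
  stopifnot(inherits(result, "simulation_result"))
  s <- result$stages
  # entering stage 1: not at target at baseline; stage 2: not at target
  # after ezetimibe -- both relative to the simulated population
  entering <- c(result$n_entering,
                result$n_entering - s$median_count_at_target[1],
                result$n_entering - s$median_count_at_target[2])
  newly <- c(s$median_count_at_target[1],
             diff(s$median_count_at_target))
  pct_prior <- ifelse(entering > 0,
                      round_half_up(100 * newly / entering, 1), 0)
  data.frame(stage = s$stage,
             median_count_at_target = s$median_count_at_target,
             pct_of_si_cohort = round_half_up(100 * s$attainment, 1),
             pct_of_prior_step = pct_prior,
             median_ldl = s$median_ldl,
             mean_ldl = s$mean_ldl,
             relative_reduction_percent = s$relative_reduction_percent)
}
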