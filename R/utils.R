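# Internal helpers shared across modules.

#' Round half away from zero
#'
#' Rounds to `digits` decimal places with exact halves going up
#' (`round_half_up(0.5) == 1`), unlike [base::round()]'s round-half-even.
#' All percentages reported by this package use this convention.
#'
#' @param x Numeric vector.
#' @param digits Number of decimal places (default 1).
#' @return Rounded numeric vector.
#' @export
#' @examples
#' round_half_up(c(1.25, 1.35), 1)
round_half_up <- function(x, digits = 1) {
  stopifnot(is.numeric(x), length(digits) == 1L, digits >= 0)
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}

#' Largest-remainder apportionment
#'
#' Splits `n` units across categories in proportion to `weights`, assigning
#' floors first and distributing the remaining units by descending
#' fractional remainder (ties broken by category order).  Used everywhere a
#' cohort mix must hit its target counts exactly.
#'
#' @param n Total count to apportion (non-negative integer).
#' @param weights Non-negative weights; need not sum to 1.
#' @return Integer vector of counts summing to `n`, named like `weights`.
#' @export
#' @examples
#' largest_remainder(1000, c(absolute = 0.018, partial = 0.068, none = 0.914))
largest_remainder <- function(n, weights) {
  stopifnot(length(n) == 1L, n >= 0, n == floor(n),
            is.numeric(weights), all(weights >= 0), sum(weights) > 0)
  quota <- n * weights / sum(weights)
  counts <- floor(quota)
  left <- n - sum(counts)
  if (left > 0) {
    # order() is stable, so ties fall to the earlier category
    take <- order(quota - counts, decreasing = TRUE)[seq_len(left)]
    counts[take] <- counts[take] + 1
  }
  counts <- as.integer(counts)
  names(counts) <- names(weights)
  counts
}

# Evaluate expr under a temporary RNG state seeded with `seed`, restoring
# the caller's state afterwards so library code never clobbers user RNG.
with_seed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(rm(".Random.seed", envir = globalenv()), add = TRUE)
  }
  set.seed(seed)
  expr
}

# Parse ISO-8601 dates strictly; NA for anything unparseable.
parse_iso_date <- function(x) {
  as.Date(as.character(x), format = "%Y-%m-%d")
}

`%||%` <- function(a, b) if (is.null(a)) b else a
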