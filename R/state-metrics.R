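# Alpha-state parameters: fractional occupancy and dwell-time statistics.

#' Fractional occupancy of the high alpha state
#'
#' Fraction of all epochs labeled high (symbol 1).
#'
#' @param seq A `state_sequence` or 0/1 vector.
#' @return Fraction in [0, 1].
#' @export
fractional_occupancy <- function(seq) {
  seq <- as_state_sequence(seq)
  mean(seq$symbols == 1L)
}

#' Extract dwell times (state run lengths)
#'
#' A dwell is a maximal run of contiguous epochs in the same state; its
#' length in epochs equals its duration in seconds at the 1-s grain. The
#' first and last runs are truncated by the recording edges; they are
#' included and flagged (set `censor_boundary = TRUE` to drop them).
#'
#' @param seq A `state_sequence` or 0/1 vector.
#' @param censor_boundary Drop the edge-truncated first/last runs?
#' @return An object of class `dwell_set`: `high_dwells`, `low_dwells`
#'   (run lengths in epochs), `n` (sequence length), `run_states` and
#'   `run_lengths` (the full run-length encoding), and logical
#'   `boundary_first`/`boundary_last` flags per run.
#' @examples
#' d <- extract_dwells(c(0, 1, 1, 0, 1))
#' d$high_dwells  # 2 1
#' d$low_dwells   # 1 1
#' @export
extract_dwells <- function(seq, censor_boundary = FALSE) {
  seq <- as_state_sequence(seq)
  r <- rle(seq$symbols)
  k <- length(r$lengths)
  boundary_first <- seq_len(k) == 1L
  boundary_last <- seq_len(k) == k
  keep <- if (censor_boundary) !(boundary_first | boundary_last)
          else rep(TRUE, k)
  structure(list(
    high_dwells = r$lengths[keep & r$values == 1L],
    low_dwells = r$lengths[keep & r$values == 0L],
    n = seq$n,
    run_states = r$values,
    run_lengths = r$lengths,
    boundary_first = boundary_first,
    boundary_last = boundary_last,
    censored = censor_boundary),
    class = "dwell_set")
}

#' @export
print.dwell_set <- function(x, ...) {
  cat(sprintf("dwell_set: %d high runs, %d low runs over %d epochs%s\n",
              length(x$high_dwells), length(x$low_dwells), x$n,
              if (x$censored) " (boundary runs censored)" else ""))
  invisible(x)
}

# ML tail exponent of a discrete power law above the median (Hill-type
# estimator with the standard -1/2 continuity correction).
powerlaw_tail_exponent <- function(dwells) {
  med <- stats::median(dwells)
  tail <- dwells[dwells > med]
  if (length(tail) < 2L) return(NA_real_)
  xmin <- min(tail)
  denom <- sum(log(tail / (xmin - 0.5)))
  if (denom <= 0) return(NA_real_)
  1 + length(tail) / denom
}

#' Summary statistics of a dwell-time distribution
#'
#' Mean and median by their standard definitions; mode is the smallest
#' most-frequent duration (deterministic tie-break); `variance_pct` is the
#' coefficient of variation, `100 * sd / mean` (0 for a single dwell); the
#' tail weight is, by default, the maximum-likelihood power-law exponent of
#' the dwell distribution above its median, with the mean/median ratio and
#' excess kurtosis as alternative named statistics. The statistic used is
#' recorded in the result.
#'
#' @param dwells Numeric vector of dwell durations (epochs, all >= 1), or a
#'   `dwell_set` (high and low dwells pooled).
#' @param tail_method One of `"powerlaw"`, `"mean_median_ratio"`,
#'   `"excess_kurtosis"`.
#' @return An object of class `dwell_stats`: `mean`, `median`, `mode`,
#'   `variance_pct`, `tail_weight`, `tail_method`, `n_dwells`.
#' @examples
#' dwell_stats(c(2, 2, 4))
#' @export
dwell_stats <- function(dwells,
                        tail_method = c("powerlaw", "mean_median_ratio",
                                        "excess_kurtosis")) {
  tail_method <- match.arg(tail_method)
  if (inherits(dwells, "dwell_set"))
    dwells <- c(dwells$high_dwells, dwells$low_dwells)
  dwells <- as.numeric(dwells)
  if (length(dwells) < 1L) stopf("at least one dwell required")
  if (any(dwells < 1)) stopf("dwell durations must be >= 1 epoch")
  m <- mean(dwells)
  s <- if (length(dwells) > 1L) stats::sd(dwells) else 0
  tab <- table(dwells)
  mode <- min(as.numeric(names(tab)[tab == max(tab)]))
  tw <- switch(tail_method,
    powerlaw = powerlaw_tail_exponent(dwells),
    mean_median_ratio = m / stats::median(dwells),
    excess_kurtosis = {
      if (length(dwells) < 2L || s == 0) NA_real_
      else mean((dwells - m)^4) / (mean((dwells - m)^2)^2) - 3
    })
  structure(list(mean = m, median = stats::median(dwells), mode = mode,
                 variance_pct = 100 * s / m, tail_weight = tw,
                 tail_method = tail_method, n_dwells = length(dwells)),
            class = "dwell_stats")
}

#' @export
print.dwell_stats <- function(x, ...) {
  cat(sprintf(
    "dwell_stats (n=%d): mean %.2f, median %.2f, mode %g, variance %.1f%%, tail weight %.2f (%s)\n",
    x$n_dwells, x$mean, x$median, x$mode, x$variance_pct, x$tail_weight,
    x$tail_method))
  invisible(x)
}

#' Long-format dwell table for export/plotting
#'
#' @param dwells A `dwell_set`.
#' @param participant_id,session Optional identifiers to stamp on each row.
#' @return Data frame with columns participant_id, session, state, dwell.
#' @export
dwell_table <- function(dwells, participant_id = NA_character_,
                        session = NA_integer_) {
  if (!inherits(dwells, "dwell_set")) stopf("`dwells` must be a dwell_set")
  data.frame(
    participant_id = participant_id, session = session,
    state = rep(c("high", "low"),
                c(length(dwells$high_dwells), length(dwells$low_dwells))),
    dwell = c(dwells$high_dwells, dwells$low_dwells),
    stringsAsFactors = FALSE)
}
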