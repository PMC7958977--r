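# Threshold-based symbolization of the alpha power series.
#
# Each 1-s epoch is labeled 1 (high alpha state) when its mean alpha power
# strictly exceeds an individualized threshold, else 0. The threshold is a
# percentage (30/50/70%) of the participant's "maximum alpha power", a
# robust cap derived from the session-1 resting eyes-open power distribution
# so that isolated high-amplitude fluctuations cannot set it.

#' Robust maximum alpha power of a resting recording
#'
#' Computes the robust cap used as the individual's "maximum alpha power".
#' The default reading is the Tukey upper fence `Q3 + 1.5 * IQR` of the
#' resting per-epoch power values (quantiles by linear interpolation); a
#' literal `1.5 * IQR` variant is available for comparison, but note that it
#' is a spread, not a power level, and can fall below the median.
#'
#' @param resting A `power_series` (or numeric vector) of resting eyes-open
#'   per-epoch alpha power; at least 4 epochs.
#' @param method `"fence"` (default, Tukey upper fence) or `"literal"`
#'   (1.5 * IQR).
#' @return Maximum alpha power in uV^2.
#' @export
max_alpha_power <- function(resting, method = c("fence", "literal")) {
  method <- match.arg(method)
  values <- if (inherits(resting, "power_series")) resting$values
            else as.numeric(resting)
  if (length(values) < 4L)
    stopf("at least 4 resting epochs required, got %d", length(values))
  q <- stats::quantile(values, c(0.25, 0.75), names = FALSE, type = 7)
  iqr <- q[2L] - q[1L]
  switch(method, fence = q[2L] + 1.5 * iqr, literal = 1.5 * iqr)
}

#' Individualized alpha-state threshold
#'
#' @param max_power Maximum alpha power (uV^2), e.g. from
#'   [max_alpha_power()].
#' @param percent Threshold percentage in (0, 100]; the study grid is
#'   30, 50 and 70.
#' @param source Identifier of the resting recording the threshold derives
#'   from (for traceability).
#' @return An object of class `threshold_spec` with fields `percent`,
#'   `max_power`, `threshold = percent/100 * max_power` and `source`.
#' @export
alpha_threshold <- function(max_power, percent = 30, source = NA_character_) {
  check_scalar(max_power, "max_power", lower = 0)
  check_scalar(percent, "percent")
  if (percent <= 0 || percent > 100)
    stopf("`percent` must be in (0, 100], got %g", percent)
  structure(list(percent = percent, max_power = max_power,
                 threshold = percent / 100 * max_power,
                 source = source),
            class = "threshold_spec")
}

#' @export
print.threshold_spec <- function(x, ...) {
  cat(sprintf("threshold_spec: %g%% of max power %.4g uV^2 -> %.4g uV^2 (source: %s)\n",
              x$percent, x$max_power, x$threshold, x$source))
  invisible(x)
}

#' Binary alpha-state sequence container
#'
#' @param symbols Vector of 0/1 symbols, one per retained 1-s epoch.
#' @return An object of class `state_sequence` with fields `symbols`
#'   (integer 0/1) and `n`.
#' @export
as_state_sequence <- function(symbols) {
  if (inherits(symbols, "state_sequence")) return(symbols)
  symbols <- as.integer(symbols)
  if (length(symbols) < 1L) stopf("state sequence must have length >= 1")
  if (anyNA(symbols) || !all(symbols %in% c(0L, 1L)))
    stopf("state symbols must all be 0 or 1")
  structure(list(symbols = symbols, n = length(symbols)),
            class = "state_sequence")
}

#' @export
print.state_sequence <- function(x, ...) {
  cat(sprintf("state_sequence: %d epochs, fractional occupancy %.3f\n",
              x$n, mean(x$symbols)))
  invisible(x)
}

#' Symbolize a power series into alpha states
#'
#' Labels each epoch 1 (high alpha state) when its power strictly exceeds
#' the threshold, 0 otherwise (ties go to the low state). Rejected epochs
#' were already dropped from the power series, so the state sequence is the
#' concatenation over retained epochs.
#'
#' @param power A `power_series` (or numeric vector).
#' @param threshold A `threshold_spec` or a single numeric threshold (uV^2).
#' @return A `state_sequence`.
#' @examples
#' symbolize(c(10, 40, 29, 31), 30)$symbols  # 0 1 0 1
#' @export
symbolize <- function(power, threshold) {
  values <- if (inherits(power, "power_series")) power$values
            else as.numeric(power)
  if (length(values) < 1L) stopf("empty power series")
  thr <- if (inherits(threshold, "threshold_spec")) threshold$threshold
         else check_scalar(threshold, "threshold")
  as_state_sequence(as.integer(values > thr))
}
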