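# Offline re-implementation of the real-time feedback computation: a 10-s
# sliding window is band-pass filtered at 8-13 Hz, alpha power is computed
# on the last 2 s of the window, and the power is mapped to a 0-10 dial
# calibrated so that 0 and 10 correspond to the 2nd and 98th percentile of
# the participant's resting-state alpha power.

#' Calibrate the feedback dial from resting power
#'
#' @param resting A `power_series` (or numeric vector) of resting alpha
#'   power; at least 50 epochs recommended (warning below that), and more
#'   than one distinct value required.
#' @param source Identifier of the resting recording (traceability).
#' @return An object of class `dial_calibration` with `p2` and `p98`, the
#'   2nd and 98th percentiles by linear interpolation.
#' @export
calibrate_dial <- function(resting, source = NA_character_) {
  values <- if (inherits(resting, "power_series")) resting$values
            else as.numeric(resting)
  if (length(unique(values)) < 2L)
    stopf("degenerate calibration: resting power is constant")
  if (length(values) < 50L)
    warnf("only %d resting epochs; >= 50 recommended for stable percentiles",
          length(values))
  q <- stats::quantile(values, c(0.02, 0.98), names = FALSE, type = 7)
  structure(list(p2 = q[1L], p98 = q[2L], source = source),
            class = "dial_calibration")
}

#' @export
print.dial_calibration <- function(x, ...) {
  cat(sprintf("dial_calibration: 0 at %.4g uV^2 (p2), 10 at %.4g uV^2 (p98)\n",
              x$p2, x$p98))
  invisible(x)
}

#' Map alpha power to the 0-10 dial
#'
#' Linear map `10 * (power - p2) / (p98 - p2)`, clipped to [0, 10].
#'
#' @param power Alpha power value(s) in uV^2.
#' @param calib A [calibrate_dial()] result.
#' @return Dial value(s) in [0, 10].
#' @export
dial_value <- function(power, calib) {
  if (!inherits(calib, "dial_calibration"))
    stopf("`calib` must be a dial_calibration")
  clip(10 * (power - calib$p2) / (calib$p98 - calib$p2), 0, 10)
}

#' Simulate the sliding-window feedback trace
#'
#' At each update time t (first at t = 10 s), the preceding 10-s window is
#' band-pass filtered (zero-phase Butterworth, order 4, 8-13 Hz by default)
#' and the alpha power is the time-domain mean square of the last 2 s of the
#' filtered window, averaged over channels, then mapped through the dial
#' calibration. The mean square of the band-limited segment equals the sum
#' of its periodogram over all bins (Parseval), so a pure in-band sinusoid
#' of amplitude a reads a^2/2.
#'
#' @param raw A [raw_eeg()] object of at least `window_secs` duration.
#' @param calib A [calibrate_dial()] result.
#' @param update_interval Seconds between dial updates (default 1).
#' @param band Pass band in Hz (default `c(8, 13)`).
#' @param window_secs Sliding-window length in seconds (default 10).
#' @param power_secs Tail of the window used for power (default 2).
#' @param filter_order Butterworth order (default 4, applied forward and
#'   backward).
#' @return An object of class `feedback_trace`: data frame with `time`
#'   (seconds from stream start) and `dial` in [0, 10].
#' @export
sliding_feedback <- function(raw, calib, update_interval = 1,
                             band = c(8, 13), window_secs = 10,
                             power_secs = 2, filter_order = 4) {
  if (!inherits(raw, "raw_eeg")) stopf("`raw` must be a raw_eeg object")
  if (!inherits(calib, "dial_calibration"))
    stopf("`calib` must be a dial_calibration")
  check_scalar(update_interval, "update_interval", lower = 1e-9)
  fs <- raw$sampling_rate
  n <- nrow(raw$samples)
  wn <- as.integer(round(window_secs * fs))
  pn <- as.integer(round(power_secs * fs))
  if (n < wn)
    stopf("stream (%.1f s) shorter than the %g-s sliding window", n / fs,
          window_secs)
  bf <- signal::butter(filter_order, band / (fs / 2), type = "pass")
  pad <- as.integer(min(fs, wn - 1L))  # odd-reflection pad absorbs edge transients
  times <- seq(window_secs, n / fs, by = update_interval)
  dial <- vapply(times, function(t) {
    end <- as.integer(round(t * fs))
    win <- raw$samples[(end - wn + 1L):end, , drop = FALSE]
    pow <- mean(apply(win, 2L, function(x) {
      xp <- c(2 * x[1L] - rev(x[2L:(pad + 1L)]), x,
              2 * x[wn] - rev(x[(wn - pad):(wn - 1L)]))
      xf <- signal::filtfilt(bf, xp)[(pad + 1L):(pad + wn)]
      mean(xf[(wn - pn + 1L):wn]^2)
    }))
    dial_value(pow, calib)
  }, numeric(1L))
  structure(data.frame(time = times, dial = dial),
            class = c("feedback_trace", "data.frame"))
}
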