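# Offline preprocessing: raw EEG -> per-epoch alpha-band power.
#
# The analysis grain is the 1-s non-overlapping epoch: the raw signal is
# anti-alias filtered and decimated to 250 Hz, cut into 1-s epochs, epochs
# with high-amplitude technical artifacts are flagged by a deterministic
# peak-amplitude criterion, and the mean alpha-band (8-13 Hz) periodogram
# power is computed per epoch and averaged over the frontal channels.

#' Raw EEG container
#'
#' @param samples Numeric matrix, time x channels (uV); finite values.
#' @param sampling_rate Sampling rate in Hz.
#' @param channel_labels Character vector, one label per column.
#' @return An object of class `raw_eeg`.
#' @export
raw_eeg <- function(samples, sampling_rate, channel_labels = colnames(samples)) {
  samples <- as.matrix(samples)
  check_scalar(sampling_rate, "sampling_rate", lower = 1e-9)
  if (is.null(channel_labels))
    stopf("channel labels required (none found on the matrix)")
  if (length(channel_labels) != ncol(samples))
    stopf("channel count (%d) != label count (%d)",
          ncol(samples), length(channel_labels))
  if (!all(is.finite(samples))) stopf("EEG samples must be finite")
  colnames(samples) <- channel_labels
  structure(list(samples = samples, sampling_rate = sampling_rate,
                 channel_labels = as.character(channel_labels)),
            class = "raw_eeg")
}

#' @export
print.raw_eeg <- function(x, ...) {
  cat(sprintf("raw_eeg: %d samples x %d channels (%s) @ %g Hz = %.1f s\n",
              nrow(x$samples), ncol(x$samples),
              paste(x$channel_labels, collapse = ", "),
              x$sampling_rate, nrow(x$samples) / x$sampling_rate))
  invisible(x)
}

#' Downsample EEG with anti-alias filtering
#'
#' Applies a zero-phase Butterworth low-pass (order 6, cutoff at 80% of the
#' target Nyquist) before keeping every `factor`-th sample. The original rate
#' must be an integer multiple of `target_rate`.
#'
#' @param raw A [raw_eeg()] object.
#' @param target_rate Target sampling rate in Hz (default 250).
#' @return A [raw_eeg()] at `target_rate`.
#' @export
downsample_eeg <- function(raw, target_rate = 250) {
  if (!inherits(raw, "raw_eeg")) stopf("`raw` must be a raw_eeg object")
  check_scalar(target_rate, "target_rate", lower = 1e-9)
  factor <- raw$sampling_rate / target_rate
  if (abs(factor - round(factor)) > 1e-9)
    stopf("sampling rate %g Hz is not an integer multiple of target %g Hz",
          raw$sampling_rate, target_rate)
  factor <- as.integer(round(factor))
  if (factor == 1L) return(raw)
  bf <- signal::butter(6, 0.8 / factor, type = "low")
  filtered <- apply(raw$samples, 2L, function(x)
    signal::filtfilt(bf, x))
  keep <- seq(1L, nrow(raw$samples), by = factor)
  raw_eeg(filtered[keep, , drop = FALSE], sampling_rate = target_rate,
          channel_labels = raw$channel_labels)
}

#' Segment EEG into non-overlapping epochs
#'
#' Cuts the signal into `epoch_duration`-second epochs; a trailing partial
#' epoch is discarded.
#'
#' @param raw A [raw_eeg()] object.
#' @param epoch_duration Epoch length in seconds (default 1).
#' @return An object of class `eeg_epochs`: samples array
#'   (time x epoch x channel), `sampling_rate`, `channel_labels`,
#'   `epoch_duration`, `n_epochs`, and a `rejected_mask` (all `FALSE` until
#'   [reject_artifact_epochs()] is applied).
#' @export
segment_epochs <- function(raw, epoch_duration = 1) {
  if (!inherits(raw, "raw_eeg")) stopf("`raw` must be a raw_eeg object")
  check_scalar(epoch_duration, "epoch_duration", lower = 1e-9)
  spe <- raw$sampling_rate * epoch_duration
  if (abs(spe - round(spe)) > 1e-9)
    stopf("epoch_duration must correspond to an integer number of samples")
  spe <- as.integer(round(spe))
  n_ep <- nrow(raw$samples) %/% spe
  if (n_ep < 1L)
    stopf("recording shorter than one epoch (%d < %d samples)",
          nrow(raw$samples), spe)
  nch <- ncol(raw$samples)
  arr <- array(raw$samples[seq_len(n_ep * spe), , drop = FALSE],
               dim = c(spe, n_ep, nch))
  structure(list(samples = arr, sampling_rate = raw$sampling_rate,
                 channel_labels = raw$channel_labels,
                 epoch_duration = epoch_duration, n_epochs = n_ep,
                 rejected_mask = rep(FALSE, n_ep)),
            class = "eeg_epochs")
}

#' Flag high-amplitude artifact epochs
#'
#' Deterministic stand-in for visual artifact inspection: an epoch is flagged
#' when its peak absolute amplitude on any channel exceeds the criterion.
#' A warning is raised when more than 10% of epochs are flagged, the nominal
#' cap on discarded data.
#'
#' @param epochs An `eeg_epochs` object.
#' @param amplitude_criterion Peak |amplitude| threshold in uV (default 100).
#' @return The `eeg_epochs` object with flagged epochs removed from
#'   `samples` and the full-length `rejected_mask` recorded.
#' @export
reject_artifact_epochs <- function(epochs, amplitude_criterion = 100) {
  if (!inherits(epochs, "eeg_epochs")) stopf("`epochs` must be an eeg_epochs object")
  check_scalar(amplitude_criterion, "amplitude_criterion", lower = 1e-9)
  peak <- apply(abs(epochs$samples), 2L, max)
  flagged <- peak > amplitude_criterion
  frac <- mean(flagged)
  if (frac > 0.10)
    warnf("%.1f%% of epochs exceed the %g uV artifact criterion (over the 10%% cap)",
          100 * frac, amplitude_criterion)
  epochs$samples <- epochs$samples[, !flagged, , drop = FALSE]
  epochs$rejected_mask <- flagged
  epochs$n_epochs <- sum(!flagged)
  epochs
}

#' One-sided periodogram of a single epoch
#'
#' Rectangular-window periodogram scaled so that the power values sum to the
#' time-domain mean square of the signal (Parseval).
#'
#' @param x Numeric vector of samples.
#' @param fs Sampling rate in Hz.
#' @return Data frame with `freq` (Hz, 0 to Nyquist) and `power` (uV^2).
#' @export
periodogram_power <- function(x, fs) {
  n <- length(x)
  X <- stats::fft(x)
  p2 <- Mod(X)^2 / n^2                     # two-sided
  half <- n %/% 2L
  idx <- seq_len(half + 1L)                # 0 .. Nyquist
  p1 <- p2[idx]
  dup <- idx > 1L & (idx - 1L) < (n - (idx - 1L))  # bins with a mirror image
  p1[dup] <- 2 * p1[dup]
  data.frame(freq = (idx - 1L) * fs / n, power = p1)
}

#' Per-epoch alpha-band power series
#'
#' Computes, for each retained epoch and each requested channel, the
#' rectangular-window periodogram and averages the power over the frequency
#' bins inside `band` (both edges inclusive), then averages over channels.
#'
#' @param epochs An `eeg_epochs` object (after optional artifact rejection).
#' @param band Length-2 frequency band in Hz, default `c(8, 13)`.
#' @param channels Channel labels to use, default `c("AF3", "AF4")`.
#' @return An object of class `power_series`: `values` (uV^2 per retained
#'   epoch), `epoch_duration`, `rejected_mask`, `band`, `channels`.
#' @export
alpha_power <- function(epochs, band = c(8, 13), channels = c("AF3", "AF4")) {
  if (!inherits(epochs, "eeg_epochs")) stopf("`epochs` must be an eeg_epochs object")
  if (length(band) != 2L || band[1L] <= 0 || band[2L] <= band[1L])
    stopf("`band` must be an increasing positive frequency pair")
  if (band[2L] > epochs$sampling_rate / 2)
    stopf("band upper edge %g Hz exceeds Nyquist %g Hz",
          band[2L], epochs$sampling_rate / 2)
  missing <- setdiff(channels, epochs$channel_labels)
  if (length(missing) > 0L)
    stopf("channel(s) %s not present; available: %s",
          paste(missing, collapse = ", "),
          paste(epochs$channel_labels, collapse = ", "))
  chi <- match(channels, epochs$channel_labels)
  spe <- dim(epochs$samples)[1L]
  freq <- (seq_len(spe %/% 2L + 1L) - 1L) * epochs$sampling_rate / spe
  in_band <- freq >= band[1L] & freq <= band[2L]
  if (!any(in_band)) stopf("no periodogram bins fall inside the band")
  vals <- vapply(seq_len(epochs$n_epochs), function(e) {
    mean(vapply(chi, function(ch) {
      pg <- periodogram_power(epochs$samples[, e, ch], epochs$sampling_rate)
      mean(pg$power[in_band])
    }, numeric(1L)))
  }, numeric(1L))
  power_series(vals, epoch_duration = epochs$epoch_duration,
               rejected_mask = epochs$rejected_mask,
               band = band, channels = channels)
}

#' Per-epoch power series container
#'
#' @param values Non-negative power per retained epoch (uV^2).
#' @param epoch_duration Epoch length in seconds.
#' @param rejected_mask Logical flag per original (pre-rejection) epoch.
#' @param band,channels Provenance of the band power.
#' @return An object of class `power_series`.
#' @export
power_series <- function(values, epoch_duration = 1,
                         rejected_mask = rep(FALSE, length(values)),
                         band = c(8, 13), channels = c("AF3", "AF4")) {
  values <- as.numeric(values)
  if (any(!is.finite(values)) || any(values < 0))
    stopf("power values must be finite and non-negative")
  if (length(values) != sum(!rejected_mask))
    stopf("length(values) (%d) must equal the number of retained epochs (%d)",
          length(values), sum(!rejected_mask))
  structure(list(values = values, epoch_duration = epoch_duration,
                 n_epochs = length(values), rejected_mask = rejected_mask,
                 band = band, channels = channels),
            class = "power_series")
}

#' @export
print.power_series <- function(x, ...) {
  cat(sprintf("power_series: %d epochs of %g s, band %g-%g Hz (%d rejected)\n",
              x$n_epochs, x$epoch_duration, x$band[1L], x$band[2L],
              sum(x$rejected_mask)))
  invisible(x)
}
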