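# Synthetic bistable-alpha cohort generator.
#
# The alpha rhythm alternates erratically between a high- and a low-amplitude
# mode; the generator realizes that as a two-state Markov chain on 1-s epochs
# driving the amplitude of a phase-continuous alpha oscillator buried in
# 1/f ("pink") plus white noise, and adds a small behavioral layer (VAS pain
# ratings with a planted dependence on high-state occupancy) so that every
# downstream stage of the analysis can be tested against known ground truth.

#' Two-state Markov transition parameters
#'
#' Per-epoch transition probabilities of the binary (low/high) alpha-state
#' chain that drives the synthetic amplitude dynamics.
#'
#' @param p_low_to_high Probability of moving low -> high in one 1-s epoch.
#' @param p_high_to_low Probability of moving high -> low in one 1-s epoch.
#' @param initial_state One of `"low"`, `"high"` or `"stationary"`;
#'   `"stationary"` draws the first state from the stationary distribution
#'   and requires `p_low_to_high + p_high_to_low > 0`.
#' @return An object of class `markov_params`.
#' @examples
#' markov_params(0.53, 0.25)
#' @export
markov_params <- function(p_low_to_high, p_high_to_low,
                          initial_state = c("stationary", "low", "high")) {
  check_prob(p_low_to_high, "p_low_to_high")
  check_prob(p_high_to_low, "p_high_to_low")
  initial_state <- match.arg(initial_state)
  if (initial_state == "stationary" && p_low_to_high + p_high_to_low <= 0)
    stopf("stationary initial state undefined when both transition probabilities are 0")
  structure(list(p_low_to_high = p_low_to_high,
                 p_high_to_low = p_high_to_low,
                 initial_state = initial_state),
            class = "markov_params")
}

#' Alpha oscillator emission parameters
#'
#' State-dependent amplitude of a fixed-frequency alpha oscillator plus
#' broadband noise, used to turn a state sequence into a raw EEG signal.
#'
#' @param alpha_freq Oscillator frequency in Hz (default 10, inside 8-13).
#' @param amp_high,amp_low Oscillator amplitude (uV) in the high and low
#'   state; `amp_high >= amp_low >= 0`.
#' @param pink_noise_sd,white_noise_sd Standard deviation (uV) of the 1/f and
#'   white noise components per channel.
#' @param sampling_rate Sampling rate in Hz; must exceed `2 * alpha_freq`.
#' @return An object of class `emission_params`.
#' @export
emission_params <- function(alpha_freq = 10, amp_high = 20, amp_low = 5,
                            pink_noise_sd = 2, white_noise_sd = 1,
                            sampling_rate = 1000) {
  check_scalar(alpha_freq, "alpha_freq", lower = 0)
  check_scalar(amp_high, "amp_high", lower = 0)
  check_scalar(amp_low, "amp_low", lower = 0)
  check_scalar(pink_noise_sd, "pink_noise_sd", lower = 0)
  check_scalar(white_noise_sd, "white_noise_sd", lower = 0)
  check_scalar(sampling_rate, "sampling_rate", lower = 0)
  if (amp_high < amp_low)
    stopf("amp_high (%g) must be >= amp_low (%g)", amp_high, amp_low)
  if (sampling_rate <= 2 * alpha_freq)
    stopf("sampling_rate must exceed twice alpha_freq (Nyquist)")
  structure(list(alpha_freq = alpha_freq, amp_high = amp_high,
                 amp_low = amp_low, pink_noise_sd = pink_noise_sd,
                 white_noise_sd = white_noise_sd,
                 sampling_rate = sampling_rate),
            class = "emission_params")
}

#' Simulate a binary alpha-state sequence
#'
#' Realizes the two-state Markov chain at 1-s epoch resolution: symbol 1 is
#' the high alpha state, 0 the low state.
#'
#' @param params A [markov_params()] object.
#' @param n_epochs Number of epochs (>= 1).
#' @param seed Optional integer seed for reproducibility.
#' @return A `state_sequence` (see [as_state_sequence()]).
#' @examples
#' s <- simulate_state_sequence(markov_params(0.53, 0.25), 1000, seed = 1)
#' fractional_occupancy(s)
#' @export
simulate_state_sequence <- function(params, n_epochs, seed = NULL) {
  if (!inherits(params, "markov_params"))
    stopf("`params` must be a markov_params object")
  check_scalar(n_epochs, "n_epochs", lower = 1)
  if (!is.null(seed)) set.seed(seed)
  p01 <- params$p_low_to_high
  p10 <- params$p_high_to_low
  s0 <- switch(params$initial_state,
               low = 0L, high = 1L,
               stationary = as.integer(stats::runif(1) < p01 / (p01 + p10)))
  n <- as.integer(n_epochs)
  symbols <- integer(n)
  symbols[1L] <- s0
  if (n > 1L) {
    u <- stats::runif(n - 1L)
    for (i in 2:n) {
      s <- symbols[i - 1L]
      symbols[i] <- if (s == 0L) as.integer(u[i - 1L] < p01)
                    else          as.integer(u[i - 1L] >= p10)
    }
  }
  as_state_sequence(symbols)
}

# 1/f-shaped Gaussian noise, unit variance, via spectral shaping of white
# noise (amplitude ~ f^(-1/2) for f > 0, DC zeroed).
pink_noise <- function(n) {
  if (n < 2L) return(stats::rnorm(n))
  x <- stats::rnorm(n)
  X <- stats::fft(x)
  # two-sided frequency index, symmetric about Nyquist
  k <- c(0, pmin(seq_len(n - 1L), n - seq_len(n - 1L)))
  scale <- c(0, 1 / sqrt(k[-1L]))
  y <- Re(stats::fft(X * scale, inverse = TRUE)) / n
  y / stats::sd(y)
}

#' Synthesize raw EEG from a state sequence
#'
#' Emits one second of signal per state symbol on two channels (AF3, AF4): a
#' shared, phase-continuous alpha oscillator whose amplitude is `amp_high`
#' during high-state epochs and `amp_low` during low-state epochs, plus
#' channel-independent pink (1/f) and white noise. Phase continuity across
#' epoch boundaries avoids spectral edge artifacts in the per-epoch power.
#'
#' @param states A `state_sequence` or 0/1 vector.
#' @param emission An [emission_params()] object.
#' @param seed Optional integer seed (noise only; the oscillator is
#'   deterministic).
#' @return A [raw_eeg()] object with `sampling_rate` samples per epoch and
#'   channels AF3 and AF4.
#' @export
synthesize_eeg <- function(states, emission = emission_params(), seed = NULL) {
  states <- as_state_sequence(states)
  if (!inherits(emission, "emission_params"))
    stopf("`emission` must be an emission_params object")
  if (!is.null(seed)) set.seed(seed)
  fs <- emission$sampling_rate
  if (abs(fs - round(fs)) > 1e-9)
    stopf("sampling_rate must be an integer number of samples per 1-s epoch")
  fs <- as.integer(round(fs))
  n_ep <- states$n
  n <- n_ep * fs
  amp <- rep(ifelse(states$symbols == 1L, emission$amp_high, emission$amp_low),
             each = fs)
  t <- (seq_len(n) - 1L) / fs
  osc <- amp * sin(2 * pi * emission$alpha_freq * t)
  make_channel <- function() {
    x <- osc
    if (emission$pink_noise_sd > 0)
      x <- x + emission$pink_noise_sd * pink_noise(n)
    if (emission$white_noise_sd > 0)
      x <- x + stats::rnorm(n, sd = emission$white_noise_sd)
    x
  }
  samples <- cbind(AF3 = make_channel(), AF4 = make_channel())
  raw_eeg(samples, sampling_rate = fs, channel_labels = c("AF3", "AF4"))
}

#' Cohort design for the synthetic study
#'
#' Describes a two-group (chronic pain patients, healthy participants),
#' multi-session neurofeedback cohort: per-group starting transition
#' probabilities with linear per-session drift ("learning"), recording
#' durations, the emission model, and a VAS pain model in which the session
#' pain level decreases by `effect_slope` VAS units per unit gain in
#' high-state fractional occupancy relative to session 1.
#'
#' Defaults place the healthy group at the session-1 transition probabilities
#' of the reference cohort (low->high 0.53, high->low 0.25, no drift) and
#' patients at low->high 0.37, high->low 0.22 with the high->low probability
#' drifting down by 0.04 per session, i.e. a planted occupancy increase.
#'
#' @param n_per_group Participants per group.
#' @param n_sessions Number of sessions (default 5).
#' @param patient_start,healthy_start Length-2 vectors
#'   `c(p_low_to_high, p_high_to_low)` at session 1.
#' @param patient_drift,healthy_drift Additive per-session increments to the
#'   two probabilities; drifted values are clipped to [0, 1].
#' @param resting_secs Seconds of eyes-open resting EEG per session.
#' @param nfb_secs Total seconds of neurofeedback training per session.
#' @param emission An [emission_params()] object.
#' @param baseline_vas Mean VAS pain rating (0-10) at baseline.
#' @param effect_slope VAS units of pain reduction per unit occupancy gain;
#'   either a single value or `c(patient = , healthy = )`.
#' @param vas_noise_sd Per-rating Gaussian noise SD (VAS units).
#' @param seed Integer master seed for the cohort.
#' @return An object of class `cohort_spec`.
#' @export
cohort_spec <- function(n_per_group = 4, n_sessions = 5,
                        patient_start = c(0.37, 0.22),
                        healthy_start = c(0.53, 0.25),
                        patient_drift = c(0, -0.04),
                        healthy_drift = c(0, 0),
                        resting_secs = 120, nfb_secs = 600,
                        emission = emission_params(),
                        baseline_vas = 7,
                        effect_slope = c(patient = 5, healthy = 0),
                        vas_noise_sd = 0.5,
                        seed = 1L) {
  check_scalar(n_per_group, "n_per_group", lower = 1)
  check_scalar(n_sessions, "n_sessions", lower = 1)
  check_scalar(resting_secs, "resting_secs", lower = 4)
  check_scalar(nfb_secs, "nfb_secs", lower = 1)
  check_scalar(baseline_vas, "baseline_vas", lower = 0, upper = 10)
  check_scalar(vas_noise_sd, "vas_noise_sd", lower = 0)
  for (v in list(patient_start, healthy_start))
    if (length(v) != 2L || any(v < 0) || any(v > 1))
      stopf("group start probabilities must be length-2 vectors in [0, 1]")
  if (length(effect_slope) == 1L)
    effect_slope <- c(patient = unname(effect_slope),
                      healthy = unname(effect_slope))
  if (!all(c("patient", "healthy") %in% names(effect_slope)))
    stopf("`effect_slope` must be a scalar or named c(patient=, healthy=)")
  structure(list(n_per_group = as.integer(n_per_group),
                 n_sessions = as.integer(n_sessions),
                 patient_start = patient_start, healthy_start = healthy_start,
                 patient_drift = patient_drift, healthy_drift = healthy_drift,
                 resting_secs = as.integer(resting_secs),
                 nfb_secs = as.integer(nfb_secs),
                 emission = emission,
                 baseline_vas = baseline_vas,
                 effect_slope = effect_slope,
                 vas_noise_sd = vas_noise_sd,
                 seed = as.integer(seed)),
            class = "cohort_spec")
}

# Session transition probabilities for one group, drift clipped to [0, 1].
session_markov <- function(start, drift, session) {
  p <- clip(start + drift * (session - 1L), 0, 1)
  markov_params(p[1L], p[2L], initial_state = "stationary")
}

#' Simulate a synthetic neurofeedback cohort
#'
#' Generates, for every participant x session: a resting-state and a
#' neurofeedback (NFB) alpha-state sequence from the group's (drifted) Markov
#' parameters, and pre/post cold-pressor VAS blocks of six ratings each whose
#' session mean follows the planted pain model
#' `baseline_vas - effect_slope * (occupancy_s - occupancy_1) + noise`,
#' clipped to [0, 10]. Raw EEG is not stored (it can be large); synthesize it
#' per record with [synthesize_eeg()] or run [run_pipeline()], which does so
#' on the fly using the per-record seeds retained in `records$eeg_seed`.
#'
#' @param spec A [cohort_spec()] object.
#' @return An object of class `alpha_cohort`: a list with `records` (one row
#'   per participant x session, with true transition probabilities, realized
#'   ground-truth occupancies and seeds), `states` (named list of resting and
#'   NFB state sequences per record), `vas` (long data frame: participant_id,
#'   group, session, block, rating_index, vas) and the echoed `spec`.
#' @export
simulate_cohort <- function(spec) {
  if (!inherits(spec, "cohort_spec")) stopf("`spec` must be a cohort_spec")
  groups <- c("patient", "healthy")
  records <- NULL
  states <- list()
  vas <- NULL
  rec <- 0L
  for (g in groups) {
    start <- if (g == "patient") spec$patient_start else spec$healthy_start
    drift <- if (g == "patient") spec$patient_drift else spec$healthy_drift
    for (i in seq_len(spec$n_per_group)) {
      pid <- sprintf("%s%02d", ifelse(g == "patient", "P", "H"), i)
      occ1 <- NA_real_
      for (s in seq_len(spec$n_sessions)) {
        rec <- rec + 1L
        mp <- session_markov(start, drift, s)
        seed_rest <- derive_seed(spec$seed, 4L * rec)
        seed_nfb <- derive_seed(spec$seed, 4L * rec + 1L)
        seed_eeg <- derive_seed(spec$seed, 4L * rec + 2L)
        seed_vas <- derive_seed(spec$seed, 4L * rec + 3L)
        rest <- simulate_state_sequence(mp, spec$resting_secs, seed = seed_rest)
        nfb <- simulate_state_sequence(mp, spec$nfb_secs, seed = seed_nfb)
        occ <- fractional_occupancy(nfb)
        if (s == 1L) occ1 <- occ
        slope <- spec$effect_slope[[g]]
        mu <- spec$baseline_vas - slope * (occ - occ1)
        set.seed(seed_vas)
        ratings <- clip(mu + stats::rnorm(12L, sd = spec$vas_noise_sd), 0, 10)
        key <- sprintf("%s_s%d", pid, s)
        states[[key]] <- list(resting = rest, nfb = nfb)
        records <- rbind(records, data.frame(
          participant_id = pid, group = g, session = s,
          p_low_to_high_true = mp$p_low_to_high,
          p_high_to_low_true = mp$p_high_to_low,
          occupancy_true = occ,
          eeg_seed = seed_eeg,
          stringsAsFactors = FALSE))
        vas <- rbind(vas, data.frame(
          participant_id = pid, group = g, session = s,
          block = rep(c("pre", "post"), each = 6L),
          rating_index = rep(1:6, 2L),
          vas = ratings,
          stringsAsFactors = FALSE))
      }
    }
  }
  structure(list(records = records, states = states, vas = vas, spec = spec),
            class = "alpha_cohort")
}

#' @export
print.alpha_cohort <- function(x, ...) {
  cat(sprintf("Synthetic alpha-NFB cohort: %d participants x %d sessions (%d records)\n",
              2L * x$spec$n_per_group, x$spec$n_sessions, nrow(x$records)))
  invisible(x)
}
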