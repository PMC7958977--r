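test_that("state-sequence simulation respects degenerate transition regimes", {
  # absorbing low state
  s <- simulate_state_sequence(markov_params(0, 0.3, initial_state = "low"),
                               100, seed = 1)
  expect_identical(s$symbols, rep(0L, 100))
  # forced alternation
  s <- simulate_state_sequence(markov_params(1, 1, initial_state = "low"),
                               4, seed = 1)
  expect_identical(s$symbols, c(0L, 1L, 0L, 1L))
  # reproducibility
  a <- simulate_state_sequence(markov_params(0.4, 0.3), 500, seed = 9)
  b <- simulate_state_sequence(markov_params(0.4, 0.3), 500, seed = 9)
  expect_identical(a$symbols, b$symbols)
})

test_that("invalid Markov parameters are rejected", {
  expect_error(markov_params(-0.1, 0.5), "probability")
  expect_error(markov_params(0.5, 1.2), "probability")
  expect_error(markov_params(0, 0, initial_state = "stationary"), "stationary")
})

test_that("empirical transition frequencies and occupancy converge to the generator", {
  p_lh <- 0.53; p_hl <- 0.25
  n <- 2000
  n_runs <- 40
  ok_lh <- ok_hl <- ok_occ <- 0L
  pi_high <- p_lh / (p_lh + p_hl)
  for (r in seq_len(n_runs)) {
    s <- simulate_state_sequence(markov_params(p_lh, p_hl), n, seed = 100 + r)
    counts <- oracle_pair_counts(s$symbols)
    n_low <- sum(counts[1L, ]); n_high <- sum(counts[2L, ])
    est_lh <- counts[1L, 2L] / n_low
    est_hl <- counts[2L, 1L] / n_high
    if (abs(est_lh - p_lh) <= 3 * sqrt(p_lh * (1 - p_lh) / n_low)) ok_lh <- ok_lh + 1L
    if (abs(est_hl - p_hl) <= 3 * sqrt(p_hl * (1 - p_hl) / n_high)) ok_hl <- ok_hl + 1L
    # occupancy SE inflated by chain autocorrelation lambda = 1 - p_lh - p_hl
    lam <- 1 - p_lh - p_hl
    se_occ <- sqrt(pi_high * (1 - pi_high) / n * (1 + lam) / (1 - lam))
    if (abs(fractional_occupancy(s) - pi_high) <= 3 * se_occ) ok_occ <- ok_occ + 1L
  }
  expect_gte(ok_lh / n_runs, 0.95)
  expect_gte(ok_hl / n_runs, 0.95)
  expect_gte(ok_occ / n_runs, 0.95)
})

test_that("synthesized EEG is deterministic, epoch-exact, and state amplitudes separate", {
  st <- simulate_state_sequence(markov_params(0.5, 0.3), 20, seed = 2)
  em <- emission_params(sampling_rate = 250)
  a <- synthesize_eeg(st, em, seed = 5)
  b <- synthesize_eeg(st, em, seed = 5)
  expect_identical(a$samples, b$samples)
  expect_identical(nrow(a$samples), 20L * 250L)
  expect_identical(a$channel_labels, c("AF3", "AF4"))

  # noiseless two-amplitude emission: epoch power ratio = (amp ratio)^2
  st2 <- as_state_sequence(c(0L, 1L))
  quiet <- emission_params(amp_high = 20, amp_low = 5, pink_noise_sd = 0,
                           white_noise_sd = 0, sampling_rate = 250)
  raw <- synthesize_eeg(st2, quiet)
  ep <- segment_epochs(raw)
  ps <- alpha_power(ep)
  expect_equal(ps$values[2L] / ps$values[1L], 16, tolerance = 1e-6)

  # degenerate emission: equal amplitudes -> equal power, states inseparable
  flat <- emission_params(amp_high = 10, amp_low = 10, pink_noise_sd = 0,
                          white_noise_sd = 0, sampling_rate = 250)
  psf <- alpha_power(segment_epochs(synthesize_eeg(st2, flat)))
  expect_equal(psf$values[1L], psf$values[2L], tolerance = 1e-9)
})

test_that("emission invariants are enforced", {
  expect_error(emission_params(amp_high = 1, amp_low = 5), "amp_high")
  expect_error(emission_params(alpha_freq = 10, sampling_rate = 15), "Nyquist")
})

test_that("cohort generator produces the study layout with bounded VAS", {
  spec <- cohort_spec(n_per_group = 4, n_sessions = 5, resting_secs = 10,
                      nfb_secs = 30, seed = 3)
  coh <- simulate_cohort(spec)
  expect_identical(nrow(coh$records), 40L)  # 4 x 5 x 2 groups
  expect_identical(nrow(coh$vas), 40L * 12L)
  expect_true(all(coh$vas$vas >= 0 & coh$vas$vas <= 10))
  # exactly six ratings per block
  n_block <- with(coh$vas, table(paste(participant_id, session, block)))
  expect_true(all(n_block == 6L))
})

test_that("planted pain effect has the expected sign; no effect gives near-zero correlation", {
  # with a planted slope and low noise, occupancy and pain change correlate
  # negatively in patients (sign recovery over seeded replicates)
  neg <- 0L
  n_rep <- 20L
  for (r in seq_len(n_rep)) {
    coh <- simulate_cohort(cohort_spec(n_per_group = 4, n_sessions = 5,
                                       resting_secs = 10, nfb_secs = 300,
                                       vas_noise_sd = 0.2, seed = 500 + r))
    pc <- pain_change(coh$vas)
    d <- merge(coh$records, pc, by = c("participant_id", "session"))
    d <- d[d$group == "patient", ]
    if (stats::cor(d$occupancy_true, d$pain_change) < 0) neg <- neg + 1L
  }
  expect_gte(neg / n_rep, 0.95)

  # zero slope everywhere: correlations scatter around zero
  rs <- vapply(1:20, function(r) {
    coh <- simulate_cohort(cohort_spec(n_per_group = 4, n_sessions = 5,
                                       resting_secs = 10, nfb_secs = 300,
                                       effect_slope = 0, seed = 900 + r))
    pc <- pain_change(coh$vas)
    d <- merge(coh$records, pc, by = c("participant_id", "session"))
    stats::cor(d$occupancy_true[d$group == "patient"],
               d$pain_change[d$group == "patient"])
  }, numeric(1L))
  expect_lt(abs(mean(rs)), 0.25)
})
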