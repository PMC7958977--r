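test_that("transition estimation matches hand counts", {
  tm <- estimate_transitions(c(0, 0, 1, 1))
  expect_identical(unname(tm$counts),
                   matrix(c(1L, 0L, 1L, 1L), 2L))
  expect_equal(unname(tm$probabilities),
               matrix(c(0.5, 0, 0.5, 1), 2L))
  expect_identical(tm$n_transitions, 3L)
})

test_that("a never-visited origin state yields an undefined row", {
  expect_warning(tm <- estimate_transitions(rep(0, 10)), "high")
  expect_equal(unname(tm$probabilities[1L, ]), c(1, 0))
  expect_true(all(is.nan(tm$probabilities[2L, ])))
  expect_error(estimate_transitions(rep(0, 10), strict = TRUE), "high")
})

test_that("estimation equals brute-force pair counting on all short sequences", {
  for (len in 2:12) {
    seqs <- all_binary_sequences(len)
    for (i in seq_len(nrow(seqs))) {
      symbols <- as.integer(seqs[i, ])
      tm <- suppressWarnings(estimate_transitions(symbols))
      counts <- oracle_pair_counts(symbols)
      expect_identical(unname(tm$counts), counts)
      expected_probs <- counts / rowSums(counts)  # 0/0 -> NaN, as returned
      expect_equal(unname(tm$probabilities), expected_probs)
    }
  }
})

test_that("count-based MLE equals identity-emission HMM estimation", {
  set.seed(29)
  for (r in 1:20) {
    s <- simulate_state_sequence(markov_params(stats::runif(1, 0.1, 0.9),
                                               stats::runif(1, 0.1, 0.9)),
                                 sample(20:200, 1L), seed = 300 + r)
    if (length(unique(s$symbols)) < 2L) next
    tm <- suppressWarnings(estimate_transitions(s))
    em <- oracle_identity_hmm(s$symbols)
    defined <- is.finite(tm$probabilities)
    expect_equal(unname(tm$probabilities[defined]), unname(em[defined]),
                 tolerance = 1e-10)
  }
})

test_that("long simulations recover the generating probabilities within 3 SE", {
  s <- simulate_state_sequence(markov_params(0.53, 0.25), 1e5, seed = 31)
  tm <- estimate_transitions(s)
  n_low <- sum(tm$counts[1L, ]); n_high <- sum(tm$counts[2L, ])
  expect_lt(abs(tm$probabilities[1L, 2L] - 0.53),
            3 * sqrt(0.53 * 0.47 / n_low))
  expect_lt(abs(tm$probabilities[2L, 1L] - 0.25),
            3 * sqrt(0.25 * 0.75 / n_high))
})

test_that("estimation error shrinks as 1/sqrt(n)", {
  err_at <- function(n) {
    mean(vapply(1:10, function(r) {
      s <- simulate_state_sequence(markov_params(0.53, 0.25), n,
                                   seed = 1000 * log10(n) + r)
      abs(estimate_transitions(s)$probabilities[1L, 2L] - 0.53)
    }, numeric(1L)))
  }
  e <- vapply(c(1e3, 1e4, 1e5), err_at, numeric(1L))
  expect_true(all(diff(e) < 0))
  # expected ratio across two decades is 10; allow wide stochastic slack
  expect_gt(e[1L] / e[3L], 3)
})

test_that("stationary distribution has the closed form and satisfies pi T = pi", {
  pi1 <- stationary_distribution(matrix(c(0.47, 0.53, 0.25, 0.75), 2L,
                                        byrow = TRUE))
  expect_equal(round(unname(pi1["high"]), 2), 0.68)
  expect_equal(unname(stationary_distribution(
    matrix(c(0.5, 0.5, 0.5, 0.5), 2L))["high"]), 0.5)
  expect_error(stationary_distribution(diag(2L)), "stationary")

  # 100 random valid matrices against the left-eigenvector oracle
  set.seed(37)
  for (r in 1:100) {
    p_lh <- stats::runif(1, 0.01, 0.99)
    p_hl <- stats::runif(1, 0.01, 0.99)
    P <- matrix(c(1 - p_lh, p_lh, p_hl, 1 - p_hl), 2L, byrow = TRUE)
    pi_hat <- stationary_distribution(P)
    ev <- eigen(t(P))
    lead <- which.min(abs(ev$values - 1))
    pi_eig <- Re(ev$vectors[, lead]); pi_eig <- pi_eig / sum(pi_eig)
    expect_equal(unname(pi_hat), pi_eig, tolerance = 1e-10)
    expect_equal(as.numeric(pi_hat %*% P), unname(pi_hat), tolerance = 1e-12)
  }
})

test_that("empirical occupancy agrees with the stationary point of the estimate", {
  for (r in 1:5) {
    s <- simulate_state_sequence(markov_params(0.4, 0.2), 5000, seed = 40 + r)
    tm <- estimate_transitions(s)
    pi_hat <- stationary_distribution(tm)
    occ <- fractional_occupancy(s)
    lam <- 1 - 0.4 - 0.2
    se <- sqrt(occ * (1 - occ) / s$n * (1 + lam) / (1 - lam))
    expect_lt(abs(occ - pi_hat["high"]), 3 * se + 1e-3)
  }
})
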