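# Independent brute-force oracles. Each deliberately avoids the code path it
# checks: loops instead of rle/table, textbook formulas instead of stats::
# shortcuts.

# Run-length counting by explicit iteration.
oracle_runs <- function(symbols) {
  lengths <- integer(0)
  values <- integer(0)
  cur <- symbols[1L]
  len <- 1L
  for (s in symbols[-1L]) {
    if (s == cur) len <- len + 1L
    else {
      lengths <- c(lengths, len); values <- c(values, cur)
      cur <- s; len <- 1L
    }
  }
  lengths <- c(lengths, len); values <- c(values, cur)
  list(lengths = lengths, values = values,
       high = lengths[values == 1L], low = lengths[values == 0L])
}

# Transition pair counts by explicit double indexing.
oracle_pair_counts <- function(symbols) {
  counts <- matrix(0L, 2L, 2L)
  for (i in seq_len(length(symbols) - 1L))
    counts[symbols[i] + 1L, symbols[i + 1L] + 1L] <-
      counts[symbols[i] + 1L, symbols[i + 1L] + 1L] + 1L
  counts
}

# Linear-interpolation quantile from the definition: h = (n-1)p + 1 on the
# sorted sample.
oracle_quantile <- function(x, p) {
  x <- sort(x)
  n <- length(x)
  h <- (n - 1) * p + 1
  lo <- floor(h)
  hi <- ceiling(h)
  x[lo] + (h - lo) * (x[hi] - x[lo])
}

# One EM (Baum-Welch) update of a 2-state HMM with identity emission. With
# the emission matrix fixed to the identity, the forward/backward masses
# collapse onto the observed symbols and a single M-step yields the
# transition MLE whatever the starting matrix.
oracle_identity_hmm <- function(symbols, A0 = matrix(0.5, 2L, 2L)) {
  n <- length(symbols)
  o <- symbols + 1L
  B <- diag(2L)
  init <- c(0.5, 0.5)
  alpha <- matrix(0, n, 2L)
  alpha[1L, ] <- init * B[, o[1L]]
  alpha[1L, ] <- alpha[1L, ] / sum(alpha[1L, ])
  for (t in 2:n) {
    a <- (alpha[t - 1L, ] %*% A0) * B[, o[t]]
    alpha[t, ] <- a / sum(a)
  }
  beta <- matrix(0, n, 2L)
  beta[n, ] <- 1
  for (t in (n - 1L):1L) {
    b <- A0 %*% (B[, o[t + 1L]] * beta[t + 1L, ])
    beta[t, ] <- b / sum(b)
  }
  xi_sum <- matrix(0, 2L, 2L)
  for (t in seq_len(n - 1L)) {
    xi <- outer(alpha[t, ], B[, o[t + 1L]] * beta[t + 1L, ]) * A0
    xi_sum <- xi_sum + xi / sum(xi)
  }
  xi_sum / rowSums(xi_sum)
}

# Tie-corrected Friedman statistic from the textbook formula
# chi2 = (k-1) * sum_j (R_j - n(k+1)/2)^2 / (A - C),
# A = sum of squared ranks, C = n k (k+1)^2 / 4.
oracle_friedman_stat <- function(mat) {
  n <- nrow(mat); k <- ncol(mat)
  r <- t(apply(mat, 1L, rank))
  Rj <- colSums(r)
  A <- sum(r^2)
  C <- n * k * (k + 1)^2 / 4
  (k - 1) * sum((Rj - n * (k + 1) / 2)^2) / (A - C)
}

# Monte-Carlo permutation p-value of the Friedman statistic (independent
# permutations of each participant's session order).
oracle_friedman_mc_p <- function(mat, n_perm = 2e4, seed = 1) {
  set.seed(seed)
  obs <- oracle_friedman_stat(mat)
  k <- ncol(mat)
  hits <- 0L
  for (b in seq_len(n_perm)) {
    perm <- t(apply(mat, 1L, function(row) row[sample.int(k)]))
    if (oracle_friedman_stat(perm) >= obs - 1e-12) hits <- hits + 1L
  }
  hits / n_perm
}

# Sample a discrete power law p(x) ~ x^(-alpha), x >= xmin, by the
# continuous-approximation inverse CDF with rounding.
sample_discrete_powerlaw <- function(n, alpha, xmin = 1) {
  u <- stats::runif(n)
  floor((xmin - 0.5) * (1 - u)^(-1 / (alpha - 1)) + 0.5)
}

# All binary sequences of a given length, as rows.
all_binary_sequences <- function(len) {
  m <- as.matrix(expand.grid(rep(list(0:1), len)))
  dimnames(m) <- NULL
  m
}

# Two-channel sinusoid raw_eeg fixture.
make_sine_eeg <- function(freq, amp, secs, fs, labels = c("AF3", "AF4")) {
  t <- (seq_len(secs * fs) - 1L) / fs
  x <- amp * sin(2 * pi * freq * t)
  raw_eeg(matrix(rep(x, length(labels)), ncol = length(labels)),
          sampling_rate = fs, channel_labels = labels)
}
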