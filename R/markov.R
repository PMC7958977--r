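# Two-state Markov chain estimation from an observed state sequence.
#
# With the emission probabilities forced to the identity matrix, the hidden
# state sequence of an HMM is fully observed, so the maximum-likelihood
# transition estimate reduces to exact counting of consecutive symbol pairs
# followed by row normalization (the test suite asserts equivalence to an
# identity-emission EM estimator).

#' Estimate the transition matrix of a state sequence
#'
#' Counts consecutive symbol pairs and row-normalizes; this is the
#' maximum-likelihood estimate of the two-state transition matrix. A state
#' that is never the origin of a transition has an undefined row, returned
#' as `NaN` with a warning (or an error in strict mode). Optional additive
#' (Laplace) smoothing is off by default, matching the convention of
#' reporting extreme rows unsmoothed.
#'
#' @param seq A `state_sequence` or 0/1 vector of length >= 2.
#' @param smoothing Non-negative pseudo-count added to every cell before
#'   normalization (default 0).
#' @param strict Error (instead of warn) on an undefined row.
#' @return An object of class `transition_matrix`: `probabilities` (2x2,
#'   rows = from low/high, columns = to low/high), `counts` (2x2 integer),
#'   `n_transitions`.
#' @examples
#' estimate_transitions(c(0, 0, 1, 1))$probabilities
#' @export
estimate_transitions <- function(seq, smoothing = 0, strict = FALSE) {
  seq <- as_state_sequence(seq)
  if (seq$n < 2L) stopf("need at least 2 epochs to estimate transitions")
  check_scalar(smoothing, "smoothing", lower = 0)
  from <- factor(seq$symbols[-seq$n], levels = c(0L, 1L))
  to <- factor(seq$symbols[-1L], levels = c(0L, 1L))
  counts <- unclass(table(from, to))
  dimnames(counts) <- list(from = c("low", "high"), to = c("low", "high"))
  num <- counts + smoothing
  row_tot <- rowSums(num)
  probs <- num / ifelse(row_tot > 0, row_tot, NA_real_)
  undefined <- row_tot == 0
  if (any(undefined)) {
    msg <- sprintf("state(s) %s never visited as transition origin; row undefined",
                   paste(rownames(counts)[undefined], collapse = ", "))
    if (strict) stopf("%s", msg) else warnf("%s", msg)
    probs[undefined, ] <- NaN
  }
  structure(list(probabilities = probs, counts = counts,
                 n_transitions = seq$n - 1L),
            class = "transition_matrix")
}

#' @export
print.transition_matrix <- function(x, ...) {
  cat(sprintf("transition_matrix (%d transitions):\n", x$n_transitions))
  print(round(x$probabilities, 4))
  invisible(x)
}

#' Stationary distribution of a two-state chain
#'
#' Closed form for the two-state chain: `pi_high = p_LH / (p_LH + p_HL)`,
#' satisfying `pi %*% P = pi`. Requires both rows defined and at least one
#' off-diagonal probability positive.
#'
#' @param x A `transition_matrix` or a 2x2 row-stochastic matrix.
#' @return Named vector `c(low = , high = )`.
#' @examples
#' stationary_distribution(matrix(c(0.47, 0.53, 0.25, 0.75), 2, byrow = TRUE))
#' @export
stationary_distribution <- function(x) {
  P <- if (inherits(x, "transition_matrix")) x$probabilities else as.matrix(x)
  if (!all(dim(P) == c(2L, 2L))) stopf("expected a 2x2 transition matrix")
  if (anyNA(P)) stopf("transition matrix has undefined rows")
  if (any(abs(rowSums(P) - 1) > 1e-9)) stopf("rows must sum to 1")
  p_lh <- P[1L, 2L]
  p_hl <- P[2L, 1L]
  if (p_lh + p_hl <= 0)
    stopf("no unique stationary distribution: both off-diagonal probabilities are 0")
  pi_high <- p_lh / (p_lh + p_hl)
  c(low = 1 - pi_high, high = pi_high)
}
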