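test_that("normalized mean alpha is a within-participant z-score of log session means", {
  # identical sessions: zero variance -> all zeros with a warning
  expect_warning(z0 <- normalized_mean_alpha(list(c(1, 2, 3), c(1, 2, 3))),
                 "zero variance")
  expect_identical(z0, c(0, 0))
  # strictly increasing session means -> strictly increasing scores
  z <- normalized_mean_alpha(list(c(1, 1), c(2, 2), c(5, 5), c(9, 9)))
  expect_true(all(diff(z) > 0))
  # independent two-step oracle: log -> mean -> standardize
  set.seed(43)
  sessions <- lapply(1:5, function(i) stats::rlnorm(50, meanlog = i / 5))
  z2 <- normalized_mean_alpha(sessions)
  m <- sapply(sessions, function(v) sum(log(v)) / length(v))
  oracle <- (m - sum(m) / 5) / sqrt(sum((m - sum(m) / 5)^2) / 4)
  expect_equal(z2, oracle, tolerance = 1e-12)
  expect_equal(mean(z2), 0, tolerance = 1e-12)
  expect_equal(stats::sd(z2), 1, tolerance = 1e-12)
})

make_vas <- function(means_by_session, pid = "P01") {
  do.call(rbind, lapply(seq_along(means_by_session), function(s)
    data.frame(participant_id = pid, session = s,
               block = rep(c("pre", "post"), each = 6L),
               rating_index = rep(1:6, 2L),
               vas = rep(means_by_session[[s]], 2L))))
}

test_that("pain change is the block mean minus the session-1 pre baseline", {
  vas <- make_vas(list(rep(7, 6), rep(5, 6)))
  pc <- pain_change(vas)
  expect_equal(pc$pain_change, c(0, -2))
  # the six-rating mean drives the difference
  vas2 <- make_vas(list(c(8, 8, 7, 7, 6, 6), rep(6, 6)))
  pc2 <- pain_change(vas2)
  expect_equal(pc2$pain_change[1L], 0)        # baseline block vs itself
  expect_equal(pc2$pain_change[2L], 6 - 7.0)  # block mean 7.0 used
  # block contract: five ratings is an error
  bad <- vas[-1L, ]
  expect_error(pain_change(bad), "exactly 6")
})

test_that("Friedman test handles constant data, reports df = sessions - 1", {
  const <- matrix(5, nrow = 4, ncol = 5)
  fr <- friedman_across_sessions(const)
  expect_equal(fr$chi2, 0)
  expect_equal(fr$df, 4L)
  expect_equal(fr$p, 1)
  set.seed(47)
  fr2 <- friedman_across_sessions(matrix(stats::rnorm(20), 4, 5))
  expect_identical(fr2$df, 4L)
  expect_error(friedman_across_sessions(matrix(c(1, NA, 2, 3), 2)), "missing")
})

test_that("Friedman statistic matches the textbook formula and a permutation oracle", {
  set.seed(53)
  mat <- matrix(stats::rnorm(20), 4, 5)
  fr <- friedman_across_sessions(mat)
  expect_equal(fr$chi2, oracle_friedman_stat(mat), tolerance = 1e-12)
  # with average-rank ties
  mat_t <- mat
  mat_t[1, 2] <- mat_t[1, 3]
  fr_t <- friedman_across_sessions(mat_t)
  expect_equal(fr_t$chi2, oracle_friedman_stat(mat_t), tolerance = 1e-12)
  # chi-square p is close to the Monte-Carlo permutation p at this small n
  p_mc <- oracle_friedman_mc_p(mat, n_perm = 2e4, seed = 54)
  expect_lt(abs(fr$p - p_mc), 0.1)
})

test_that("Friedman is invariant to monotone within-participant transformations", {
  set.seed(59)
  mat <- matrix(stats::rlnorm(20), 4, 5)
  f0 <- friedman_across_sessions(mat)$chi2
  expect_equal(friedman_across_sessions(log(mat))$chi2, f0)
  expect_equal(friedman_across_sessions(mat^3)$chi2, f0)
  # row-wise monotone maps (different per participant) also preserve ranks
  mat2 <- mat
  mat2[1, ] <- exp(mat2[1, ]); mat2[2, ] <- 10 * mat2[2, ] + 3
  expect_equal(friedman_across_sessions(mat2)$chi2, f0)
})

test_that("Pearson correlation reproduces exact linear relations and affine invariance", {
  x <- 1:10
  expect_equal(correlate_with_pain(x, -2 * x + 3)$r, -1)
  expect_equal(correlate_with_pain(x, 5 * x - 1)$r, 1)
  set.seed(61)
  a <- stats::rnorm(20); b <- stats::rnorm(20)
  r0 <- correlate_with_pain(a, b)$r
  expect_equal(correlate_with_pain(3 * a - 7, b)$r, r0, tolerance = 1e-12)
  expect_equal(correlate_with_pain(a, -0.5 * b + 2)$r, -r0, tolerance = 1e-12)
  # grouping splits the pairs
  g <- rep(c("patient", "healthy"), each = 10)
  res <- correlate_with_pain(c(x, x), c(-x, x), group = g)
  expect_equal(res$r[res$group == "patient"], -1)
  expect_equal(res$r[res$group == "healthy"], 1)
  expect_identical(res$n, c(10L, 10L))
  # degenerate variance flagged
  expect_warning(res0 <- correlate_with_pain(rep(1, 5), 1:5), "zero variance")
  expect_true(is.na(res0$r))
})
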