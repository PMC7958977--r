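# Behavioral and cohort-level statistics: normalized mean alpha power,
# cold-pressor VAS pain change, Friedman tests across sessions, and Pearson
# correlations between alpha-state parameters and pain change.

#' Normalized log mean alpha power per session
#'
#' The traditional static learning index: per-epoch powers are
#' log-transformed, averaged per session, and z-scored across the
#' participant's sessions, so each participant's five sessions have mean 0
#' and SD 1. Zero variance across sessions yields all-zero scores with a
#' warning.
#'
#' @param sessions A list (one element per session, in session order) of
#'   `power_series` objects or positive numeric vectors of per-epoch power.
#' @return Numeric vector of dimensionless scores, one per session.
#' @export
normalized_mean_alpha <- function(sessions) {
  if (!is.list(sessions) || length(sessions) < 2L)
    stopf("need a list of at least 2 sessions to normalize across")
  m <- vapply(sessions, function(s) {
    v <- if (inherits(s, "power_series")) s$values else as.numeric(s)
    if (any(v <= 0)) stopf("power values must be positive for log transform")
    mean(log(v))
  }, numeric(1L))
  s <- stats::sd(m)
  if (s == 0) {
    warnf("zero variance of session mean log alpha; returning all-zero scores")
    return(rep(0, length(m)))
  }
  (m - mean(m)) / s
}

# Validate a long VAS table and return it; used by pain_change.
check_vas_table <- function(vas) {
  need <- c("participant_id", "session", "block", "vas")
  if (!is.data.frame(vas) || !all(need %in% names(vas)))
    stopf("VAS table must have columns %s", paste(need, collapse = ", "))
  if (any(vas$vas < 0 | vas$vas > 10))
    stopf("VAS ratings must lie in [0, 10]")
  counts <- stats::aggregate(vas$vas,
                             by = list(participant_id = vas$participant_id,
                                       session = vas$session,
                                       block = vas$block),
                             FUN = length)
  if (any(counts$x != 6L))
    stopf("every VAS block must contain exactly 6 ratings (one every 30 s of the 3-min cold-pressor block)")
  vas
}

#' Per-session change in cold-pressor pain ratings
#'
#' Each block's pain level is the mean of its six VAS ratings; the change
#' score of session s is that session's block mean minus the session-1
#' pre-NFB block mean (negative = pain reduction).
#'
#' @param vas Long VAS table with columns `participant_id`, `session`,
#'   `block` (`"pre"`/`"post"`), `vas`; six rows per block.
#' @param block Which block represents the session: `"pre"` (default),
#'   `"post"`, or `"mean"` of both.
#' @return Data frame with `participant_id`, `session`, `pain_change`.
#' @export
pain_change <- function(vas, block = c("pre", "post", "mean")) {
  block <- match.arg(block)
  vas <- check_vas_table(vas)
  block_means <- stats::aggregate(
    vas$vas, by = list(participant_id = vas$participant_id,
                       session = vas$session, block = vas$block),
    FUN = mean)
  names(block_means)[4L] <- "vas_mean"
  out <- NULL
  for (pid in unique(block_means$participant_id)) {
    bm <- block_means[block_means$participant_id == pid, ]
    base <- bm$vas_mean[bm$session == 1L & bm$block == "pre"]
    if (length(base) != 1L)
      stopf("participant %s is missing the session-1 pre-NFB baseline block", pid)
    for (s in sort(unique(bm$session))) {
      v <- switch(block,
        pre = bm$vas_mean[bm$session == s & bm$block == "pre"],
        post = bm$vas_mean[bm$session == s & bm$block == "post"],
        mean = mean(bm$vas_mean[bm$session == s]))
      if (length(v) != 1L)
        stopf("participant %s session %d lacks the requested '%s' block",
              pid, s, block)
      out <- rbind(out, data.frame(participant_id = pid, session = s,
                                   pain_change = v - base,
                                   stringsAsFactors = FALSE))
    }
  }
  out
}

#' Friedman test of a parameter across sessions
#'
#' Nonparametric repeated-measures test on a participants x sessions matrix,
#' via the rank-based chi-square approximation with average-rank tie
#' handling (`stats::friedman.test`). Data that are constant within every
#' participant carry no rank information; that degenerate case returns a
#' statistic of 0 with p = 1.
#'
#' @param mat Numeric matrix, rows = participants, columns = sessions; no
#'   missing cells.
#' @return An object of class `friedman_result`: `chi2`, `df`
#'   (= sessions - 1), `p`.
#' @export
friedman_across_sessions <- function(mat) {
  mat <- as.matrix(mat)
  if (nrow(mat) < 2L || ncol(mat) < 2L)
    stopf("need >= 2 participants and >= 2 sessions")
  if (anyNA(mat)) stopf("missing cells are not allowed")
  k <- ncol(mat)
  ranks <- t(apply(mat, 1L, rank))
  if (all(apply(ranks, 1L, function(r) length(unique(r)) == 1L))) {
    res <- list(chi2 = 0, df = k - 1L, p = 1)
  } else {
    ft <- stats::friedman.test(mat)
    res <- list(chi2 = unname(ft$statistic),
                df = as.integer(unname(ft$parameter)), p = ft$p.value)
  }
  structure(res, class = "friedman_result")
}

#' @export
print.friedman_result <- function(x, ...) {
  cat(sprintf("Friedman chi-square(%d) = %.3f, p = %.3f\n", x$df, x$chi2, x$p))
  invisible(x)
}

#' Pearson correlation between a parameter and pain change
#'
#' Pools all (participant, session) pairs within each group and reports the
#' Pearson correlation with a two-sided p-value; significance is flagged at
#' p < 0.05. Pooling across sessions of the same participant ignores
#' within-participant dependence; it matches the scatter-level analysis the
#' parameter tables feed.
#'
#' @param parameter Numeric vector of parameter values.
#' @param pain Numeric vector of pain-change scores, same length.
#' @param group Optional factor/character of group labels; if supplied, one
#'   correlation per group.
#' @return Data frame with `group`, `r`, `p`, `n`, `significant`.
#' @export
correlate_with_pain <- function(parameter, pain, group = NULL) {
  if (length(parameter) != length(pain))
    stopf("parameter and pain vectors must have equal length")
  if (is.null(group)) group <- rep("all", length(parameter))
  out <- NULL
  for (g in unique(group)) {
    x <- parameter[group == g]
    y <- pain[group == g]
    ok <- is.finite(x) & is.finite(y)
    x <- x[ok]; y <- y[ok]
    if (length(x) < 3L)
      stopf("group '%s' has fewer than 3 complete pairs", g)
    if (stats::sd(x) == 0 || stats::sd(y) == 0) {
      warnf("zero variance in group '%s'; correlation undefined", g)
      row <- data.frame(group = g, r = NA_real_, p = NA_real_,
                        n = length(x), significant = NA)
    } else {
      ct <- stats::cor.test(x, y, method = "pearson")
      row <- data.frame(group = g, r = unname(ct$estimate), p = ct$p.value,
                        n = length(x), significant = ct$p.value < 0.05)
    }
    out <- rbind(out, row)
  }
  out
}
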