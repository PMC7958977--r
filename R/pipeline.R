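# End-to-end orchestration: synthetic cohort (or EEG files on disk) ->
# per-epoch alpha power -> individualized thresholds -> state sequences ->
# alpha-state parameters -> tidy cohort table and group statistics.

# raw EEG -> power series, per the offline analysis chain.
preprocess_record <- function(raw, config) {
  raw <- downsample_eeg(raw, target_rate = config$target_rate)
  ep <- segment_epochs(raw, epoch_duration = config$epoch_duration)
  n_total <- ep$n_epochs
  ep <- reject_artifact_epochs(ep, amplitude_criterion = config$artifact_criterion)
  ps <- alpha_power(ep, band = config$band, channels = config$channels)
  list(power = ps, n_epochs = n_total, n_rejected = sum(ep$rejected_mask))
}

# Alpha-state parameters of one power series at one threshold.
state_parameters <- function(power, thr, config) {
  states <- symbolize(power, thr)
  occ <- fractional_occupancy(states)
  dw <- extract_dwells(states, censor_boundary = config$censor_boundary_dwells)
  ds <- if (length(dw$high_dwells) > 0L)
    dwell_stats(dw$high_dwells, tail_method = config$tail_method)
  else
    list(mean = NA_real_, median = NA_real_, mode = NA_real_,
         variance_pct = NA_real_, tail_weight = NA_real_)
  tm <- suppressWarnings(estimate_transitions(states))
  P <- tm$probabilities
  list(states = states, dwells = dw,
       row = data.frame(
         threshold_pct = thr$percent, occupancy = occ,
         dwell_mean = ds$mean, dwell_median = ds$median,
         dwell_mode = ds$mode, dwell_variance_pct = ds$variance_pct,
         dwell_tail_weight = ds$tail_weight,
         p_low_low = P[1L, 1L], p_low_high = P[1L, 2L],
         p_high_high = P[2L, 2L], p_high_low = P[2L, 1L]))
}

# Named list: participant -> list of per-session raw_eeg accessors.
# Synthetic mode synthesizes EEG on demand from the cohort's state
# sequences and per-record seeds; files mode reads from the manifest.
record_sources <- function(config) {
  if (config$mode == "synthetic") {
    cohort_args <- config$cohort
    if (is.null(cohort_args$seed)) cohort_args$seed <- config$seed
    spec <- do.call(cohort_spec, cohort_args)
    cohort <- simulate_cohort(spec)
    recs <- cohort$records
    get_raw <- function(rec, which) {
      key <- sprintf("%s_s%d", rec$participant_id, rec$session)
      seed <- if (which == "nfb") rec$eeg_seed else derive_seed(rec$eeg_seed, 1L)
      synthesize_eeg(cohort$states[[key]][[which]],
                     emission = spec$emission, seed = seed)
    }
    list(records = recs, vas = cohort$vas, get_raw = get_raw, cohort = cohort)
  } else {
    manifest_path <- file.path(config$input_dir, "manifest.csv")
    vas_path <- file.path(config$input_dir, "vas.csv")
    if (!file.exists(manifest_path)) stopf("missing %s", manifest_path)
    if (!file.exists(vas_path)) stopf("missing %s", vas_path)
    recs <- utils::read.csv(manifest_path, stringsAsFactors = FALSE)
    need <- c("participant_id", "group", "session", "resting_path", "nfb_path")
    if (!all(need %in% names(recs)))
      stopf("manifest.csv must have columns %s", paste(need, collapse = ", "))
    vas <- utils::read.csv(vas_path, stringsAsFactors = FALSE)
    get_raw <- function(rec, which) {
      path <- if (which == "nfb") rec$nfb_path else rec$resting_path
      read_eeg(file.path(config$input_dir, path), channels = config$channels)
    }
    list(records = recs, vas = vas, get_raw = get_raw, cohort = NULL)
  }
}

#' Run the full alpha-state analysis pipeline
#'
#' Orchestrates the offline analysis end to end. In synthetic mode a cohort
#' is simulated from `config$cohort` (see [cohort_spec()]); in files mode
#' EEG is read from `input_dir/manifest.csv` and VAS ratings from
#' `input_dir/vas.csv`. For every participant, the session-1 resting
#' recording sets the individualized thresholds (one per configured
#' percentage); every session's NFB recording is then preprocessed,
#' symbolized at each threshold, and summarized as fractional occupancy,
#' high-state dwell statistics and the 2x2 transition probabilities, next
#' to the normalized log mean alpha power and the session's pain change.
#' Group-level Friedman tests and pain correlations are computed per
#' parameter and threshold. Deterministic given `config$seed`.
#'
#' @param config An [analysis_config()] object.
#' @return An object of class `alpha_pipeline_result`: `cohort_table` (one
#'   row per participant x session x threshold), `stats` (one row per group
#'   x threshold x parameter), `dwells` (long dwell table at the first
#'   configured threshold), `thresholds` (per participant), `log` (stage
#'   counts and the config echo). If `config$output_dir` is set, the tables
#'   are also written there as CSV plus a YAML log.
#' @export
run_pipeline <- function(config) {
  if (!inherits(config, "analysis_config"))
    stopf("`config` must be an analysis_config")
  src <- record_sources(config)
  recs <- src$records
  participants <- unique(recs$participant_id)
  cohort_table <- NULL
  dwell_rows <- NULL
  threshold_log <- NULL
  stage_log <- NULL
  for (pid in participants) {
    prec <- recs[recs$participant_id == pid, ]
    prec <- prec[order(prec$session), ]
    s1 <- prec[prec$session == min(prec$session), ][1L, ]
    resting <- preprocess_record(src$get_raw(s1, "resting"), config)
    maxp <- max_alpha_power(resting$power, method = config$max_power_method)
    thrs <- lapply(config$thresholds, function(pc)
      alpha_threshold(maxp, percent = pc,
                      source = sprintf("%s_s%d_resting", pid, s1$session)))
    threshold_log <- rbind(threshold_log, data.frame(
      participant_id = pid, max_power = maxp,
      percent = config$thresholds,
      threshold = vapply(thrs, `[[`, numeric(1L), "threshold"),
      stringsAsFactors = FALSE))
    session_powers <- list()
    session_rows <- list()
    for (i in seq_len(nrow(prec))) {
      rec <- prec[i, ]
      nfb <- preprocess_record(src$get_raw(rec, "nfb"), config)
      session_powers[[i]] <- nfb$power
      stage_log <- rbind(stage_log, data.frame(
        participant_id = pid, session = rec$session,
        epochs_total = nfb$n_epochs, epochs_rejected = nfb$n_rejected,
        stringsAsFactors = FALSE))
      rows <- NULL
      for (k in seq_along(thrs)) {
        sp <- state_parameters(nfb$power, thrs[[k]], config)
        rows <- rbind(rows, sp$row)
        if (k == 1L)
          dwell_rows <- rbind(dwell_rows,
                              dwell_table(sp$dwells, participant_id = pid,
                                          session = rec$session))
      }
      rows$participant_id <- rec$participant_id
      rows$group <- rec$group
      rows$session <- rec$session
      session_rows[[i]] <- rows
    }
    mean_alpha <- normalized_mean_alpha(session_powers)
    for (i in seq_along(session_rows))
      session_rows[[i]]$mean_alpha <- mean_alpha[i]
    cohort_table <- rbind(cohort_table, do.call(rbind, session_rows))
  }
  pain <- pain_change(src$vas, block = config$pain_block)
  cohort_table <- merge(cohort_table, pain,
                        by = c("participant_id", "session"), sort = FALSE)
  col_order <- c("participant_id", "group", "session", "threshold_pct",
                 "mean_alpha", "occupancy", "dwell_mean", "dwell_median",
                 "dwell_mode", "dwell_variance_pct", "dwell_tail_weight",
                 "p_low_low", "p_low_high", "p_high_high", "p_high_low",
                 "pain_change")
  cohort_table <- cohort_table[order(match(cohort_table$group, c("patient", "healthy")),
                                     cohort_table$participant_id,
                                     cohort_table$session,
                                     cohort_table$threshold_pct),
                               col_order]
  rownames(cohort_table) <- NULL
  stats <- cohort_statistics(cohort_table)
  result <- structure(list(cohort_table = cohort_table, stats = stats,
                           dwells = dwell_rows, thresholds = threshold_log,
                           log = list(stages = stage_log,
                                      config = yaml::as.yaml(unclass(config)))),
                      class = "alpha_pipeline_result")
  if (!is.null(config$output_dir)) {
    dir.create(config$output_dir, recursive = TRUE, showWarnings = FALSE)
    utils::write.csv(cohort_table,
                     file.path(config$output_dir, "cohort_table.csv"),
                     row.names = FALSE)
    utils::write.csv(stats, file.path(config$output_dir, "stats.csv"),
                     row.names = FALSE)
    utils::write.csv(dwell_rows, file.path(config$output_dir, "dwells.csv"),
                     row.names = FALSE)
    writeLines(result$log$config, file.path(config$output_dir, "config.yaml"))
  }
  result
}

#' Group-level statistics of a cohort table
#'
#' For every group x threshold x parameter (normalized mean alpha,
#' fractional occupancy, mean high-state dwell time, low-to-high transition
#' probability): a Friedman test of the parameter across sessions
#' (participants x sessions matrix) and the Pearson correlation between the
#' pooled (participant, session) parameter values and pain change.
#'
#' @param cohort_table A cohort table as produced by [run_pipeline()].
#' @return Data frame with one row per group x threshold x parameter.
#' @export
cohort_statistics <- function(cohort_table) {
  params <- c(mean_alpha = "mean_alpha", occupancy = "occupancy",
              dwell_mean = "dwell_mean", p_low_high = "p_low_high")
  out <- NULL
  for (g in unique(cohort_table$group)) {
    for (thr in sort(unique(cohort_table$threshold_pct))) {
      sub <- cohort_table[cohort_table$group == g &
                          cohort_table$threshold_pct == thr, ]
      for (pn in names(params)) {
        wide <- stats::reshape(
          sub[, c("participant_id", "session", pn)],
          idvar = "participant_id", timevar = "session", direction = "wide")
        mat <- as.matrix(wide[, -1L, drop = FALSE])
        fr <- tryCatch(friedman_across_sessions(mat),
                       error = function(e) list(chi2 = NA_real_,
                                                df = NA_integer_, p = NA_real_))
        ct <- tryCatch(
          suppressWarnings(correlate_with_pain(sub[[pn]], sub$pain_change)),
          error = function(e) data.frame(r = NA_real_, p = NA_real_,
                                         n = sum(is.finite(sub[[pn]]))))
        out <- rbind(out, data.frame(
          group = g, threshold_pct = thr, parameter = pn,
          friedman_chi2 = fr$chi2, friedman_df = fr$df, friedman_p = fr$p,
          pearson_r = ct$r[1L], pearson_p = ct$p[1L], n_pairs = ct$n[1L],
          stringsAsFactors = FALSE))
      }
    }
  }
  rownames(out) <- NULL
  out
}

#' Write a synthetic cohort to disk as an analyzable dataset
#'
#' Synthesizes and writes the EEG of every record (resting and NFB) as
#' delimited text, plus `manifest.csv`, `vas.csv` and a
#' `ground_truth.csv` sidecar with the generating parameters, laid out so
#' that [run_pipeline()] in files mode (with `input_dir = dir`) can consume
#' it directly.
#'
#' @param cohort An `alpha_cohort` from [simulate_cohort()].
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  if (!inherits(cohort, "alpha_cohort")) stopf("`cohort` must be an alpha_cohort")
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  recs <- cohort$records
  manifest <- NULL
  for (i in seq_len(nrow(recs))) {
    rec <- recs[i, ]
    key <- sprintf("%s_s%d", rec$participant_id, rec$session)
    st <- cohort$states[[key]]
    rest_path <- sprintf("%s_resting.tsv", key)
    nfb_path <- sprintf("%s_nfb.tsv", key)
    write_eeg(synthesize_eeg(st$resting, emission = cohort$spec$emission,
                             seed = derive_seed(rec$eeg_seed, 1L)),
              file.path(dir, rest_path), digits = 8)
    write_eeg(synthesize_eeg(st$nfb, emission = cohort$spec$emission,
                             seed = rec$eeg_seed),
              file.path(dir, nfb_path), digits = 8)
    manifest <- rbind(manifest, data.frame(
      participant_id = rec$participant_id, group = rec$group,
      session = rec$session, resting_path = rest_path, nfb_path = nfb_path,
      stringsAsFactors = FALSE))
  }
  utils::write.csv(manifest, file.path(dir, "manifest.csv"), row.names = FALSE)
  utils::write.csv(cohort$vas, file.path(dir, "vas.csv"), row.names = FALSE)
  truth <- recs[, setdiff(names(recs), "eeg_seed")]
  utils::write.csv(truth, file.path(dir, "ground_truth.csv"), row.names = FALSE)
  invisible(dir)
}
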