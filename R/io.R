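# File I/O and analysis configuration.
#
# EEG travels as a delimited-text matrix (tab-separated, one column per
# channel, header row of labels) with a YAML sidecar `<path>.meta.yaml`
# holding the sampling rate and channel labels — a zero-dependency text
# format that round-trips exactly at the written precision.

#' Write EEG to delimited text with a YAML sidecar
#'
#' @param raw A [raw_eeg()] object.
#' @param path Output path for the sample matrix; the sidecar is written to
#'   `<path>.meta.yaml`.
#' @param digits Significant digits written (default 15, near double
#'   precision).
#' @return `path`, invisibly.
#' @export
write_eeg <- function(raw, path, digits = 15) {
  if (!inherits(raw, "raw_eeg")) stopf("`raw` must be a raw_eeg object")
  m <- signif(raw$samples, digits)
  utils::write.table(m, path, sep = "\t", row.names = FALSE,
                     col.names = raw$channel_labels, quote = FALSE)
  yaml::write_yaml(list(sampling_rate = raw$sampling_rate,
                        channel_labels = as.list(raw$channel_labels)),
                   paste0(path, ".meta.yaml"))
  invisible(path)
}

#' Read EEG from delimited text
#'
#' @param path Path to the sample matrix written by [write_eeg()]; the
#'   sidecar `<path>.meta.yaml` must be present.
#' @param channels Optional subset of channel labels to keep; a missing
#'   channel is an error naming the available labels.
#' @return A [raw_eeg()] object.
#' @export
read_eeg <- function(path, channels = NULL) {
  if (!file.exists(path)) stopf("EEG file not found: %s", path)
  meta_path <- paste0(path, ".meta.yaml")
  if (!file.exists(meta_path)) stopf("missing sidecar: %s", meta_path)
  meta <- yaml::read_yaml(meta_path)
  labels <- unlist(meta$channel_labels)
  m <- as.matrix(utils::read.table(path, header = TRUE, sep = "\t",
                                   check.names = FALSE))
  if (!identical(colnames(m), labels))
    stopf("column headers of %s do not match sidecar channel labels", path)
  raw <- raw_eeg(m, sampling_rate = meta$sampling_rate,
                 channel_labels = labels)
  if (!is.null(channels)) {
    missing <- setdiff(channels, raw$channel_labels)
    if (length(missing) > 0L)
      stopf("channel(s) %s not in %s; available: %s",
            paste(missing, collapse = ", "), path,
            paste(raw$channel_labels, collapse = ", "))
    raw <- raw_eeg(raw$samples[, channels, drop = FALSE],
                   sampling_rate = raw$sampling_rate,
                   channel_labels = channels)
  }
  raw
}

analysis_config_defaults <- function() {
  list(
    mode = "synthetic",          # "synthetic" or "files"
    band = c(8, 13),             # Hz, inclusive edges
    thresholds = c(30, 50, 70),  # percent of max resting alpha power
    channels = c("AF3", "AF4"),
    epoch_duration = 1,          # s
    target_rate = 250,           # Hz
    artifact_criterion = 100,    # uV peak amplitude
    max_power_method = "fence",  # or "literal"
    tail_method = "powerlaw",
    pain_block = "pre",          # block feeding the session pain level
    censor_boundary_dwells = FALSE,
    seed = 1L,
    input_dir = NULL,            # mode = "files": manifest.csv + vas.csv here
    output_dir = NULL,           # optional CSV output directory
    cohort = list()              # overrides passed to cohort_spec()
  )
}

#' Build a validated analysis configuration
#'
#' Collects every analysis constant (band, thresholds, channels, epoch and
#' rate settings, artifact criterion, module decision switches, seeds,
#' paths) with the study defaults; unknown keys are rejected.
#'
#' @param ... Named overrides of the defaults; `cohort` is a named list of
#'   [cohort_spec()] overrides for synthetic mode.
#' @return An object of class `analysis_config`.
#' @export
analysis_config <- function(...) {
  cfg <- analysis_config_defaults()
  overrides <- list(...)
  if (length(overrides) > 0L && is.null(names(overrides)))
    stopf("configuration overrides must be named")
  unknown <- setdiff(names(overrides), names(cfg))
  if (length(unknown) > 0L)
    stopf("unknown configuration key(s): %s", paste(unknown, collapse = ", "))
  cfg[names(overrides)] <- overrides
  if (length(cfg$band) != 2L || cfg$band[1L] <= 0 || cfg$band[2L] <= cfg$band[1L])
    stopf("`band` must be an increasing positive pair")
  if (any(cfg$thresholds <= 0 | cfg$thresholds > 100))
    stopf("`thresholds` must be percentages in (0, 100]")
  if (!cfg$mode %in% c("synthetic", "files"))
    stopf("`mode` must be 'synthetic' or 'files'")
  if (!cfg$max_power_method %in% c("fence", "literal"))
    stopf("`max_power_method` must be 'fence' or 'literal'")
  if (!cfg$pain_block %in% c("pre", "post", "mean"))
    stopf("`pain_block` must be 'pre', 'post' or 'mean'")
  if (cfg$mode == "files" && is.null(cfg$input_dir))
    stopf("mode 'files' requires `input_dir`")
  unknown_cohort <- setdiff(names(cfg$cohort),
                            names(formals(cohort_spec)))
  if (length(unknown_cohort) > 0L)
    stopf("unknown cohort key(s): %s", paste(unknown_cohort, collapse = ", "))
  if (!is.null(cfg$cohort$emission) &&
      !inherits(cfg$cohort$emission, "emission_params"))
    cfg$cohort$emission <- do.call(emission_params, cfg$cohort$emission)
  structure(cfg, class = "analysis_config")
}

#' Load an analysis configuration from YAML
#'
#' @param path Path to a YAML file whose keys are [analysis_config()]
#'   arguments.
#' @return An object of class `analysis_config`.
#' @export
load_config <- function(path) {
  if (!file.exists(path)) stopf("config file not found: %s", path)
  raw <- yaml::read_yaml(path)
  if (!is.null(raw$band)) raw$band <- as.numeric(unlist(raw$band))
  if (!is.null(raw$thresholds)) raw$thresholds <- as.numeric(unlist(raw$thresholds))
  if (!is.null(raw$channels)) raw$channels <- as.character(unlist(raw$channels))
  do.call(analysis_config, raw)
}
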