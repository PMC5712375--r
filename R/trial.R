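#' EEG trial container
#'
#' An `eeg_trial` stores one recording: a channels-by-samples matrix in
#' microvolts, the sampling rate, ordered channel names and a tibble of
#' event marks (gait start/stop instants from the motion-capture ground
#' truth). Times are seconds from the first sample; sample `k` (1-based)
#' covers the half-open interval `[(k-1)/fs, k/fs)`.
#'
#' @param data Numeric matrix, channels x samples (microvolts).
#' @param sample_rate Sampling rate in Hz (nominally 500).
#' @param channel_names Character vector, one per row of `data`.
#' @param events Tibble/data frame with columns `kind` ("start"/"stop")
#'   and `time_s`, or NULL for no events.
#' @return An `eeg_trial` object.
#' @examples
#' tr <- new_trial(matrix(rnorm(1000), 2), 500, c("C3", "C4"))
#' trial_duration(tr)
#' @export
new_trial <- function(data, sample_rate, channel_names,
                      events = NULL) {
  data <- as.matrix(data)
  storage.mode(data) <- "double"
  assert_finite(data, "trial data")
  if (sample_rate <= 0) {
    stop_gaitbci("sample_rate must be positive", "gaitbci_validation_error")
  }
  if (length(channel_names) != nrow(data) || anyDuplicated(channel_names)) {
    stop_gaitbci("channel_names must be unique and match data rows",
                 "gaitbci_validation_error")
  }
  rownames(data) <- channel_names
  events <- normalize_events(events, duration = ncol(data) / sample_rate)
  structure(list(data = data, sample_rate = sample_rate,
                 channel_names = as.character(channel_names),
                 events = events),
            class = "eeg_trial")
}

normalize_events <- function(events, duration) {
  if (is.null(events) || nrow(as.data.frame(events)) == 0) {
    return(tibble::tibble(kind = character(), time_s = numeric()))
  }
  events <- tibble::as_tibble(events)
  stopifnot(all(c("kind", "time_s") %in% names(events)))
  if (!all(events$kind %in% c("start", "stop"))) {
    stop_gaitbci("event kind must be 'start' or 'stop'",
                 "gaitbci_validation_error")
  }
  if (any(events$time_s < 0) || any(events$time_s > duration)) {
    stop_gaitbci("event times must lie within [0, trial duration]",
                 "gaitbci_validation_error")
  }
  dplyr::arrange(events[, c("kind", "time_s")], .data$time_s)
}

#' Trial duration in seconds
#' @param trial An `eeg_trial`.
#' @return Duration in seconds.
#' @export
trial_duration <- function(trial) {
  ncol(trial$data) / trial$sample_rate
}

#' @export
print.eeg_trial <- function(x, ...) {
  cat(sprintf(
    "<eeg_trial: %d channels x %d samples @ %g Hz (%.3f s), %d events>\n",
    nrow(x$data), ncol(x$data), x$sample_rate, trial_duration(x),
    nrow(x$events)))
  invisible(x)
}

#' Event times of one kind
#' @param trial An `eeg_trial`.
#' @param kind "start" or "stop".
#' @return Numeric vector of event times in seconds.
#' @export
event_times <- function(trial, kind = c("start", "stop")) {
  kind <- match.arg(kind)
  trial$events$time_s[trial$events$kind == kind]
}
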