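#' Read a trial from TSV files
#'
#' The native interchange format is a pair of plain TSV files. The signal
#' file carries comment-header lines `# sample_rate_hz=<fs>` and
#' `# channels=<tab-joined names>`, then one row per sample:
#' `time_s<TAB>v1<TAB>...<TAB>vN` in microvolts. The events file has a
#' header `kind<TAB>time_s` and one `start`/`stop` row per event.
#'
#' @param signal_path Path to the signal TSV.
#' @param events_path Path to the events TSV, or NULL for no events.
#' @return An [new_trial()] object.
#' @seealso [write_trial()]
#' @export
read_trial <- function(signal_path, events_path = NULL) {
  lines <- readLines(signal_path)
  hdr <- grep("^#", lines, value = TRUE)
  get_field <- function(key) {
    hit <- grep(sprintf("^#\\s*%s=", key), hdr, value = TRUE)
    if (length(hit) != 1) {
      stop_gaitbci(
        sprintf("malformed header: expected exactly one '# %s=' line", key),
        "gaitbci_format_error")
    }
    sub(sprintf("^#\\s*%s=", key), "", hit)
  }
  fs <- suppressWarnings(as.numeric(get_field("sample_rate_hz")))
  if (!is.finite(fs)) {
    stop_gaitbci("malformed header: sample_rate_hz is not numeric",
                 "gaitbci_format_error")
  }
  channels <- strsplit(get_field("channels"), "\t", fixed = TRUE)[[1]]
  body <- lines[!grepl("^#", lines)]
  body <- body[nzchar(body)]
  if (length(body) == 0) {
    data <- matrix(numeric(0), nrow = length(channels), ncol = 0)
  } else {
    m <- utils::read.table(text = body, sep = "\t", header = FALSE,
                           colClasses = "numeric")
    if (ncol(m) != length(channels) + 1) {
      stop_gaitbci(sprintf(
        "signal rows have %d columns; expected time + %d channels",
        ncol(m), length(channels)), "gaitbci_format_error")
    }
    data <- t(as.matrix(m[, -1, drop = FALSE]))
  }
  events <- NULL
  if (!is.null(events_path)) {
    ev <- utils::read.table(events_path, sep = "\t", header = TRUE,
                            colClasses = c("character", "numeric"))
    events <- tibble::tibble(kind = ev$kind, time_s = ev$time_s)
  }
  new_trial(data, fs, channels, events)
}

#' Write a trial to TSV files
#'
#' Inverse of [read_trial()]; values are written with 17 significant
#' digits so a read/write round trip preserves doubles exactly.
#'
#' @param trial An `eeg_trial`.
#' @param signal_path Output path for the signal TSV.
#' @param events_path Output path for the events TSV, or NULL to skip.
#' @return Invisibly, `trial`.
#' @export
write_trial <- function(trial, signal_path, events_path = NULL) {
  stopifnot(inherits(trial, "eeg_trial"))
  n <- ncol(trial$data)
  con <- file(signal_path, "w")
  on.exit(close(con), add = TRUE)
  writeLines(c(
    sprintf("# sample_rate_hz=%s", format(trial$sample_rate, digits = 17)),
    paste0("# channels=", paste(trial$channel_names, collapse = "\t"))
  ), con)
  if (n > 0) {
    times <- (seq_len(n) - 1) / trial$sample_rate
    block <- cbind(times, t(trial$data))
    rows <- apply(block, 1, function(r)
      paste(formatC(r, digits = 17, format = "g"), collapse = "\t"))
    writeLines(rows, con)
  }
  if (!is.null(events_path)) {
    con2 <- file(events_path, "w")
    on.exit(close(con2), add = TRUE)
    writeLines("kind\ttime_s", con2)
    if (nrow(trial$events) > 0) {
      writeLines(paste(trial$events$kind,
                       formatC(trial$events$time_s, digits = 17,
                               format = "g"),
                       sep = "\t"), con2)
    }
  }
  invisible(trial)
}
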