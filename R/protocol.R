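#' Build labelled analysis windows around gait events
#'
#' For one trial and one detection model (start or stop of gait), returns
#' the active (state 1, intention) and non-active (state 0, rest or gait)
#' windows that feed epoch slicing.
#'
#' Pseudo-online: the active window spans `[e - pre_event_s, e +
#' (active_len_s - pre_event_s)]` around each event instant `e` (defaults:
#' 4 s starting 2 s before the event); the non-active span covers the whole
#' preceding rest (start model) or gait (stop model) phase, from the end of
#' the previous event's active window (or the trial start), ending `gap_s`
#' before the active window begins.
#'
#' Offline: the active window is the `active_len_s` seconds preceding the
#' event, `[e - 4, e]`, and the non-active window is an equal-length window
#' ending `gap_s` before the active window starts.
#'
#' Events whose windows would extend outside the recording are dropped;
#' the number dropped is attached as attribute `n_skipped`.
#'
#' @param trial An `eeg_trial` with event marks.
#' @param event_kind "start" or "stop": which detection model.
#' @param protocol "offline" or "pseudo_online".
#' @param active_len_s Active-window length in seconds (default 4).
#' @param pre_event_s Pseudo-online lead of the active window before the
#'   event (default 2).
#' @param gap_s Guard gap between non-active and active windows (default
#'   0.5).
#' @return Tibble with columns `window_id`, `event_time`, `event_kind`,
#'   `state` (0/1), `t_begin`, `t_end`, `protocol`.
#' @export
build_windows <- function(trial, event_kind = c("start", "stop"),
                          protocol = c("offline", "pseudo_online"),
                          active_len_s = 4, pre_event_s = 2, gap_s = 0.5) {
  stopifnot(inherits(trial, "eeg_trial"))
  event_kind <- match.arg(event_kind)
  protocol <- match.arg(protocol)
  ev <- event_times(trial, event_kind)
  if (length(ev) == 0) {
    stop_gaitbci(sprintf("trial has no '%s' events", event_kind),
                 "gaitbci_validation_error")
  }
  dur <- trial_duration(trial)
  all_ev <- trial$events$time_s
  rows <- list()
  n_skipped <- 0L
  for (i in seq_along(ev)) {
    e <- ev[i]
    if (protocol == "offline") {
      a0 <- e - active_len_s; a1 <- e
      n1 <- a0 - gap_s; n0 <- n1 - active_len_s
    } else {
      a0 <- e - pre_event_s; a1 <- e + (active_len_s - pre_event_s)
      n1 <- a0 - gap_s
      prev <- all_ev[all_ev < e]
      n0 <- if (length(prev) == 0) 0 else {
        max(prev) + (active_len_s - pre_event_s)
      }
    }
    if (n0 < 0 || a0 < 0 || a1 > dur + 1e-9 || n1 <= n0) {
      n_skipped <- n_skipped + 1L
      next
    }
    rows[[length(rows) + 1]] <- tibble::tibble(
      event_time = e, state = c(0L, 1L),
      t_begin = c(n0, a0), t_end = c(n1, a1))
  }
  out <- dplyr::bind_rows(rows)
  if (nrow(out) == 0) {
    out <- tibble::tibble(event_time = numeric(), state = integer(),
                          t_begin = numeric(), t_end = numeric())
  }
  out <- dplyr::mutate(out,
                       window_id = dplyr::row_number(),
                       event_kind = event_kind, protocol = protocol)
  out <- out[, c("window_id", "event_time", "event_kind", "state",
                 "t_begin", "t_end", "protocol")]
  attr(out, "n_skipped") <- n_skipped
  out
}

#' Slice windows into overlapping 1-s epochs
#'
#' Within each window, epochs of `epoch_len_s` seconds begin at `t_begin`,
#' `t_begin + hop_s`, ... for as long as the epoch fits wholly inside the
#' window (epochs straddling the edge are discarded, keeping the feature
#' input a fixed 500 samples).
#'
#' @param trial An `eeg_trial`.
#' @param windows Tibble from [build_windows()].
#' @param epoch_len_s Epoch length in seconds (default 1).
#' @param hop_s Hop between consecutive epoch onsets (default 0.2).
#' @return Tibble with one row per epoch: `epoch_id`, `window_id`,
#'   `state`, `event_kind`, `t_begin`, and a list-column `data` of
#'   channels-by-samples matrices.
#' @export
slice_epochs <- function(trial, windows, epoch_len_s = 1, hop_s = 0.2) {
  stopifnot(inherits(trial, "eeg_trial"))
  fs <- trial$sample_rate
  n_ep <- as.integer(round(epoch_len_s * fs))
  n_total <- ncol(trial$data)
  rows <- purrr::pmap(
    list(windows$window_id, windows$state, windows$event_kind,
         windows$t_begin, windows$t_end),
    function(wid, state, kind, t0, t1) {
      n_fit <- floor((t1 - t0 - epoch_len_s) / hop_s + 1e-9) + 1
      if (n_fit < 1) return(NULL)
      starts <- t0 + hop_s * (seq_len(n_fit) - 1)
      mats <- lapply(starts, function(s) {
        i0 <- as.integer(round(s * fs))
        if (i0 < 0 || i0 + n_ep > n_total) return(NULL)
        trial$data[, (i0 + 1):(i0 + n_ep), drop = FALSE]
      })
      keep <- !vapply(mats, is.null, logical(1))
      if (!any(keep)) return(NULL)
      tibble::tibble(window_id = wid, state = state, event_kind = kind,
                     t_begin = starts[keep], data = mats[keep])
    })
  out <- dplyr::bind_rows(rows)
  if (nrow(out) == 0) {
    return(tibble::tibble(epoch_id = integer(), window_id = integer(),
                          state = integer(), event_kind = character(),
                          t_begin = numeric(), data = list()))
  }
  dplyr::mutate(out, epoch_id = dplyr::row_number(), .before = 1)
}

#' Train/test split plan over trials
#'
#' Offline evaluation uses leave-one-out cross-validation over trials;
#' pseudo-online uses a fixed chronological split (the first trials build
#' the model, the remaining trials replay as test data), e.g. a 6/4 ratio
#' for a 10-trial subject or 4/3 for a 7-trial one.
#'
#' @param n_trials Number of trials.
#' @param protocol "offline" (LOOCV) or "pseudo_online" (fixed split).
#' @param ratio Length-2 integer vector `c(n_train, n_test)` for the
#'   pseudo-online split; ignored for offline.
#' @return Tibble with columns `fold`, `train` (list of indices), `test`
#'   (list of indices).
#' @export
make_split <- function(n_trials, protocol = c("offline", "pseudo_online"),
                       ratio = NULL) {
  protocol <- match.arg(protocol)
  if (n_trials < 2) {
    stop_gaitbci("need at least two trials", "gaitbci_validation_error")
  }
  if (protocol == "offline") {
    return(tibble::tibble(
      fold = seq_len(n_trials),
      train = lapply(seq_len(n_trials), function(i) setdiff(seq_len(n_trials), i)),
      test = as.list(seq_len(n_trials))))
  }
  if (is.null(ratio)) ratio <- c(6, n_trials - 6)
  ratio <- as.integer(ratio)
  if (length(ratio) != 2 || any(ratio < 1) || sum(ratio) > n_trials) {
    stop_gaitbci("ratio must be c(n_train, n_test) with sum <= n_trials",
                 "gaitbci_validation_error")
  }
  tibble::tibble(fold = 1L,
                 train = list(seq_len(ratio[1])),
                 test = list(ratio[1] + seq_len(ratio[2])))
}
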