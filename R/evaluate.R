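#' Compare predicted and true epoch labels
#'
#' Element-wise comparison of the classifier output with the true state
#' of each epoch: TRUE (a "T" outcome) where they agree, FALSE ("F")
#' where they differ.
#'
#' @param true_labels,predicted_labels Equal-length 0/1 vectors.
#' @return Logical vector of outcomes.
#' @export
score_epochs <- function(true_labels, predicted_labels) {
  if (length(true_labels) != length(predicted_labels)) {
    stop_gaitbci("label vectors must have equal length",
                 "gaitbci_validation_error")
  }
  as.integer(true_labels) == as.integer(predicted_labels)
}

#' Detection in an active window from its epoch outcomes
#'
#' Offline, a majority of correct epochs (`#T > #F`) marks the event
#' detected; pseudo-online, at least one run of `consecutive` or more
#' correct epochs in a row is required (consecutive 1-s epochs at the
#' 0.2-s hop).
#'
#' @param outcomes Logical outcome vector for one window, in time order.
#' @param protocol "offline" or "pseudo_online".
#' @param consecutive Run-length threshold for pseudo-online (default 5).
#' @return TRUE if the event counts as detected.
#' @export
active_window_detected <- function(outcomes,
                                   protocol = c("offline", "pseudo_online"),
                                   consecutive = 5) {
  protocol <- match.arg(protocol)
  if (length(outcomes) == 0) return(FALSE)
  if (protocol == "offline") {
    sum(outcomes) > sum(!outcomes)
  } else {
    r <- runs_of(outcomes)
    any(r$value & r$length >= consecutive)
  }
}

#' False activations in a non-active span from its epoch outcomes
#'
#' Offline, a majority of wrong epochs in the 4-s window counts one false
#' positive (at most one per window). Pseudo-online, every maximal run of
#' `consecutive` or more wrong epochs counts one false activation
#' (`fp_counting = "per_run"`, the default: a sustained spurious command
#' triggers a device once however long it lasts); `"floor_div"` instead
#' counts `floor(run length / consecutive)` per run.
#'
#' @param outcomes Logical outcome vector for one non-active span.
#' @inheritParams active_window_detected
#' @param fp_counting "per_run" or "floor_div".
#' @return Non-negative integer count of false activations.
#' @export
count_false_activations <- function(outcomes,
                                    protocol = c("offline", "pseudo_online"),
                                    consecutive = 5,
                                    fp_counting = c("per_run", "floor_div")) {
  protocol <- match.arg(protocol)
  fp_counting <- match.arg(fp_counting)
  if (length(outcomes) == 0) return(0L)
  if (protocol == "offline") {
    return(as.integer(sum(!outcomes) > sum(outcomes)))
  }
  r <- runs_of(outcomes)
  f_runs <- r$length[!r$value]
  if (fp_counting == "per_run") {
    sum(f_runs >= consecutive)
  } else {
    sum(f_runs %/% consecutive)
  }
}

#' Per-window detection record
#'
#' Groups epoch outcomes by window and applies the protocol's detection
#' rules, yielding the raw counts behind the performance indices.
#'
#' @param epochs Tibble with `window_id` and `state` per epoch, ordered
#'   in time within each window (e.g. from [slice_epochs()] or
#'   [epoch_features()]).
#' @param outcomes Logical vector from [score_epochs()], one per row of
#'   `epochs`.
#' @param windows Tibble from [build_windows()] (supplies non-active span
#'   durations).
#' @inheritParams count_false_activations
#' @return A `detection_record`: tibble with one row per window
#'   (`window_id`, `state`, `n_epochs`, `detected`, `n_false`,
#'   `duration_min`), with the protocol in attribute `protocol`.
#' @export
detect_events <- function(epochs, outcomes, windows,
                          protocol = c("offline", "pseudo_online"),
                          consecutive = 5,
                          fp_counting = c("per_run", "floor_div")) {
  protocol <- match.arg(protocol)
  fp_counting <- match.arg(fp_counting)
  stopifnot(nrow(epochs) == length(outcomes))
  df <- dplyr::mutate(epochs[, c("window_id", "state")], outcome = outcomes)
  rec <- df |>
    dplyr::group_by(.data$window_id, .data$state) |>
    dplyr::summarise(
      n_epochs = dplyr::n(),
      detected = .data$state[1] == 1L &&
        active_window_detected(.data$outcome, protocol, consecutive),
      n_false = if (.data$state[1] == 0L) {
        count_false_activations(.data$outcome, protocol, consecutive,
                                fp_counting)
      } else 0L,
      .groups = "drop")
  dur <- windows[, c("window_id", "t_begin", "t_end")]
  rec <- dplyr::left_join(rec, dur, by = "window_id") |>
    dplyr::mutate(duration_min = (.data$t_end - .data$t_begin) / 60) |>
    dplyr::select(-"t_begin", -"t_end")
  attr(rec, "protocol") <- protocol
  class(rec) <- c("detection_record", class(rec))
  rec
}

#' Performance indices of a detection record
#'
#' * TPR (%): true event detections over true events (active windows).
#' * Acc (%): true event detections over all detections (true plus false
#'   activations); undefined (NA) when nothing was detected at all.
#' * FP/min: false activations per minute of non-active time.
#'
#' @param record A `detection_record` from [detect_events()], or a list
#'   with fields `n_events`, `n_detected`, `n_false`, `nonactive_min`.
#' @return Tibble with one row: `tpr`, `acc`, `fp_per_min`,
#'   `fp_duration_min` (4/60 offline, 1/60 pseudo-online), plus the raw
#'   counts.
#' @export
compute_indices <- function(record) {
  if (inherits(record, "detection_record")) {
    protocol <- attr(record, "protocol")
    act <- record[record$state == 1L, ]
    non <- record[record$state == 0L, ]
    counts <- list(n_events = nrow(act),
                   n_detected = sum(act$detected),
                   n_false = sum(non$n_false),
                   nonactive_min = sum(non$duration_min))
  } else {
    protocol <- attr(record, "protocol")
    if (is.null(protocol)) protocol <- record$protocol
    counts <- record
  }
  if (is.null(counts$n_events) || counts$n_events < 1) {
    stop_gaitbci("need at least one true event", "gaitbci_validation_error")
  }
  if (counts$nonactive_min <= 0) {
    stop_gaitbci("non-active time is zero; FP/min undefined",
                 "gaitbci_validation_error")
  }
  total_det <- counts$n_detected + counts$n_false
  tibble::tibble(
    tpr = 100 * counts$n_detected / counts$n_events,
    acc = if (total_det == 0) NA_real_ else
      100 * counts$n_detected / total_det,
    fp_per_min = counts$n_false / counts$nonactive_min,
    fp_duration_min = if (identical(protocol, "pseudo_online")) 1 / 60 else 4 / 60,
    n_events = counts$n_events, n_detected = counts$n_detected,
    n_false = counts$n_false, nonactive_min = counts$nonactive_min)
}

#' Weighted Discriminator index
#'
#' Composite performance score `WD = 0.4 TPR + 0.6 Acc - FPR` with TPR
#' and Acc as per-unit values and `FPR = FP/min x duration of a single
#' false positive in minutes` (4/60 offline, 1/60 pseudo-online). Ranges
#' from 1 (all events detected, no false activations) down to -1.
#' Reported values are rounded to two decimals, ties away from zero.
#'
#' @param tpr_pct True positive rate in percent.
#' @param acc_pct Accuracy in percent (NA propagates).
#' @param fp_per_min False activations per minute.
#' @param fp_duration_min Duration of one false positive in minutes:
#'   `4/60` (offline) or `1/60` (pseudo-online).
#' @param digits Decimal places for the reported value (default 2); NULL
#'   for the raw value.
#' @return The WD value (NA if `acc_pct` is NA).
#' @examples
#' weighted_discriminator(87.5, 98, 0.38, 4 / 60)
#' @export
weighted_discriminator <- function(tpr_pct, acc_pct, fp_per_min,
                                   fp_duration_min, digits = 2) {
  wd <- 0.4 * tpr_pct / 100 + 0.6 * acc_pct / 100 -
    fp_per_min * fp_duration_min
  if (!is.null(digits)) wd <- round_half_up(wd, digits)
  wd
}

#' Full evaluation report for a detection record
#'
#' @inheritParams compute_indices
#' @return Tibble with `tpr`, `acc`, `fp_per_min`, `fpr`, `wd` plus raw
#'   counts.
#' @export
evaluation_report <- function(record) {
  idx <- compute_indices(record)
  dplyr::mutate(idx,
                fpr = .data$fp_per_min * .data$fp_duration_min,
                wd = weighted_discriminator(.data$tpr, .data$acc,
                                            .data$fp_per_min,
                                            .data$fp_duration_min),
                .after = "fp_per_min")
}

#' Average evaluation reports over trials
#'
#' Arithmetic mean and sample standard deviation of each index; trials
#' with undefined Acc (no detections at all) are excluded from the Acc
#' and WD means and counted in `n_undefined_acc`.
#'
#' @param reports Tibble of per-trial reports (rows from
#'   [evaluation_report()] stacked together).
#' @return One-row tibble of means with `*_sd` columns and
#'   `n_undefined_acc`.
#' @export
aggregate_reports <- function(reports) {
  cols <- intersect(c("tpr", "acc", "fp_per_min", "fpr", "wd"),
                    names(reports))
  means <- vapply(cols, function(cl) mean(reports[[cl]], na.rm = TRUE),
                  numeric(1))
  sds <- vapply(cols, function(cl) {
    v <- reports[[cl]][!is.na(reports[[cl]])]
    if (length(v) < 2) 0 else stats::sd(v)
  }, numeric(1))
  out <- tibble::as_tibble(as.list(means))
  names(sds) <- paste0(cols, "_sd")
  dplyr::bind_cols(out, tibble::as_tibble(as.list(sds)),
                   tibble::tibble(n_trials = nrow(reports),
                                  n_undefined_acc = sum(is.na(reports$acc))))
}
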