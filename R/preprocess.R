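#' Surface-Laplacian weights
#'
#' Inverse-distance weights for the spatial Laplacian filter. For electrode
#' i the weight of electrode j is
#' `g_ij = (1/d_ij) / sum_{k != i} (1/d_ik)` with `d` the 3-D chord
#' distance, so each row sums to one and the diagonal is zero.
#'
#' @param layout An `electrode_layout` (weights are computed over all its
#'   electrodes, i.e. the full recorded montage).
#' @return Square matrix of weights with electrode dimnames.
#' @export
laplacian_weights <- function(layout) {
  d <- electrode_distances(layout)
  if (nrow(d) < 2) {
    stop_gaitbci("need at least two electrodes", "gaitbci_validation_error")
  }
  inv <- 1 / d
  diag(inv) <- 0
  g <- inv / rowSums(inv)
  g
}

#' Apply the surface-Laplacian spatial filter
#'
#' Subtracts from each channel the distance-weighted mean of every other
#' channel: `out_i(t) = V_i(t) - sum_{j != i} g_ij V_j(t)`. The filter is
#' applied over the full montage before any channel subsetting, so that
#' each sensor's signal is referenced against the whole scalp.
#'
#' @param trial An `eeg_trial` whose channels match the weight matrix
#'   dimnames in order.
#' @param weights Matrix from [laplacian_weights()].
#' @return A filtered `eeg_trial` (events unchanged).
#' @export
laplacian_filter <- function(trial, weights) {
  stopifnot(inherits(trial, "eeg_trial"))
  if (!identical(rownames(weights), trial$channel_names)) {
    stop_gaitbci("weight matrix channels do not match trial channels",
                 "gaitbci_validation_error")
  }
  out <- trial$data - weights %*% trial$data
  new_trial(out, trial$sample_rate, trial$channel_names, trial$events)
}

#' Zero-phase Butterworth high-pass filter
#'
#' Removes the DC component and slow drifts ahead of FFT band-power
#' features (the Hilbert-Huang and Stockwell paths operate on the raw
#' Laplacian-filtered signal). The filter is applied forward-backward
#' (zero phase) over the whole trial so that overlapping 1-s epochs carry
#' no group-delay misalignment relative to the event marks.
#'
#' @param trial An `eeg_trial`.
#' @param order Filter order (default 4).
#' @param cutoff_hz High-pass cutoff in Hz (default 0.2).
#' @return A filtered `eeg_trial`.
#' @export
butterworth_highpass <- function(trial, order = 4, cutoff_hz = 0.2) {
  stopifnot(inherits(trial, "eeg_trial"))
  fs <- trial$sample_rate
  if (cutoff_hz <= 0 || cutoff_hz >= fs / 2) {
    stop_gaitbci("cutoff must lie in (0, Nyquist)", "gaitbci_validation_error")
  }
  if (ncol(trial$data) < 3 * order) {
    stop_gaitbci("trial too short for the filter order",
                 "gaitbci_validation_error")
  }
  bf <- signal::butter(order, cutoff_hz / (fs / 2), type = "high")
  out <- t(apply(trial$data, 1, function(ch)
    signal::filtfilt(bf, ch)))
  new_trial(out, fs, trial$channel_names, trial$events)
}

#' Subset and reorder channels
#'
#' @param trial An `eeg_trial`.
#' @param names Channels to keep, in the requested order; must all be
#'   present in the trial.
#' @return An `eeg_trial` restricted to `names`.
#' @export
select_channels <- function(trial, names) {
  stopifnot(inherits(trial, "eeg_trial"))
  missing <- setdiff(names, trial$channel_names)
  if (length(missing) > 0) {
    stop_gaitbci(paste("unknown channel(s):", paste(missing, collapse = ", ")),
                 "gaitbci_validation_error")
  }
  new_trial(trial$data[names, , drop = FALSE], trial$sample_rate,
            names, trial$events)
}
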