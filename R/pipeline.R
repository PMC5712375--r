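#' Preprocess a trial for feature extraction
#'
#' Surface-Laplacian filter over the full recorded montage, optional
#' zero-phase Butterworth high-pass (FFT path only), then subsetting to
#' the analysis electrodes.
#'
#' @param trial An `eeg_trial`.
#' @param layout Electrode layout covering the trial's channels.
#' @param method Feature method; the 0.2-Hz high-pass is applied only for
#'   "fft" (the Hilbert-Huang and Stockwell paths are insensitive to the
#'   DC component).
#' @param spatial_filter "laplacian" (default) or "none".
#' @param highpass_order,highpass_cutoff_hz Butterworth parameters
#'   (defaults 4 and 0.2 Hz).
#' @return Preprocessed `eeg_trial` restricted to
#'   `layout$feature_subset`.
#' @export
preprocess_trial <- function(trial, layout = standard_1010_layout(),
                             method = c("fft", "hht", "st"),
                             spatial_filter = c("laplacian", "none"),
                             highpass_order = 4, highpass_cutoff_hz = 0.2) {
  method <- match.arg(method)
  spatial_filter <- match.arg(spatial_filter)
  if (spatial_filter == "laplacian") {
    sub <- layout$positions[match(trial$channel_names,
                                  layout$positions$name), ]
    if (anyNA(sub$name)) {
      stop_gaitbci("trial channels missing from the layout",
                   "gaitbci_validation_error")
    }
    sub_layout <- new_electrode_layout(
      sub, feature_subset = intersect(layout$feature_subset,
                                      trial$channel_names))
    trial <- laplacian_filter(trial, laplacian_weights(sub_layout))
  }
  if (method == "fft") {
    trial <- butterworth_highpass(trial, highpass_order,
                                  highpass_cutoff_hz)
  }
  select_channels(trial, intersect(layout$feature_subset,
                                   trial$channel_names))
}

#' Run the full detection pipeline over a set of trials
#'
#' Preprocesses every trial, slices labelled windows into 1-s epochs at
#' the 0.2-s hop, extracts per-electrode band features with the chosen
#' time-frequency method, trains the RBF-SVM per split, and scores each
#' test trial with the event-detection indices and the Weighted
#' Discriminator. Offline evaluation uses leave-one-out cross-validation
#' over trials; pseudo-online uses the fixed chronological split.
#'
#' @param trials List of `eeg_trial` objects.
#' @param method "fft", "hht" or "st".
#' @param event "start" or "stop": which detection model.
#' @param protocol "offline" or "pseudo_online".
#' @param layout Electrode layout (default [standard_1010_layout()]).
#' @param ratio Pseudo-online `c(n_train, n_test)` split (default 6 and
#'   the rest).
#' @param bands Band list from [band_set()].
#' @param cost,gamma SVM hyperparameters (see [train_classifier()]).
#' @param consecutive Pseudo-online run-length threshold (default 5).
#' @param fp_counting False-activation counting rule (default
#'   "per_run").
#' @param spatial_filter "laplacian" (default) or "none".
#' @param feature_args List of extra arguments for the feature extractor
#'   (e.g. `list(max_freq_hz = 50)` for a truncated Stockwell grid).
#' @return A `bci_run` object; see [tidy.bci_run()] and
#'   [glance.bci_run()].
#' @export
run_pipeline <- function(trials, method = c("fft", "hht", "st"),
                         event = c("start", "stop"),
                         protocol = c("offline", "pseudo_online"),
                         layout = standard_1010_layout(), ratio = NULL,
                         bands = band_set(), cost = 1, gamma = NULL,
                         consecutive = 5,
                         fp_counting = c("per_run", "floor_div"),
                         spatial_filter = c("laplacian", "none"),
                         feature_args = list()) {
  method <- match.arg(method)
  event <- match.arg(event)
  protocol <- match.arg(protocol)
  fp_counting <- match.arg(fp_counting)
  spatial_filter <- match.arg(spatial_filter)
  if (length(trials) < 2) {
    stop_gaitbci("need at least two trials", "gaitbci_validation_error")
  }
  fs <- trials[[1]]$sample_rate

  prepped <- lapply(trials, preprocess_trial, layout = layout,
                    method = method, spatial_filter = spatial_filter)
  per_trial <- lapply(prepped, function(tr) {
    w <- build_windows(tr, event, protocol)
    ep <- slice_epochs(tr, w)
    f <- do.call(epoch_features,
                 c(list(ep, fs = fs, method = method, bands = bands),
                   feature_args))
    list(windows = w, features = f)
  })

  split <- make_split(length(trials), protocol, ratio)
  reports <- list()
  for (k in seq_len(nrow(split))) {
    tr_idx <- split$train[[k]]
    te_idx <- split$test[[k]]
    train_f <- dplyr::bind_rows(lapply(per_trial[tr_idx],
                                       function(z) z$features))
    model <- train_classifier(train_f, cost = cost, gamma = gamma)
    for (i in te_idx) {
      f <- per_trial[[i]]$features
      pred <- classify_epochs(model, f)
      out <- score_epochs(f$state, pred)
      rec <- detect_events(f, out, per_trial[[i]]$windows, protocol,
                           consecutive, fp_counting)
      rep_i <- evaluation_report(rec)
      rep_i$trial <- i
      rep_i$fold <- split$fold[k]
      reports[[length(reports) + 1]] <- rep_i
    }
  }
  reports <- dplyr::bind_rows(reports)
  structure(list(reports = reports,
                 summary = aggregate_reports(reports),
                 method = method, event = event, protocol = protocol,
                 n_trials = length(trials)),
            class = "bci_run")
}

#' @export
print.bci_run <- function(x, ...) {
  cat(sprintf("<bci_run: %s features, %s model, %s protocol, %d trials>\n",
              x$method, x$event, x$protocol, x$n_trials))
  s <- x$summary
  cat(sprintf("  mean TPR %.2f%%  Acc %.2f%%  FP/min %.2f  WD %.2f\n",
              s$tpr, s$acc, s$fp_per_min, s$wd))
  invisible(x)
}

#' Per-trial results of a pipeline run
#'
#' @param x A `bci_run`.
#' @param ... Unused.
#' @return Tibble with one row per evaluated trial: `trial`, `fold`,
#'   `tpr`, `acc`, `fp_per_min`, `fpr`, `wd` and raw counts.
#' @method tidy bci_run
#' @export
tidy.bci_run <- function(x, ...) {
  dplyr::relocate(x$reports, "trial", "fold")
}

#' One-row summary of a pipeline run
#'
#' @param x A `bci_run`.
#' @param ... Unused.
#' @return One-row tibble: method/event/protocol and averaged indices
#'   with standard deviations.
#' @method glance bci_run
#' @export
glance.bci_run <- function(x, ...) {
  dplyr::bind_cols(
    tibble::tibble(method = x$method, event = x$event,
                   protocol = x$protocol),
    x$summary)
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance
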