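#' Synthetic-trial configuration
#'
#' Parameters of the synthetic EEG generator, which emulates the
#' structure the pipeline assumes: trials of `cycles` gait cycles
#' (relax, start intention, gait, stop intention), 1/f background noise
#' on every recorded channel, sustained band-limited oscillators on the
#' analysis channels, and an event-related desynchronisation (ERD):
#' inside a window before each start/stop event the oscillator amplitude
#' on affected channels is scaled by `1 - depth` (or `1 + depth` for
#' synchronisation), strongest near Cz and decaying linearly with chord
#' distance from it.
#'
#' @param n_trials Number of trials (default 10, the healthy-subject
#'   count).
#' @param cycles Gait cycles per trial (default 4 -> 4 start + 4 stop
#'   events).
#' @param relax_s,gait_s Mean phase durations in seconds (default 10
#'   each, long enough to host both offline windows and their guard
#'   gap).
#' @param jitter_s Half-width of the uniform jitter on each phase
#'   duration (default 1).
#' @param tail_s Recording tail after the last stop event (default 3).
#' @param fs Sampling rate in Hz (default 500).
#' @param layout Electrode layout; its full montage is generated and its
#'   `feature_subset` carries the oscillators (default
#'   [standard_1010_layout()]).
#' @param background `list(exponent, rms_uv)`: 1/f spectral exponent and
#'   per-channel RMS in microvolts (defaults 1 and 10).
#' @param oscillators Named list per band: `list(freq_hz, rms_uv)`
#'   (defaults: alpha 10 Hz / 10 uV, beta 22 Hz / 10 uV, gamma 40 Hz /
#'   5 uV on the analysis channels, i.e. oscillator-to-background RMS 1
#'   for the ERD carriers).
#' @param erd `list(depth, lead_s, duration_s, bands, type)`: modulation
#'   depth in `[0, 1]`, window start `lead_s` seconds before each event,
#'   window length `duration_s` (defaults 0.8, 4, 4 so the modulation
#'   covers the 4 s of intention preceding the event), affected bands
#'   (default alpha and beta), and `type` "erd" (suppression) or "ers".
#' @param seed Base random seed (default 42).
#' @return A validated `synth_config` list.
#' @export
synth_config <- function(n_trials = 10, cycles = 4, relax_s = 10,
                         gait_s = 10, jitter_s = 1, tail_s = 3, fs = 500,
                         layout = standard_1010_layout(),
                         background = list(exponent = 1, rms_uv = 10),
                         oscillators = list(
                           alpha = list(freq_hz = 10, rms_uv = 10),
                           beta = list(freq_hz = 22, rms_uv = 10),
                           gamma = list(freq_hz = 40, rms_uv = 5)),
                         erd = list(depth = 0.8, lead_s = 4,
                                    duration_s = 4,
                                    bands = c("alpha", "beta"),
                                    type = "erd"),
                         seed = 42) {
  cfg <- list(n_trials = n_trials, cycles = cycles, relax_s = relax_s,
              gait_s = gait_s, jitter_s = jitter_s, tail_s = tail_s,
              fs = fs, layout = layout, background = background,
              oscillators = oscillators, erd = erd, seed = seed)
  if (erd$depth < 0 || erd$depth > 1) {
    stop_gaitbci("erd depth must lie in [0, 1]", "gaitbci_config_error")
  }
  # both phases must host an offline active window, its non-active
  # partner and the guard gap (2 x 4 s + 0.5 s) even at maximal jitter
  min_phase <- 8.5
  if (relax_s - jitter_s < min_phase || gait_s - jitter_s < min_phase) {
    stop_gaitbci(
      sprintf("phase durations minus jitter must be >= %.1f s", min_phase),
      "gaitbci_config_error")
  }
  if (erd$lead_s < 0 || erd$duration_s <= 0 ||
      erd$lead_s > min_phase || !all(erd$bands %in% names(oscillators))) {
    stop_gaitbci("invalid erd window or band specification",
                 "gaitbci_config_error")
  }
  structure(cfg, class = "synth_config")
}

# 1/f^exponent noise with target RMS, via spectral shaping of white noise
pink_noise <- function(n, fs, exponent, rms) {
  half <- floor(n / 2)
  f <- (1:half) * fs / n
  mag <- f^(-exponent / 2)
  phase <- stats::runif(half, 0, 2 * pi)
  spec <- complex(modulus = mag, argument = phase)
  full <- complex(real = numeric(n))
  full[2:(half + 1)] <- spec
  if (n %% 2 == 0) {
    full[half + 1] <- complex(real = mag[half], imaginary = 0)
    if (half > 1) full[n:(n - half + 2)] <- Conj(spec[1:(half - 1)])
  } else {
    full[n:(n - half + 1)] <- Conj(spec)
  }
  x <- Re(stats::fft(full, inverse = TRUE)) / n
  x * rms / stats::sd(x)
}

#' Generate one synthetic trial
#'
#' Fully reproducible from `trial_seed`: phase durations are jittered,
#' events placed at the relax-to-gait and gait-to-relax transitions, 1/f
#' background generated per channel, and band oscillators (with
#' event-locked amplitude modulation) added on the analysis channels.
#'
#' @param config A [synth_config()].
#' @param trial_seed Integer seed for this trial (defaults to
#'   `config$seed`).
#' @return An `eeg_trial` with `cycles` start and `cycles` stop events.
#' @export
generate_trial <- function(config, trial_seed = config$seed) {
  stopifnot(inherits(config, "synth_config"))
  set.seed(as.integer(trial_seed %% .Machine$integer.max),
           kind = "Mersenne-Twister")
  fs <- config$fs
  # phase schedule
  t <- 0
  starts <- numeric(0); stops <- numeric(0)
  for (cy in seq_len(config$cycles)) {
    t <- t + config$relax_s + stats::runif(1, -config$jitter_s,
                                           config$jitter_s)
    starts <- c(starts, t)
    t <- t + config$gait_s + stats::runif(1, -config$jitter_s,
                                          config$jitter_s)
    stops <- c(stops, t)
  }
  total_s <- t + config$tail_s
  n <- as.integer(ceiling(total_s * fs))
  tt <- (seq_len(n) - 1) / fs
  names_all <- config$layout$positions$name
  data <- t(vapply(names_all, function(ch)
    pink_noise(n, fs, config$background$exponent,
               config$background$rms_uv),
    numeric(n)))

  # per-channel modulation depth: linear decay with chord distance to Cz
  feat <- config$layout$feature_subset
  d <- electrode_distances(config$layout)
  w_cz <- stats::setNames(pmax(0, 1 - d[feat, "Cz"] / 2), feat)
  events <- sort(c(starts, stops))
  erd <- config$erd
  sign_mod <- if (identical(erd$type, "ers")) +1 else -1

  for (bn in names(config$oscillators)) {
    osc <- config$oscillators[[bn]]
    a0 <- osc$rms_uv * sqrt(2)
    affected <- bn %in% erd$bands
    for (ch in feat) {
      phase <- stats::runif(1, 0, 2 * pi)
      env <- rep(1, n)
      if (affected && erd$depth > 0) {
        dep <- erd$depth * w_cz[[ch]]
        for (e in events) {
          w0 <- e - erd$lead_s
          sel <- tt >= w0 & tt < w0 + erd$duration_s
          env[sel] <- 1 + sign_mod * dep
        }
      }
      data[ch, ] <- data[ch, ] +
        a0 * env * sin(2 * pi * osc$freq_hz * tt + phase)
    }
  }
  ev <- tibble::tibble(
    kind = rep(c("start", "stop"), each = config$cycles),
    time_s = c(starts, stops))
  new_trial(data, fs, names_all, ev)
}

#' Generate a synthetic dataset
#'
#' Independent trials (jittered phase schedules, fresh noise and
#' oscillator phases) from per-trial seeds `seed + 1, ..., seed +
#' n_trials`, with a manifest recording the seeds and event times.
#'
#' @param config A [synth_config()].
#' @return List with `trials` (list of `eeg_trial`) and `manifest`
#'   (tibble: `trial`, `seed`, `kind`, `time_s`).
#' @export
generate_dataset <- function(config) {
  stopifnot(inherits(config, "synth_config"))
  seeds <- config$seed + seq_len(config$n_trials)
  trials <- lapply(seeds, function(s) generate_trial(config, s))
  manifest <- purrr::map2_dfr(seq_along(trials), trials, function(i, tr) {
    dplyr::mutate(tr$events, trial = i, seed = seeds[i], .before = 1)
  })
  list(trials = trials, manifest = manifest)
}
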