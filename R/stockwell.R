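#' Discrete Stockwell transform
#'
#' Time-frequency decomposition with a frequency-scaled Gaussian window:
#' each frequency voice `n > 0` is the inverse DFT over `m` of
#' `X[m + n] * exp(-2 pi^2 m^2 / n^2)`, where `X` is the DFT of the
#' signal normalised by `1/N` (so a unit-amplitude cosine at an integer
#' bin has voice magnitude 0.5) and `m` is taken symmetric around zero.
#' The zero-frequency voice is the signal mean replicated over time.
#' Summing a voice over time recovers the raw DFT coefficient of the
#' signal at that bin (the transform's collapse property).
#'
#' @param x Numeric signal, length >= 4.
#' @param fs Sampling rate in Hz.
#' @param max_freq_hz Highest voice frequency to compute (default
#'   Nyquist).
#' @return An `st_voices` object: list with `S` (complex voices x time
#'   matrix, row 1 = DC), `freq_hz` (per-row voice frequencies), `fs`.
#' @export
stockwell_transform <- function(x, fs, max_freq_hz = fs / 2) {
  assert_finite(x, "signal")
  n <- length(x)
  if (n < 4) {
    stop_gaitbci("signal too short for the Stockwell transform",
                 "gaitbci_validation_error")
  }
  X <- stats::fft(x) / n
  nv <- min(floor(max_freq_hz * n / fs), floor(n / 2))
  ck <- st_cache_get(n, nv)
  Y <- matrix(X[ck$idx], nrow = n) * ck$G
  S_t <- stats::mvfft(Y, inverse = TRUE)  # time x voices
  S <- rbind(rep(mean(x), n), t(S_t))
  structure(list(S = S, freq_hz = (0:nv) * fs / n, fs = fs),
            class = "st_voices")
}

# Gaussian windows and circular-shift indices depend only on (n, nv);
# cache them because the pipeline transforms thousands of 500-sample
# epochs with identical geometry.
.st_cache <- new.env(parent = emptyenv())

st_cache_get <- function(n, nv) {
  key <- paste(n, nv, sep = "_")
  if (!is.null(.st_cache[[key]])) return(.st_cache[[key]])
  m <- 0:(n - 1)
  m_eff <- ifelse(m > n / 2, m - n, m)
  idx <- outer(m, seq_len(nv), function(m, v) (m + v) %% n + 1)
  G <- outer(m_eff, seq_len(nv),
             function(m, v) exp(-2 * pi^2 * m^2 / v^2))
  .st_cache[[key]] <- list(idx = idx, G = G)
  .st_cache[[key]]
}

#' @export
print.st_voices <- function(x, ...) {
  cat(sprintf("<st_voices: %d voices x %d samples @ %g Hz>\n",
              nrow(x$S), ncol(x$S), x$fs))
  invisible(x)
}

#' Stockwell energy spectrum
#'
#' Squared voice amplitudes mapped onto the shared 1-Hz time-frequency
#' grid used by the Hilbert-Huang path; the DC voice is excluded.
#'
#' @param voices An `st_voices` object.
#' @param bin_hz Grid bin width in Hz (default 1).
#' @param max_freq_hz Upper edge of the grid (default `fs / 2`).
#' @return A `tf_spectrum` (see [hilbert_spectrum()]).
#' @export
st_energy_spectrum <- function(voices, bin_hz = 1,
                               max_freq_hz = voices$fs / 2) {
  stopifnot(inherits(voices, "st_voices"))
  n_bins <- as.integer(round(max_freq_hz / bin_hz))
  n_t <- ncol(voices$S)
  grid <- matrix(0, n_bins, n_t)
  for (r in seq_along(voices$freq_hz)) {
    f <- voices$freq_hz[r]
    if (f <= 0) next
    b <- as.integer(round(f / bin_hz))
    if (b >= 1 && b <= n_bins) {
      grid[b, ] <- grid[b, ] + Mod(voices$S[r, ])^2
    }
  }
  new_tf_spectrum(grid, seq_len(n_bins) * bin_hz, voices$fs)
}

#' Stockwell band features for one epoch
#'
#' Per electrode: Stockwell transform, energy spectrum, marginal spectrum
#' over the 1-s epoch, then the peak marginal energy per half-open band.
#'
#' @inheritParams fft_band_features
#' @param max_freq_hz Highest voice frequency (default Nyquist).
#' @return Electrodes-by-bands matrix of non-negative features.
#' @export
st_band_features <- function(epoch, fs, bands = band_set(),
                             max_freq_hz = fs / 2) {
  epoch <- as.matrix(epoch)
  assert_finite(epoch, "epoch")
  out <- t(apply(epoch, 1, function(ch) {
    v <- stockwell_transform(ch, fs, max_freq_hz = max_freq_hz)
    h <- marginal_spectrum(st_energy_spectrum(v, max_freq_hz = max_freq_hz))
    band_peaks(h, bands)
  }))
  dimnames(out) <- list(rownames(epoch), names(bands))
  out
}
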