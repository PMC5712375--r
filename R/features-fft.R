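#' Frequency bands of interest
#'
#' Default analysis bands: alpha 8-13 Hz, beta 13-32 Hz (the
#' event-related desynchronisation/synchronisation carriers) and gamma
#' 32-50 Hz (attentive focus). Band intervals are half-open `[low, high)`
#' so adjacent bands at 13 and 32 Hz do not double-count a bin.
#'
#' @param bands Named list of `c(low, high)` pairs in Hz, ordered by low
#'   edge.
#' @param nyquist_hz Upper bound for validation (default 250).
#' @return A validated named list of band edges.
#' @export
band_set <- function(bands = list(alpha = c(8, 13), beta = c(13, 32),
                                  gamma = c(32, 50)),
                     nyquist_hz = 250) {
  lows <- vapply(bands, `[`, numeric(1), 1)
  highs <- vapply(bands, `[`, numeric(1), 2)
  if (any(lows <= 0) || any(highs <= lows) || any(highs > nyquist_hz)) {
    stop_gaitbci("bands must satisfy 0 < low < high <= Nyquist",
                 "gaitbci_validation_error")
  }
  if (is.unsorted(lows)) {
    stop_gaitbci("bands must be ordered by low edge",
                 "gaitbci_validation_error")
  }
  bands
}

#' One-sided power spectrum of an epoch
#'
#' Power per DFT bin, scaled so a unit-amplitude sinusoid at an integer
#' bin contributes 0.5 (its mean-square power): bin k in 1..N/2-1 gets
#' `2 |X_k|^2 / N^2`, DC and Nyquist get `|X_k|^2 / N^2`. Summing all
#' bins recovers the mean square of the signal (Parseval).
#'
#' @param x Numeric vector (one channel, one epoch).
#' @param fs Sampling rate in Hz.
#' @return Tibble with `freq_hz` and `power` columns.
#' @export
power_spectrum <- function(x, fs) {
  assert_finite(x, "epoch")
  n <- length(x)
  X <- stats::fft(x)
  half <- floor(n / 2)
  p <- Mod(X[1:(half + 1)])^2 / n^2
  scale <- rep(2, half + 1)
  scale[1] <- 1
  if (n %% 2 == 0) scale[half + 1] <- 1
  tibble::tibble(freq_hz = (0:half) * fs / n, power = p * scale)
}

#' FFT band-power features for one epoch
#'
#' Harmonic band content per electrode: the sum of one-sided DFT power
#' over the bins falling in each half-open band `[low, high)`. With 1-s
#' epochs at 500 Hz the bin spacing is 1 Hz, so a band like 8-13 Hz sums
#' bins 8..12.
#'
#' @param epoch Channels-by-samples numeric matrix (microvolts).
#' @param fs Sampling rate in Hz.
#' @param bands Band list from [band_set()].
#' @param statistic "power" (band sum, default) or "peak" (largest
#'   single-bin power in the band).
#' @return Electrodes-by-bands matrix of non-negative band features
#'   (microvolts squared), dimnames from epoch rownames and band names.
#' @export
fft_band_features <- function(epoch, fs, bands = band_set(),
                              statistic = c("power", "peak")) {
  statistic <- match.arg(statistic)
  epoch <- as.matrix(epoch)
  assert_finite(epoch, "epoch")
  out <- t(apply(epoch, 1, function(ch) {
    ps <- power_spectrum(ch, fs)
    vapply(bands, function(b) {
      sel <- ps$freq_hz >= b[1] & ps$freq_hz < b[2]
      if (statistic == "power") sum(ps$power[sel]) else max(ps$power[sel], 0)
    }, numeric(1))
  }))
  dimnames(out) <- list(rownames(epoch), names(bands))
  out
}
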