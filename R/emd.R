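#' Empirical Mode Decomposition
#'
#' Decomposes a signal into Intrinsic Mode Functions (IMFs) by sifting:
#' natural cubic splines through the local maxima and minima give upper
#' and lower envelopes, their mean is subtracted, and the process repeats
#' until the candidate satisfies (a) extrema and zero-crossing counts
#' differing by at most one, and (b) the Rilling amplitude criterion
#' (`sigma(t) = |mean envelope| / envelope amplitude` below `theta1` on at
#' least a `1 - alpha` fraction of samples and below `theta2` everywhere),
#' with both conditions held for `confirm_iters` consecutive sifting
#' iterations to avoid accidental modes. Extraction stops when the residue
#' has too few extrema to envelope (monotonic trend) or `max_imfs` is
#' reached. Extrema are mirror-extended (two per side) before spline
#' fitting to curb end effects.
#'
#' By construction the IMFs and residue sum back to the input exactly.
#'
#' @param x Numeric signal.
#' @param theta1,theta2,alpha Rilling stopping thresholds (defaults 0.05,
#'   0.5, 0.05).
#' @param confirm_iters Consecutive iterations the stopping conditions
#'   must hold (default 3).
#' @param max_imfs Safety cap on the number of IMFs (default 10).
#' @param max_sift Safety cap on sifting iterations per IMF (default 100).
#' @return List of class `imf_set`: `imfs` (list of numeric vectors),
#'   `residue`, `n` (signal length).
#' @export
emd <- function(x, theta1 = 0.05, theta2 = 0.5, alpha = 0.05,
                confirm_iters = 3, max_imfs = 10, max_sift = 100) {
  assert_finite(x, "signal")
  n <- length(x)
  if (n < 8) {
    stop_gaitbci("signal too short for EMD (need >= 8 samples)",
                 "gaitbci_validation_error")
  }
  imfs <- list()
  r <- x
  repeat {
    if (length(imfs) >= max_imfs) break
    ext <- local_extrema(r)
    if (length(ext$maxima) < 2 || length(ext$minima) < 2) break
    p <- r
    confirmed <- 0L
    for (it in seq_len(max_sift)) {
      ext <- local_extrema(p)
      if (length(ext$maxima) < 2 || length(ext$minima) < 2) break
      e_up <- spline_envelope(p, ext$maxima, n)
      e_lo <- spline_envelope(p, ext$minima, n)
      m <- (e_up + e_lo) / 2
      a <- (e_up - e_lo) / 2
      sigma <- abs(m) / pmax(abs(a), .Machine$double.eps)
      ok <- mean(sigma < theta1) >= 1 - alpha &&
        all(sigma < theta2) &&
        counts_balanced(p)
      confirmed <- if (ok) confirmed + 1L else 0L
      if (confirmed >= confirm_iters) break
      p <- p - m
    }
    imfs[[length(imfs) + 1]] <- p
    r <- r - p
  }
  structure(list(imfs = imfs, residue = r, n = n), class = "imf_set")
}

# indices of strict local maxima and minima (plateaus take their midpoint)
local_extrema <- function(x) {
  n <- length(x)
  if (n < 3) return(list(maxima = integer(), minima = integer()))
  d <- diff(x)
  # collapse exact plateaus so flat tops register one extremum
  s <- sign(d)
  idx <- which(s != 0)
  if (length(idx) < 2) return(list(maxima = integer(), minima = integer()))
  maxima <- integer(); minima <- integer()
  for (k in seq_len(length(idx) - 1)) {
    i <- idx[k]; j <- idx[k + 1]
    if (s[i] > 0 && s[j] < 0) maxima <- c(maxima, (i + j + 1) %/% 2)
    if (s[i] < 0 && s[j] > 0) minima <- c(minima, (i + j + 1) %/% 2)
  }
  list(maxima = maxima, minima = minima)
}

# natural cubic spline through the extrema, mirror-extending two extrema
# beyond each edge of the signal
spline_envelope <- function(x, idx, n) {
  k <- length(idx)
  take_l <- seq_len(min(2, k))
  take_r <- seq(k, by = -1, length.out = min(2, k))
  ti <- c(2 - idx[take_l], idx, 2 * n - idx[take_r])
  vi <- c(x[idx[take_l]], x[idx], x[idx[take_r]])
  o <- order(ti)
  ti <- ti[o]; vi <- vi[o]
  keep <- !duplicated(ti)
  stats::spline(ti[keep], vi[keep], xout = seq_len(n),
                method = "natural")$y
}

# IMF count condition: #extrema and #zero crossings differ by <= 1
counts_balanced <- function(x) {
  ext <- local_extrema(x)
  n_ext <- length(ext$maxima) + length(ext$minima)
  s <- sign(x)
  s <- s[s != 0]
  n_zc <- sum(diff(s) != 0)
  abs(n_ext - n_zc) <= 1
}

#' Huang orthogonality index of an IMF set
#'
#' Sum of pairwise IMF cross-products relative to the total signal energy;
#' near zero for a clean decomposition.
#'
#' @param decomp An `imf_set` from [emd()].
#' @return A single non-negative number (0 when fewer than 2 IMFs).
#' @export
imf_orthogonality <- function(decomp) {
  imfs <- decomp$imfs
  if (length(imfs) < 2) return(0)
  total <- Reduce(`+`, imfs) + decomp$residue
  denom <- sum(total^2)
  cross <- 0
  for (i in seq_along(imfs)) {
    for (j in seq_along(imfs)) {
      if (i != j) cross <- cross + sum(imfs[[i]] * imfs[[j]])
    }
  }
  abs(cross) / denom
}

#' Analytic signal of one IMF
#'
#' Hilbert-transform based analytic signal `z = imf + i H(imf)`, giving
#' the instantaneous amplitude `|z|`, unwrapped phase, and pulsation
#' (phase derivative by central differences, one-sided at the edges).
#'
#' @param imf Numeric signal (one IMF).
#' @param fs Sampling rate in Hz.
#' @return Tibble with columns `amplitude` (same units as input), `phase`
#'   (rad), `pulsation` (rad/s) and `freq_hz`.
#' @export
analytic_mode <- function(imf, fs) {
  assert_finite(imf, "imf")
  n <- length(imf)
  if (all(imf == 0)) {
    return(tibble::tibble(amplitude = rep(0, n), phase = rep(0, n),
                          pulsation = rep(0, n), freq_hz = rep(0, n)))
  }
  X <- stats::fft(imf)
  h <- numeric(n)
  if (n %% 2 == 0) {
    h[1] <- 1; h[2:(n / 2)] <- 2; h[n / 2 + 1] <- 1
  } else {
    h[1] <- 1; h[2:((n + 1) / 2)] <- 2
  }
  z <- stats::fft(X * h, inverse = TRUE) / n
  amp <- Mod(z)
  phase <- unwrap_phase(Arg(z))
  puls <- phase_gradient(phase) * fs
  tibble::tibble(amplitude = amp, phase = phase, pulsation = puls,
                 freq_hz = puls / (2 * pi))
}

unwrap_phase <- function(p) {
  d <- diff(p)
  jumps <- round(d / (2 * pi))
  p - 2 * pi * c(0, cumsum(jumps))
}

phase_gradient <- function(p) {
  n <- length(p)
  if (n < 2) return(rep(0, n))
  g <- numeric(n)
  g[1] <- p[2] - p[1]
  g[n] <- p[n] - p[n - 1]
  if (n > 2) g[2:(n - 1)] <- (p[3:n] - p[1:(n - 2)]) / 2
  g
}

#' Hilbert spectrum of a set of analytic modes
#'
#' Time-frequency energy grid `H(f, t)`: for each mode and sample, the
#' squared instantaneous amplitude is deposited into the 1-Hz-wide bin
#' whose centre is nearest the instantaneous frequency. Samples with
#' non-positive or out-of-range instantaneous frequency are discarded and
#' counted in attribute `n_dropped`.
#'
#' @param modes List of tibbles from [analytic_mode()], equal lengths.
#' @param fs Sampling rate in Hz.
#' @param bin_hz Frequency bin width (default 1).
#' @param max_freq_hz Upper edge of the grid (default `fs / 2`).
#' @return A `tf_spectrum`: list with `grid` (freq bins x time samples),
#'   `freq_hz` (bin centres), `fs`.
#' @export
hilbert_spectrum <- function(modes, fs, bin_hz = 1, max_freq_hz = fs / 2) {
  n_bins <- as.integer(round(max_freq_hz / bin_hz))
  freqs <- (seq_len(n_bins)) * bin_hz
  if (length(modes) == 0) {
    return(new_tf_spectrum(matrix(0, n_bins, 0), freqs, fs))
  }
  n_t <- nrow(modes[[1]])
  grid <- matrix(0, n_bins, n_t)
  dropped <- 0L
  for (m in modes) {
    stopifnot(nrow(m) == n_t)
    b <- as.integer(round(m$freq_hz / bin_hz))
    ok <- b >= 1 & b <= n_bins & m$freq_hz > 0
    dropped <- dropped + sum(!ok)
    if (any(ok)) {
      ij <- cbind(b[ok], which(ok))
      e <- m$amplitude[ok]^2
      for (r in seq_len(nrow(ij))) {
        grid[ij[r, 1], ij[r, 2]] <- grid[ij[r, 1], ij[r, 2]] + e[r]
      }
    }
  }
  out <- new_tf_spectrum(grid, freqs, fs)
  attr(out, "n_dropped") <- dropped
  out
}

new_tf_spectrum <- function(grid, freq_hz, fs) {
  structure(list(grid = grid, freq_hz = freq_hz, fs = fs),
            class = "tf_spectrum")
}

#' @export
print.tf_spectrum <- function(x, ...) {
  cat(sprintf("<tf_spectrum: %d freq bins x %d samples @ %g Hz>\n",
              nrow(x$grid), ncol(x$grid), x$fs))
  invisible(x)
}

#' Marginal spectrum of a time-frequency grid
#'
#' Integrates the energy grid over the epoch time span (rectangle rule,
#' step `1/fs`), giving per-frequency energy in units of microvolts
#' squared times seconds for a 1-s epoch.
#'
#' @param H A `tf_spectrum`.
#' @return Tibble with `freq_hz` and `energy`.
#' @export
marginal_spectrum <- function(H) {
  stopifnot(inherits(H, "tf_spectrum"))
  tibble::tibble(freq_hz = H$freq_hz,
                 energy = rowSums(H$grid) / H$fs)
}

#' Hilbert-Huang band features for one epoch
#'
#' Per electrode: EMD, analytic signal per IMF, Hilbert spectrum, marginal
#' spectrum, then the peak marginal energy within each band (half-open
#' `[low, high)`). Electrodes whose EMD yields no IMFs contribute zeros.
#'
#' @inheritParams fft_band_features
#' @param ... Passed on to [emd()] (thresholds, caps).
#' @return Electrodes-by-bands matrix of non-negative features.
#' @export
hht_band_features <- function(epoch, fs, bands = band_set(), ...) {
  epoch <- as.matrix(epoch)
  assert_finite(epoch, "epoch")
  out <- t(apply(epoch, 1, function(ch) {
    dec <- emd(ch, ...)
    if (length(dec$imfs) == 0) return(rep(0, length(bands)))
    modes <- lapply(dec$imfs, analytic_mode, fs = fs)
    h <- marginal_spectrum(hilbert_spectrum(modes, fs))
    band_peaks(h, bands)
  }))
  dimnames(out) <- list(rownames(epoch), names(bands))
  out
}

band_peaks <- function(h, bands) {
  vapply(bands, function(b) {
    sel <- h$freq_hz >= b[1] & h$freq_hz < b[2]
    if (!any(sel)) 0 else max(h$energy[sel])
  }, numeric(1))
}
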