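# Shared fixtures and independent oracles used across the suite.

# single-channel epoch matrix holding a pure tone
tone_epoch <- function(freq_hz, fs = 500, n = 500, amp = 1,
                       channel = "Cz", phase = 0) {
  t <- (seq_len(n) - 1) / fs
  matrix(amp * sin(2 * pi * freq_hz * t + phase), nrow = 1,
         dimnames = list(channel, NULL))
}

# three electrodes on the unit sphere with chord distances
# d(1,2) = 1, d(1,3) = 2 (angles 60 and 180 degrees from electrode 1)
layout_dist_1_2 <- function() {
  new_electrode_layout(tibble::tibble(
    name = c("e1", "e2", "e3"),
    x = c(0, sin(pi / 3), 0),
    y = c(0, 0, 0),
    z = c(1, cos(pi / 3), -1)))
}

# three electrodes with the two neighbours of e1 equidistant (chord 1)
layout_equidistant <- function() {
  new_electrode_layout(tibble::tibble(
    name = c("e1", "e2", "e3"),
    x = c(0, sin(pi / 3), 0),
    y = c(0, 0, sin(pi / 3)),
    z = c(1, cos(pi / 3), cos(pi / 3))))
}

# brute-force O(N^2) DFT, no fft() anywhere
brute_dft <- function(x) {
  n <- length(x)
  k <- 0:(n - 1)
  vapply(k, function(kk)
    sum(x * exp(-2i * pi * kk * k / n)), complex(1))
}

# brute-force O(N^2)-per-voice discrete Stockwell transform: direct
# summation of the shifted-spectrum formula with a symmetric Gaussian,
# using the brute-force DFT (independent of the fft-based path)
st_direct <- function(x, fs) {
  n <- length(x)
  X <- brute_dft(x) / n
  nv <- floor(n / 2)
  m <- 0:(n - 1)
  m_eff <- ifelse(m > n / 2, m - n, m)
  S <- matrix(0i, nv, n)
  for (v in seq_len(nv)) {
    Y <- X[(m + v) %% n + 1] * exp(-2 * pi^2 * m_eff^2 / v^2)
    for (tau in 0:(n - 1)) {
      S[v, tau + 1] <- sum(Y * exp(2i * pi * m * tau / n))
    }
  }
  S
}

# exhaustive-scan oracles for the pseudo-online run rules
oracle_detected <- function(outcomes, k = 5) {
  run <- 0
  for (o in outcomes) {
    run <- if (o) run + 1 else 0
    if (run >= k) return(TRUE)
  }
  FALSE
}

oracle_fp_count <- function(outcomes, k = 5) {
  count <- 0; run <- 0
  for (o in c(outcomes, TRUE)) {  # sentinel closes a trailing F-run
    if (!o) run <- run + 1
    else {
      if (run >= k) count <- count + 1
      run <- 0
    }
  }
  count
}

# small separable feature set for classifier tests
separable_features <- function(n_per_class = 40, seed = 7) {
  set.seed(seed)
  f1 <- matrix(rnorm(n_per_class * 3, mean = 0, sd = 0.3), ncol = 3)
  f2 <- matrix(rnorm(n_per_class * 3, mean = 4, sd = 0.3), ncol = 3)
  tibble::tibble(state = rep(c(0L, 1L), each = n_per_class),
                 a = c(f1[, 1], f2[, 1]), b = c(f1[, 2], f2[, 2]),
                 c = c(f1[, 3], f2[, 3]))
}

# minimal synthetic trial for protocol/io tests: known events, light data
tiny_trial <- function(duration_s = 30, fs = 100, n_ch = 2,
                       events = tibble::tibble(kind = c("start", "stop"),
                                               time_s = c(10, 20)),
                       seed = 11) {
  set.seed(seed)
  n <- duration_s * fs
  new_trial(matrix(rnorm(n_ch * n), n_ch), fs,
            paste0("ch", seq_len(n_ch)), events)
}
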