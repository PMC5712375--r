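fs <- 500
tt <- (0:499) / fs
interior <- 51:450  # central 80% of a 1-s epoch

test_that("EMD handles degenerate and clean inputs", {
  # monotone ramp: nothing to sift
  d <- emd(seq(0, 1, length.out = 500))
  expect_length(d$imfs, 0)
  expect_equal(d$residue, seq(0, 1, length.out = 500))
  # clean 10 Hz tone: first IMF is the tone
  x <- sin(2 * pi * 10 * tt)
  d <- emd(x)
  expect_gte(length(d$imfs), 1)
  expect_gte(cor(d$imfs[[1]][interior], x[interior]), 0.99)
  expect_error(emd(rnorm(4)), class = "gaitbci_validation_error")
})

test_that("EMD separates well-spaced tones and is complete", {
  hi <- sin(2 * pi * 25 * tt)
  lo <- sin(2 * pi * 5 * tt)
  d <- emd(hi + lo)
  expect_gte(length(d$imfs), 2)
  expect_gte(cor(d$imfs[[1]][interior], hi[interior]), 0.95)
  expect_gte(cor(d$imfs[[2]][interior], lo[interior]), 0.95)
  # Huang orthogonality index small on a clean two-tone input
  expect_lt(imf_orthogonality(d), 0.2)
  # completeness on random signals
  set.seed(23)
  for (rep in 1:10) {
    x <- rnorm(500)
    dx <- emd(x)
    rec <- Reduce(`+`, c(dx$imfs, list(dx$residue)))
    expect_lt(sqrt(mean((rec - x)^2)) / sqrt(mean(x^2)), 1e-9)
  }
})

test_that("analytic signal recovers amplitude and frequency", {
  x <- 2 * cos(2 * pi * 10 * tt)
  am <- analytic_mode(x, fs)
  expect_equal(am$amplitude[interior], rep(2, length(interior)),
               tolerance = 0.02)
  expect_equal(am$freq_hz[interior], rep(10, length(interior)),
               tolerance = 0.02)
  # zero signal
  z <- analytic_mode(rep(0, 500), fs)
  expect_equal(z$amplitude, rep(0, 500))
  # linear chirp 5 -> 20 Hz over 1 s
  f_inst <- 5 + 15 * tt
  chirp <- cos(2 * pi * (5 * tt + 7.5 * tt^2))
  ac <- analytic_mode(chirp, fs)
  rel <- abs(ac$freq_hz[interior] - f_inst[interior]) / f_inst[interior]
  expect_lt(max(rel), 0.05)
})

test_that("Hilbert and marginal spectra concentrate tone energy", {
  x <- 2 * sin(2 * pi * 10 * tt)
  H <- hilbert_spectrum(list(analytic_mode(x, fs)), fs)
  expect_equal(dim(H$grid), c(250, 500))
  expect_true(all(H$grid >= 0))
  # per-sample deposit ~ a^2 = 4 in the 10 Hz bin over the interior
  expect_equal(unname(H$grid[10, interior]), rep(4, length(interior)),
               tolerance = 0.05)
  expect_equal(sum(H$grid[-10, interior]), 0, tolerance = 1e-6)
  # empty mode list -> zero grid
  H0 <- hilbert_spectrum(list(), fs)
  expect_equal(ncol(H0$grid), 0)
  # marginal spectrum: rectangle-rule integral; unit tone integrates to 1
  h1 <- marginal_spectrum(
    hilbert_spectrum(list(analytic_mode(sin(2 * pi * 10 * tt), fs)), fs))
  expect_equal(h1$energy[h1$freq_hz == 10], 1, tolerance = 0.05)
  # linearity: doubling the grid doubles h
  H2 <- H
  H2$grid <- 2 * H$grid
  expect_equal(marginal_spectrum(H2)$energy,
               2 * marginal_spectrum(H)$energy)
  # total marginal energy matches the analytic-signal convention:
  # |a|^2 of a real narrowband signal is twice its mean square
  expect_equal(sum(marginal_spectrum(H)$energy), 2 * sum(x^2) / fs,
               tolerance = 0.05)
})

test_that("HHT band features pick the right band", {
  z <- hht_band_features(tone_epoch(0, amp = 0), fs)
  expect_equal(unname(z["Cz", ]), c(0, 0, 0))
  f10 <- hht_band_features(tone_epoch(10), fs)
  expect_gt(f10["Cz", "alpha"], 10 * f10["Cz", "beta"])
  expect_gt(f10["Cz", "alpha"], 10 * f10["Cz", "gamma"])
  f40 <- hht_band_features(tone_epoch(40), fs)
  expect_gt(f40["Cz", "gamma"], 10 * f40["Cz", "alpha"])
  expect_gt(f40["Cz", "gamma"], 10 * f40["Cz", "beta"])
})
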