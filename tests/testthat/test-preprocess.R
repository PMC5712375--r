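test_that("Laplacian weights follow inverse-distance normalisation", {
  # neighbours at chord distances 1 and 2 from e1: weights 2/3 and 1/3
  g <- laplacian_weights(layout_dist_1_2())
  expect_equal(g["e1", c("e2", "e3")], c(e2 = 2 / 3, e3 = 1 / 3))
  # equidistant neighbours split evenly
  g2 <- laplacian_weights(layout_equidistant())
  expect_equal(g2["e1", c("e2", "e3")], c(e2 = 0.5, e3 = 0.5))
  # rows always sum to one, zero diagonal, non-negative
  for (g_ in list(g, g2, laplacian_weights(standard_1010_layout()))) {
    expect_equal(unname(rowSums(g_)), rep(1, nrow(g_)), tolerance = 1e-9)
    expect_equal(unname(diag(g_)), rep(0, nrow(g_)))
    expect_true(all(g_ >= 0))
  }
})

test_that("Laplacian filter matches hand-computed references", {
  mk <- function(v) new_trial(matrix(v, 3, 1), 500, c("e1", "e2", "e3"))
  # equidistant neighbours 3 and 6: 10 - 4.5 = 5.5
  out <- laplacian_filter(mk(c(10, 3, 6)),
                          laplacian_weights(layout_equidistant()))
  expect_equal(unname(out$data["e1", 1]), 5.5)
  # neighbours at distances 1 and 2: 10 - (2/3*3 + 1/3*6) = 6
  out2 <- laplacian_filter(mk(c(10, 3, 6)),
                           laplacian_weights(layout_dist_1_2()))
  expect_equal(unname(out2$data["e1", 1]), 6)
  # spatially uniform field vanishes on every channel and sample
  lay <- standard_1010_layout()
  tru <- new_trial(matrix(7.3, 31, 50), 500, lay$positions$name)
  filt <- laplacian_filter(tru, laplacian_weights(lay))
  expect_true(max(abs(filt$data)) < 1e-9)
  # channel mismatch rejected
  expect_error(laplacian_filter(tiny_trial(),
                                laplacian_weights(layout_equidistant())),
               class = "gaitbci_validation_error")
})

test_that("Laplacian filter is linear", {
  lay <- layout_dist_1_2()
  g <- laplacian_weights(lay)
  set.seed(5)
  X <- matrix(rnorm(3 * 100), 3)
  Y <- matrix(rnorm(3 * 100), 3)
  mk <- function(m) new_trial(m, 500, c("e1", "e2", "e3"))
  lhs <- laplacian_filter(mk(2 * X - 3 * Y), g)$data
  rhs <- 2 * laplacian_filter(mk(X), g)$data -
    3 * laplacian_filter(mk(Y), g)$data
  expect_equal(lhs, rhs, tolerance = 1e-9)
})

test_that("Butterworth high-pass removes DC and passes the band", {
  # a 0.2 Hz filter settles over tens of seconds, so use a trial-length
  # signal and judge the interior; edge transients scale with the
  # removed offset
  fs <- 500
  t <- (0:(60 * fs - 1)) / fs
  ch <- "Cz"
  mk <- function(v) new_trial(matrix(v, 1), fs, ch)
  interior <- (10 * fs):(50 * fs)
  # constant rejected to < 1% of its amplitude
  const <- butterworth_highpass(mk(rep(42, length(t))))
  expect_lt(max(abs(const$data[1, interior])), 0.01 * 42)
  # 10 Hz amplitude preserved within 1%
  tone <- sin(2 * pi * 10 * t)
  hp <- butterworth_highpass(mk(tone))
  expect_equal(hp$data[1, interior], tone[interior], tolerance = 0.01)
  # DC offset + tone -> tone, residual < 1% of the offset
  both <- butterworth_highpass(mk(100 + tone))
  expect_lt(max(abs(both$data[1, interior] - tone[interior])), 0.01 * 100)
  # idempotent on band content above 1 Hz
  twice <- butterworth_highpass(hp)
  expect_equal(twice$data[1, interior], hp$data[1, interior],
               tolerance = 0.02)
  expect_error(butterworth_highpass(mk(1:5)),
               class = "gaitbci_validation_error")
})

test_that("channel selection subsets, reorders and is idempotent", {
  lay <- standard_1010_layout()
  tr <- new_trial(matrix(seq_len(31 * 4), 31), 500, lay$positions$name)
  nine <- select_channels(tr, lay$feature_subset)
  expect_equal(nine$channel_names, lay$feature_subset)
  expect_equal(nine$data["Cz", ], tr$data["Cz", ])
  expect_equal(select_channels(nine, lay$feature_subset), nine)
  expect_equal(select_channels(tr, tr$channel_names), tr)
  expect_error(select_channels(tr, "nope"),
               class = "gaitbci_validation_error")
})
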