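test_that("epoch scoring compares labels element-wise", {
  expect_equal(score_epochs(c(1, 0, 1), c(1, 0, 1)), rep(TRUE, 3))
  expect_equal(score_epochs(c(1, 0, 1), c(0, 1, 0)), rep(FALSE, 3))
  expect_equal(score_epochs(c(1, 0, 1), c(1, 1, 1)), c(TRUE, FALSE, TRUE))
  expect_error(score_epochs(1, c(1, 0)), class = "gaitbci_validation_error")
})

test_that("detection rules follow protocol-specific logic", {
  # offline: majority of T detects
  expect_true(active_window_detected(rep(c(TRUE, FALSE), c(9, 7)),
                                     "offline"))
  expect_false(active_window_detected(rep(c(TRUE, FALSE), c(7, 9)),
                                      "offline"))
  # pseudo-online: needs a run of >= 5 consecutive T
  expect_false(active_window_detected(
    c(rep(TRUE, 4), FALSE, rep(TRUE, 4)), "pseudo_online"))
  expect_true(active_window_detected(
    c(FALSE, rep(TRUE, 5), FALSE), "pseudo_online"))
  # offline non-active: at most one FP per window
  expect_equal(count_false_activations(rep(FALSE, 16), "offline"), 1L)
  expect_equal(count_false_activations(rep(c(FALSE, TRUE), 8), "offline"), 0L)
  # pseudo-online: one FP per maximal run of >= 5 F
  expect_equal(count_false_activations(rep(FALSE, 12), "pseudo_online"), 1L)
  expect_equal(count_false_activations(
    c(rep(FALSE, 5), TRUE, rep(FALSE, 6)), "pseudo_online"), 2L)
  expect_equal(count_false_activations(
    rep(FALSE, 12), "pseudo_online", fp_counting = "floor_div"), 2L)
})

test_that("run-based rules match exhaustive enumeration up to length 12", {
  for (len in 1:12) {
    for (code in 0:(2^len - 1)) {
      outcomes <- as.logical(bitwAnd(bitwShiftR(code, 0:(len - 1)), 1L))
      expect_identical(
        active_window_detected(outcomes, "pseudo_online"),
        oracle_detected(outcomes))
      expect_identical(
        count_false_activations(outcomes, "pseudo_online"),
        as.integer(oracle_fp_count(outcomes)))
    }
  }
})

test_that("indices reproduce worked ratios", {
  rec <- function(det, fp, mins, proto = "offline")
    list(n_events = 4, n_detected = det, n_false = fp,
         nonactive_min = mins, protocol = proto)
  # 1 of 4 events detected, no false activations
  i1 <- compute_indices(rec(1, 0, 4 * 4 / 60))
  expect_equal(i1$tpr, 25)
  expect_equal(i1$acc, 100)
  expect_equal(i1$fp_per_min, 0)
  # all detected
  i2 <- compute_indices(rec(4, 0, 4 * 4 / 60))
  expect_equal(c(i2$tpr, i2$acc), c(100, 100))
  # 4 true + 2 false over 0.5 min
  i3 <- compute_indices(rec(4, 2, 0.5))
  expect_equal(i3$acc, 100 * 4 / 6)
  expect_equal(i3$fp_per_min, 4)
  # nothing detected: Acc undefined
  i4 <- compute_indices(rec(0, 0, 0.5))
  expect_true(is.na(i4$acc))
  expect_error(compute_indices(rec(1, 0, 0)),
               class = "gaitbci_validation_error")
})

test_that("detect_events + evaluation_report wire counts through", {
  # two active, two non-active windows, hand-built outcomes
  epochs <- tibble::tibble(
    window_id = rep(1:4, each = 16),
    state = rep(c(0L, 1L, 0L, 1L), each = 16))
  outcomes <- c(rep(FALSE, 16),              # non-active: majority F -> 1 FP
                rep(c(TRUE, FALSE), c(9, 7)), # active: detected
                rep(TRUE, 16),               # non-active: clean
                rep(c(TRUE, FALSE), c(7, 9))) # active: missed
  windows <- tibble::tibble(window_id = 1:4,
                            t_begin = c(0, 5, 10, 15),
                            t_end = c(4, 9, 14, 19))
  rec <- detect_events(epochs, outcomes, windows, "offline")
  rep_ <- evaluation_report(rec)
  expect_equal(rep_$tpr, 50)
  expect_equal(rep_$acc, 50)
  expect_equal(rep_$fp_per_min, 1 / (8 / 60))
  expect_equal(rep_$fpr, rep_$fp_per_min * 4 / 60)
  expect_equal(rep_$wd,
               weighted_discriminator(50, 50, rep_$fp_per_min, 4 / 60))
})

test_that("WD reproduces printed worked examples", {
  expect_equal(weighted_discriminator(100, 100, 0, 4 / 60), 1.00)
  expect_equal(weighted_discriminator(87.50, 98.00, 0.38, 4 / 60), 0.91)
  expect_equal(weighted_discriminator(62.50, 100.00, 0.00, 1 / 60), 0.85)
  expect_equal(weighted_discriminator(100.00, 83.57, 5.14, 1 / 60), 0.82)
  expect_equal(weighted_discriminator(0, 0, 60, 1 / 60), -1.00)
  # ties round away from zero
  expect_equal(weighted_discriminator(81.25, 100, 0, 1 / 60), 0.93)
  expect_true(is.na(weighted_discriminator(50, NA, 0, 1 / 60)))
})

test_that("WD is bounded, extremal only at perfection, and monotone", {
  set.seed(53)
  for (i in 1:200) {
    tpr <- runif(1, 0, 100); acc <- runif(1, 0, 100)
    fp <- runif(1, 0, 15); dur <- sample(c(4 / 60, 1 / 60), 1)
    wd <- weighted_discriminator(tpr, acc, fp, dur, digits = NULL)
    expect_lte(wd, 1)
    if (fp * dur <= 1) expect_gte(wd, -1)
    # monotonicity by finite differences
    eps <- 1
    expect_gt(weighted_discriminator(tpr + eps, acc, fp, dur,
                                     digits = NULL), wd)
    expect_gt(weighted_discriminator(tpr, acc + eps, fp, dur,
                                     digits = NULL), wd)
    expect_lt(weighted_discriminator(tpr, acc, fp + eps, dur,
                                     digits = NULL), wd)
  }
  expect_equal(weighted_discriminator(100, 100, 0, 4 / 60, digits = NULL), 1)
  expect_lt(weighted_discriminator(99.9, 100, 0, 4 / 60, digits = NULL), 1)
})

test_that("aggregation averages defined indices and tracks NAs", {
  r <- tibble::tibble(tpr = c(100, 50), acc = c(100, NA),
                      fp_per_min = c(0, 3), fpr = c(0, 0.2),
                      wd = c(1, NA))
  a <- aggregate_reports(r)
  expect_equal(a$tpr, 75)
  expect_equal(a$acc, 100)     # NA excluded
  expect_equal(a$n_undefined_acc, 1L)
  # single report: itself, sd 0
  a1 <- aggregate_reports(r[1, ])
  expect_equal(a1$wd, 1)
  expect_equal(a1$wd_sd, 0)
  # mean WD equals WD of mean indices when all Acc defined (linearity)
  r2 <- tibble::tibble(tpr = c(80, 60), acc = c(90, 70),
                       fp_per_min = c(3, 1), fpr = c(0.2, 1 / 15),
                       wd = weighted_discriminator(c(80, 60), c(90, 70),
                                                   c(3, 1), 4 / 60,
                                                   digits = NULL))
  a2 <- aggregate_reports(r2)
  expect_equal(a2$wd,
               weighted_discriminator(a2$tpr, a2$acc, a2$fp_per_min,
                                      4 / 60, digits = NULL))
})
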