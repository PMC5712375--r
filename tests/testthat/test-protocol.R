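test_that("window placement follows the protocol rules", {
  tr <- tiny_trial(duration_s = 30, fs = 100,
                   events = tibble::tibble(kind = "start", time_s = 10))
  po <- build_windows(tr, "start", "pseudo_online")
  act <- po[po$state == 1, ]
  non <- po[po$state == 0, ]
  expect_equal(c(act$t_begin, act$t_end), c(8, 12))
  expect_equal(non$t_end, 7.5)
  expect_equal(non$t_begin, 0)   # whole preceding rest phase

  off <- build_windows(tr, "start", "offline")
  expect_equal(c(off$t_begin[off$state == 1], off$t_end[off$state == 1]),
               c(6, 10))
  expect_equal(c(off$t_begin[off$state == 0], off$t_end[off$state == 0]),
               c(1.5, 5.5))
})

test_that("a full trial yields 4 active and 4 non-active windows per model", {
  cfg <- synth_config(n_trials = 1)
  tr <- generate_trial(cfg, 1)
  for (kind in c("start", "stop")) {
    for (proto in c("offline", "pseudo_online")) {
      w <- build_windows(tr, kind, proto)
      expect_equal(sum(w$state == 1), 4)
      expect_equal(sum(w$state == 0), 4)
      expect_true(all(w$t_end > w$t_begin))
      # active windows last exactly 4 s
      expect_equal(unique(w$t_end[w$state == 1] - w$t_begin[w$state == 1]),
                   4)
      # gap of at least 0.5 s between paired non-active end / active start
      gaps <- w$t_begin[w$state == 1] - w$t_end[w$state == 0]
      expect_true(all(gaps >= 0.5 - 1e-9))
    }
  }
  # events whose windows fall before the recording start are dropped
  early <- new_trial(tr$data, tr$sample_rate, tr$channel_names,
                     tibble::tibble(kind = "start", time_s = 3))
  w <- build_windows(early, "start", "offline")
  expect_equal(nrow(w), 0)
  expect_equal(attr(w, "n_skipped"), 1L)
})

test_that("epoch slicing is exact: hop, count, containment", {
  tr <- tiny_trial(duration_s = 30, fs = 100,
                   events = tibble::tibble(kind = "start", time_s = 10))
  w <- tibble::tibble(window_id = 1:3, event_time = 10,
                      event_kind = "start", state = 1L,
                      t_begin = c(2, 5, 8), t_end = c(6, 6, 8.9),
                      protocol = "offline")
  ep <- slice_epochs(tr, w)
  # 4-s window: 16 epochs; 1-s window: 1; 0.9-s window: 0
  expect_equal(sum(ep$window_id == 1), 16)
  expect_equal(sum(ep$window_id == 2), 1)
  expect_equal(sum(ep$window_id == 3), 0)
  # consecutive epochs exactly 0.2 s apart, wholly inside the window
  t1 <- ep$t_begin[ep$window_id == 1]
  expect_equal(diff(t1), rep(0.2, 15))
  expect_true(all(t1 >= 2 & t1 + 1 <= 6 + 1e-9))
  # each epoch carries 100 samples (1 s at this fs) per channel
  expect_true(all(vapply(ep$data, ncol, integer(1)) == 100))
  # labels inherited from the window
  expect_true(all(ep$state == 1L))
})

test_that("split plans partition trials correctly", {
  loocv <- make_split(10, "offline")
  expect_equal(nrow(loocv), 10)
  for (k in 1:10) {
    expect_equal(sort(c(loocv$train[[k]], loocv$test[[k]])), 1:10)
    expect_length(loocv$train[[k]], 9)
  }
  # each trial is test exactly once
  expect_equal(sort(unlist(loocv$test)), 1:10)

  s64 <- make_split(10, "pseudo_online", c(6, 4))
  expect_equal(s64$train[[1]], 1:6)
  expect_equal(s64$test[[1]], 7:10)
  s43 <- make_split(7, "pseudo_online", c(4, 3))
  expect_equal(s43$train[[1]], 1:4)
  expect_equal(s43$test[[1]], 5:7)
  expect_error(make_split(5, "pseudo_online", c(6, 4)),
               class = "gaitbci_validation_error")
  expect_error(make_split(1, "offline"), class = "gaitbci_validation_error")
})

test_that("active and non-active epochs never overlap in time", {
  cfg <- synth_config(n_trials = 1)
  tr <- generate_trial(cfg, 2)
  w <- build_windows(tr, "start", "pseudo_online")
  ep <- slice_epochs(tr, w)
  act <- ep[ep$state == 1, ]
  non <- ep[ep$state == 0, ]
  for (i in seq_len(nrow(act))) {
    overlap <- non$t_begin < act$t_begin[i] + 1 &
      non$t_begin + 1 > act$t_begin[i]
    expect_false(any(overlap))
  }
})
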