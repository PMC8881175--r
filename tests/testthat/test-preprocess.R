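make_recording <- function(n_channels = 3, dur_s = 30, fs = 256,
                           events = NULL, data = NULL) {
  n <- dur_s * fs
  if (is.null(data)) data <- matrix(0, n_channels, n)
  eeg_recording(data, fs = fs, events = events)
}

test_that("high-pass filter kills DC and passes the band", {
  fs <- 256
  n <- 30 * fs
  t <- (0:(n - 1)) / fs
  dc <- matrix(5, 1, n)
  rec <- eeg_recording(dc, fs = fs)
  out <- highpass_filter(rec, cutoff = 1)
  mid <- 2000:(n - 2000)  # away from filter edges
  expect_lt(max(abs(out$data[1, mid])), 0.01 * 5)
  # 10 Hz sinusoid passes within 12%
  s <- matrix(sin(2 * pi * 10 * t), 1, n)
  outs <- highpass_filter(eeg_recording(s, fs = fs), cutoff = 1)
  expect_equal(max(abs(outs$data[1, mid])), 1, tolerance = 0.12)
  expect_error(highpass_filter(rec, cutoff = 200), "Nyquist")
})

test_that("filtered white noise stays near zero mean", {
  fs <- 256
  withr::with_seed(21, {
    x <- matrix(rnorm(30 * fs, sd = 2), 1)
    out <- highpass_filter(eeg_recording(x, fs = fs), cutoff = 1)
    expect_lt(abs(mean(out$data)), 0.1 * 2)
  })
})

test_that("linked-mastoid rereferencing subtracts the mastoid mean", {
  n <- 256
  data <- rbind(ch1 = rep(7, n), M1 = rep(2, n), M2 = rep(4, n))
  rec <- eeg_recording(data, fs = 256)
  out <- rereference_linked_mastoids(rec, c("M1", "M2"))
  expect_equal(out$data["ch1", ], rep(7 - 3, n))
  expect_equal(out$data["M1", ], rep(-1, n))
  # zero mastoids leave data unchanged
  data0 <- rbind(ch1 = rnorm(n), M1 = rep(0, n), M2 = rep(0, n))
  rec0 <- eeg_recording(data0, fs = 256)
  expect_equal(rereference_linked_mastoids(rec0, c("M1", "M2"))$data,
               rec0$data)
  # channels equal to the mastoid mean annihilate
  data1 <- matrix(3, 3, n, dimnames = list(c("a", "M1", "M2"), NULL))
  expect_true(all(rereference_linked_mastoids(
    eeg_recording(data1, 256), c("M1", "M2"))$data == 0))
  # common offset added to every channel does not change the result
  recb <- eeg_recording(data0 + 11, fs = 256)
  expect_equal(rereference_linked_mastoids(recb, c("M1", "M2"))$data,
               rereference_linked_mastoids(rec0, c("M1", "M2"))$data)
  expect_error(rereference_linked_mastoids(rec, c("M1", "nope")), "missing")
})

test_that("epoch extraction follows half-open sample arithmetic", {
  ev <- data.frame(time_ms = 1000, label = "stim")
  rec <- make_recording(events = ev)
  eps <- extract_epochs(rec, c(-100, 200))
  expect_length(eps, 1)
  expect_equal(ncol(eps[[1]]$data), 77)  # ceil(300 ms * 0.256)
  expect_equal(eps[[1]]$t0, -100)
  # events too close to the edge are dropped with a warning
  ev2 <- data.frame(time_ms = c(50, 1000, 2000), label = "s")
  rec2 <- make_recording(events = ev2)
  expect_warning(eps2 <- extract_epochs(rec2, c(-100, 200)), "dropped")
  expect_length(eps2, 2)
  # well-spaced events conserve count
  ev3 <- data.frame(time_ms = seq(500, 25000, by = 500), label = "s")
  expect_length(extract_epochs(make_recording(events = ev3), c(-100, 200)),
                nrow(ev3))
  # no events -> empty result, not an error
  expect_length(extract_epochs(make_recording(), c(-100, 200)), 0)
})

test_that("baseline correction zeroes the pre-stimulus mean and is idempotent", {
  ep <- eeg_epoch(matrix(5, 2, 77), fs = 256, t0 = -100)
  out <- baseline_correct(ep, c(-100, 0))
  expect_true(all(out$data == 0))
  # toy single channel: baseline samples {1, 3} -> subtract 2 everywhere
  d <- matrix(c(1, 3, 9, 9), 1, 4)
  ep2 <- eeg_epoch(d, fs = 1000, t0 = -2)
  out2 <- baseline_correct(ep2, c(-2, 0))
  expect_equal(as.vector(out2$data), c(-1, 1, 7, 7))
  # idempotent
  st <- small_study(n_trials = 1, seed = 8)
  ep3 <- st$noise[[1]]
  ep3$t0 <- -100
  once <- baseline_correct(ep3, c(-100, 0))
  twice <- baseline_correct(once, c(-100, 0))
  expect_equal(once$data, twice$data, tolerance = 1e-12)
  tt <- epoch_times(once)
  expect_equal(max(abs(rowMeans(once$data[, tt >= -100 & tt < 0]))), 0,
               tolerance = 1e-12)
  expect_error(baseline_correct(ep, c(300, 400)), "baseline")
})
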