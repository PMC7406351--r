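# The gammatone filter bank is the physiological receiver: 80 channels with
# fc_k = 5702 * 2^(k/20.9) Hz, order 4, b = 0.15 fc, envelope detection and
# de-chirp summation.

rp_fb <- receiver_params()
search_call <- list(dur_ms = 7, tf_khz = 39, bw_khz = 8)

test_that("centre frequencies span ~5.9-81 kHz and grow geometrically", {
  fc <- gammatone_fc(80)
  expect_length(fc, 80)
  expect_equal(fc[1], 5702 * 2^(1 / 20.9))
  expect_equal(fc[80] / 1000, 81, tolerance = 0.01)
  expect_equal(sd(diff(log(fc))), 0, tolerance = 1e-12)
})

test_that("a pure tone at a channel's fc excites that channel maximally", {
  fs <- 5e5
  fc <- gammatone_fc(80)
  j <- 40
  t <- seq(0, 0.004, by = 1 / fs)
  x <- sin(2 * pi * fc[j] * t)
  env <- gammatone_filterbank(x, fs, rp_fb)
  expect_equal(which.max(apply(env, 2, max)), j)
})

test_that("impulse-response envelope peaks near (n-1)/(2 pi b), earlier for higher fc", {
  fs <- 5e5
  x <- c(1, numeric(1500))
  env <- gammatone_filterbank(x, fs, rp_fb)
  fc <- attr(env, "fc")
  pk <- apply(env, 2, which.max) / fs
  pred <- (4 - 1) / (2 * pi * 0.15 * fc)    # closed-form gamma envelope peak
  ks <- c(10, 40, 70)
  for (k in ks) expect_lt(abs(pk[k] - pred[k]), pred[k] * 0.5 + 2e-5)
  expect_true(all(diff(pk[ks]) < 0))
})

test_that("with no maskers runs (a) and (b) agree: no jams, no false alarms", {
  ec <- data.frame(id = 1L, level_db = 40, arrival_s = 0.02, bearing_rad = 0)
  r <- filterbank_detect(search_call, ec, maskers = NULL, rp = rp_fb)
  expect_true(r$detections$detected)
  expect_false(r$detections$jammed)
  expect_false(r$false_alarm)
  expect_lt(abs(r$detections$time_error_s), 5e-4)
})

test_that("a loud masker overlapping the echo in time and band jams it", {
  ec <- data.frame(id = 1L, level_db = 12, arrival_s = 0.02, bearing_rad = 0)
  mk <- data.frame(level_db = 60, arrival_s = 0.0185, dur_ms = 7,
                   tf_khz = 39, bw_khz = 8, bearing_rad = 0.4)
  r <- filterbank_detect(search_call, ec, mk, rp = rp_fb)
  expect_true(r$detections$jammed)
  expect_false(r$detections$detected)
})

test_that("a masker alone above threshold and earliest produces a false alarm", {
  ec <- data.frame(id = 1L, level_db = 40, arrival_s = 0.03, bearing_rad = 0)
  mk <- data.frame(level_db = 45, arrival_s = 0.012, dur_ms = 7,
                   tf_khz = 39, bw_khz = 8, bearing_rad = 0.4)
  r <- filterbank_detect(search_call, ec, mk, rp = rp_fb)
  expect_true(r$false_alarm)
  expect_equal(r$fa_arrival_s, 0.012, tolerance = 1.5e-3)
})

test_that("false alarms are impossible when no masker exceeds the 7 dB threshold", {
  ec <- data.frame(id = 1L, level_db = 40, arrival_s = 0.03, bearing_rad = 0)
  mk <- data.frame(level_db = c(3, 5), arrival_s = c(0.012, 0.02), dur_ms = 7,
                   tf_khz = 39, bw_khz = 8, bearing_rad = 0)
  r <- filterbank_detect(search_call, ec, mk, rp = rp_fb)
  expect_false(r$false_alarm)
  expect_true(r$detections$detected)
})
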