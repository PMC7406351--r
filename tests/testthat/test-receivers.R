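# The masking-window truth table uses a masker chirp identical to the
# template, whose matched-filter peak therefore sits exactly at its arrival
# time at its own level (0 dB correlation penalty), so window membership and
# level margins can be controlled exactly.

search_call <- list(dur_ms = 7, tf_khz = 39, bw_khz = 8)

mk_row <- function(level, arrival) {
  data.frame(level_db = level, arrival_s = arrival, dur_ms = 7,
             tf_khz = 39, bw_khz = 8, bearing_rad = 0)
}
echo_row <- function(level = 30, arrival = 0.02) {
  data.frame(id = 1L, level_db = level, arrival_s = arrival, bearing_rad = 0)
}

test_that("prefilter drops sub-threshold signals, monotonically in the threshold", {
  sig <- data.frame(level_db = c(-5, 2, 10, 35))
  expect_equal(nrow(prefilter_audible(sig, 0)), 3)
  expect_equal(nrow(prefilter_audible(sig, 30)), 1)
  expect_lte(nrow(prefilter_audible(sig, 30)), nrow(prefilter_audible(sig, 0)))
  empty <- sig[0, , drop = FALSE]
  expect_equal(nrow(prefilter_audible(empty)), 0)
})

test_that("forward/backward masking windows and thresholds form the exact truth table", {
  ec <- echo_row(level = 30, arrival = 0.02)
  cases <- list(
    # masker peak 2 ms before the echo, 3 dB below self: within the 5 dB
    # forward margin -> jammed
    list(mk = mk_row(27, 0.018), jam = TRUE),
    # 2 ms before but 6 dB below self: outside the margin -> clean
    list(mk = mk_row(24, 0.018), jam = FALSE),
    # 5 ms before the echo: outside the 3 ms window at any level -> clean
    list(mk = mk_row(80, 0.015), jam = FALSE),
    # 0.5 ms after, 1 dB below self: backward threshold is 0 dB -> clean
    list(mk = mk_row(29, 0.0205), jam = FALSE),
    # 0.5 ms after, at self level: jammed
    list(mk = mk_row(30, 0.0205), jam = TRUE),
    # 2 ms after: outside the 1 ms backward window -> clean
    list(mk = mk_row(80, 0.022), jam = FALSE)
  )
  for (cs in cases) {
    r <- correlation_receiver(search_call, ec, cs$mk)
    expect_equal(r$jammed, cs$jam)
    expect_equal(r$detected, !cs$jam)
  }
})

test_that("with zero conspecifics jamming probability is exactly zero", {
  ec <- data.frame(id = 1:4, level_db = c(10, 25, 40, 3),
                   arrival_s = c(0.01, 0.02, 0.03, 0.04), bearing_rad = 0)
  r <- correlation_receiver(search_call, ec, maskers = NULL)
  expect_false(any(r$jammed))
  expect_true(all(r$detected))
})

test_that("sub-hearing-threshold signals neither mask nor get detected", {
  ec <- echo_row(level = -2)
  r <- correlation_receiver(search_call, ec, mk_row(80, 0.019))
  expect_false(r$audible)
  expect_false(r$detected)
  ec2 <- echo_row(level = 30)
  r2 <- correlation_receiver(search_call, ec2, mk_row(-1, 0.019))
  expect_false(r2$jammed)  # inaudible masker never jams
})

test_that("SNR follows the matched-filter definition and falls with interference", {
  expect_equal(snr(30, NULL, 0), 30)
  expect_lt(snr(30, 20, 0), 30)
  expect_equal(snr(30, NULL, 10), 20)
  ec <- echo_row(level = 30)
  r_clean <- correlation_receiver(search_call, ec, NULL)
  r_mask <- correlation_receiver(search_call, ec, mk_row(24, 0.018))
  expect_equal(r_clean$snr_db, 30)
  expect_lt(r_mask$snr_db, r_clean$snr_db)
})

test_that("call-duration variant gates detection at the 15 dB correlation threshold", {
  call8 <- list(dur_ms = 8, tf_khz = 39, bw_khz = 8)
  at <- correlation_receiver(call8, echo_row(level = 15), NULL,
                             duration_experiment = TRUE)
  expect_true(at$detected)   # an 8 ms call at threshold level just passes
  below <- correlation_receiver(call8, echo_row(level = 14.5), NULL,
                                duration_experiment = TRUE)
  expect_false(below$detected)
  # a shorter call needs proportionally more level (10 log10(dur/8))
  call2 <- list(dur_ms = 2, tf_khz = 39, bw_khz = 8)
  expect_false(correlation_receiver(call2, echo_row(level = 16), NULL,
                                    duration_experiment = TRUE)$detected)
  expect_true(correlation_receiver(call2, echo_row(level = 22), NULL,
                                   duration_experiment = TRUE)$detected)
})

test_that("range error: 0.85 cm timing floor and 1.31 cm at 10 dB SNR", {
  floor_m <- 0.5 * 343 * 50e-6
  expect_equal(floor_m, 0.008575)             # the printed 0.85 cm, rounded
  expect_equal(floor_m * 100, 0.85, tolerance = 0.01)
  expect_equal(range_error_sd(1e9), floor_m, tolerance = 1e-9)
  expect_equal(range_error_sd(10), sqrt(0.01^2 + floor_m^2), tolerance = 1e-12)
  expect_equal(range_error_sd(10) * 100, 1.31, tolerance = 0.01)
  s <- range_error_sd(seq(1, 60, by = 1))
  expect_true(all(diff(s) <= 0))
  set.seed(4)
  est <- range_estimate(rep(2, 2e4), 10)
  expect_equal(mean(est), 2, tolerance = 1e-3)
  expect_equal(sd(est), range_error_sd(10), tolerance = 0.05)
})

test_that("DOA error anchors: 1.5 deg on-axis, 10 deg at 90 deg, 1 deg noise at 10 dB", {
  deg <- pi / 180
  expect_equal(doa_error_sd(0, 1e9), 1.5 * deg, tolerance = 1e-9)
  expect_equal(doa_error_sd(pi / 2, 1e9), 10 * deg, tolerance = 1e-9)
  expect_equal(doa_error_sd(0, 10), sqrt(1^2 + 1.5^2) * deg, tolerance = 1e-12)
  s <- doa_error_sd(0.3, seq(1, 60))
  expect_true(all(diff(s) <= 0))
  set.seed(5)
  est <- doa_estimate(rep(0.2, 2e4), 20)
  expect_equal(mean(est), 0.2, tolerance = 2e-3)
})
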