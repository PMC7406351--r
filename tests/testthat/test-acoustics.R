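# Independent step-by-step evaluations of the level equations, written
# longhand against the constants, serve as oracles for the vectorized
# implementations.

test_that("piston gain: boresight limit, first null, symmetry and back lobe", {
  f <- 39e3
  expect_equal(piston_gain(0, f, role = "mouth"), 1)
  lam <- 343 / f
  g0_ear <- 4 * pi * (pi * 0.007^2) / lam^2
  expect_equal(piston_gain(0, f, role = "ear"), g0_ear, tolerance = 1e-12)
  # first zero of J1 found by root-finding, independent of the implementation
  x0 <- uniroot(function(x) besselJ(x, 1), c(3, 4.5), tol = 1e-12)$root
  expect_equal(x0, 3.8317, tolerance = 1e-4)
  phi0 <- asin(x0 / (2 * pi * f / 343 * 0.007))
  expect_lt(piston_gain(phi0, f, role = "ear") / g0_ear, 1e-10)
  # symmetric about boresight
  expect_equal(piston_gain(0.4, f, role = "ear"), piston_gain(-0.4, f, role = "ear"))
  # at 180 degrees sin(phi) = 0: the piston value returns to G0, minus the
  # full 20 dB back-hemisphere penalty
  expect_equal(10 * log10(piston_gain(pi, f, role = "mouth")), -20, tolerance = 1e-9)
  # halfway into the back hemisphere: 10 dB penalty
  expect_equal(piston_gain(3 * pi / 4, f, role = "mouth") /
                 piston_gain(pi / 4, f, role = "mouth"),
               10^(-1), tolerance = 1e-9)
})

test_that("atmospheric attenuation matches the printed substitutions and is increasing", {
  expect_equal(atmospheric_attenuation(40e3), 1.22)
  expect_equal(atmospheric_attenuation(20e3), 0.46)
  f <- seq(20e3, 80e3, by = 5e3)
  expect_true(all(diff(atmospheric_attenuation(f)) > 0))
})

test_that("disc target strength scales as A^2 / lambda^2", {
  lam <- 343 / 39e3
  expect_equal(disc_target_strength(0.02, lam),
               4 * pi * (pi * 0.02^2)^2 / lam^2, tolerance = 1e-12)
  expect_equal(disc_target_strength(0.04, lam) / disc_target_strength(0.02, lam), 16)
  expect_equal(disc_target_strength(0.02, lam / 2) / disc_target_strength(0.02, lam), 4)
})

test_that("own echo level matches a term-by-term hand evaluation and 2D/c delay", {
  f <- 39e3; D <- 1.7; phi <- 0.3; SL <- 110
  lam <- 343 / f; k <- 2 * pi / lam
  j <- function(a) (2 * besselJ(k * a * sin(phi), 1) / (k * a * sin(phi)))^2
  gt <- 1 * j(0.003)
  gr <- (4 * pi * pi * 0.007^2 / lam^2) * j(0.007)
  sigma <- 4 * pi * (pi * 0.02^2)^2 / lam^2
  alpha <- 3.8e-2 * 39 - 0.3
  lvl <- SL + 10 * log10(gt * gr * lam^2 * sigma / ((4 * pi)^3 * D^4)) -
    2 * alpha * (D - 0.1)
  e <- own_echo(SL, f, D, phi)
  expect_equal(e$level_db, lvl, tolerance = 1e-9)
  expect_equal(e$delay_s, 2 * D / 343)
  expect_equal(own_echo(110, f, 3.43, 0)$delay_s, 0.02)
  expect_error(own_echo(110, f, -1, 0), "invalid")
})

test_that("far-field spreading loses 12 dB per doubling of distance", {
  f <- 39e3; alpha <- atmospheric_attenuation(f)
  l1 <- own_echo(110, f, 2, 0)$level_db + 2 * alpha * (2 - 0.1)
  l2 <- own_echo(110, f, 4, 0)$level_db + 2 * alpha * (4 - 0.1)
  expect_equal(l1 - l2, 40 * log10(2), tolerance = 1e-9)
})

test_that("conspecific call level matches the one-way hand oracle and exceeds the echo", {
  f <- 39e3; D <- 1; SL <- 110
  lam <- 343 / f
  gr0 <- 4 * pi * pi * 0.007^2 / lam^2
  lvl <- SL + 10 * log10(1 * gr0 * (lam / (4 * pi * D))^2) -
    atmospheric_attenuation(f) * (D - 0.1)
  cc <- conspecific_call(SL, f, D, 0, 0)
  expect_equal(cc$level_db, lvl, tolerance = 1e-9)
  expect_equal(cc$delay_s, D / 343)
  # the one-way call is far louder than the two-way echo off a 2 cm disc at
  # the same range: the basis of jamming being stronger than desired echoes
  expect_gt(cc$level_db, own_echo(SL, f, D, 0)$level_db + 15)
})

test_that("bistatic conspecific echo: hand oracle, monostatic limit, below direct call", {
  f <- 39e3; SL <- 110
  lam <- 343 / f
  gt <- 1; gr0 <- 4 * pi * pi * 0.007^2 / lam^2
  sigma <- 4 * pi * (pi * 0.02^2)^2 / lam^2
  dtx <- 2.2; drx <- 1.4
  lvl <- SL + 10 * log10(gt * gr0 * lam^2 * sigma / ((4 * pi)^3 * dtx^2 * drx^2)) -
    atmospheric_attenuation(f) * (dtx + drx - 0.2)
  ce <- conspecific_echo(SL, f, dtx, drx, 0, 0)
  expect_equal(ce$level_db, lvl, tolerance = 1e-9)
  expect_equal(ce$delay_s, (dtx + drx) / 343)
  # transmitter = receiver reduces exactly to the monostatic sonar equation
  mono <- conspecific_echo(SL, f, 1.7, 1.7, 0.25, 0.25)
  expect_equal(mono$level_db, own_echo(SL, f, 1.7, 0.25)$level_db, tolerance = 1e-9)
  # weaker than the direct conspecific call over the same total path
  expect_lt(conspecific_echo(SL, f, 1, 1, 0, 0)$level_db,
            conspecific_call(SL, f, 2, 0, 0)$level_db)
})

test_that("levels decrease monotonically with distance beyond the reference", {
  f <- 39e3
  d <- seq(0.2, 8, by = 0.2)
  expect_true(all(diff(own_echo(110, f, d, 0)$level_db) < 0))
  expect_true(all(diff(conspecific_call(110, f, d, 0, 0)$level_db) < 0))
})

test_that("border clutter: power sum, frontal sector, and offset scaling", {
  ar <- arena()
  cl <- clutter_sum(5, 5, 0.3, ar, 110, 40e3, ts_offset_db = 0)
  expect_true(all(abs(cl$point_bearing_rad) <= pi / 2 + 1e-9))
  expect_gte(cl$level_db, max(cl$point_level_db))   # non-coherent sum property
  cl20 <- clutter_sum(5, 5, 0.3, ar, 110, 40e3, ts_offset_db = 20)
  expect_equal(cl20$level_db - cl$level_db, 20, tolerance = 1e-9)
  # from the arena centre, baseline clutter is weak against a 1 m prey echo
  expect_lt(cl$level_db, own_echo(110, 40e3, 1, 0)$level_db)
})
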