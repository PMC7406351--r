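test_that("jamming probability counts pursued-prey echoes only", {
  # the worked group-hunt example: 64 pursued echoes, 8 jammed
  calls <- data.frame(focal_audible = rep(TRUE, 64),
                      focal_jammed = c(rep(TRUE, 8), rep(FALSE, 56)),
                      phase = "search")
  expect_equal(jamming_probability(calls), 0.125)
  # non-focal (inaudible) echoes never enter the denominator
  calls2 <- rbind(calls, data.frame(focal_audible = rep(FALSE, 100),
                                    focal_jammed = FALSE, phase = "search"))
  expect_equal(jamming_probability(calls2), 0.125)
  # no pursued echoes -> undefined
  expect_true(is.na(jamming_probability(calls2[calls2$focal_audible == FALSE, ])))
})

test_that("jamming probability equals a brute-force recount from raw logs", {
  set.seed(8)
  n <- 500
  calls <- data.frame(
    focal_audible = runif(n) < 0.7,
    focal_jammed = FALSE,
    phase = sample(c("search", "approach", "buzz1", "buzz2"), n, TRUE)
  )
  calls$focal_jammed[calls$focal_audible] <- runif(sum(calls$focal_audible)) < 0.2
  # independent replay: loop over rows and count
  num <- den <- 0
  for (k in seq_len(n)) {
    if (calls$focal_audible[k]) {
      den <- den + 1
      if (calls$focal_jammed[k]) num <- num + 1
    }
  }
  expect_equal(jamming_probability(calls), num / den)
  bp <- jamming_probability(calls, by_phase = TRUE)
  for (ph in bp$phase) {
    sub <- calls[calls$phase == ph, ]
    expect_equal(bp$p_jam[bp$phase == ph],
                 sum(sub$focal_jammed & sub$focal_audible) / sum(sub$focal_audible))
  }
})

test_that("masking effect is the percent reduction against the null condition", {
  expect_equal(masking_effect(0.5, 0.5), 0)
  expect_equal(masking_effect(0.26, 0.34), 100 * (1 - 0.26 / 0.34))
  expect_equal(masking_effect(0.26, 0.34), 23.5, tolerance = 0.1)
  expect_lt(masking_effect(0.6, 0.5), 0)  # can be negative
  expect_error(masking_effect(0.2, 0), "non-zero")
})

test_that("delta-method ratio SD matches the formula and a Monte-Carlo oracle", {
  expect_equal(ratio_sd(2, 0, 4, 0)$sd, 0)
  r <- ratio_sd(3, 0.3, 3, 0.3)     # u = v in distribution: cv 0.1 each
  expect_equal(r$mean, 1)
  expect_equal(r$sd, sqrt(2) * 0.1, tolerance = 1e-12)
  set.seed(10)
  u <- rnorm(2e5, 2, 0.1); v <- rnorm(2e5, 4, 0.3)
  mc <- sd(u / v)
  expect_lt(abs(ratio_sd(2, 0.1, 4, 0.3)$sd - mc) / mc, 0.05)
})

test_that("emergent frequency shift reflects phase composition, not repertoires", {
  solo <- data.frame(tf_khz = c(rep(39, 80), rep(19, 20)),
                     bw_khz = c(rep(8, 80), rep(20, 20)),
                     phase = c(rep("search", 80), rep("buzz2", 20)))
  # identical composition -> zero shift
  expect_equal(emergent_frequency_shift(solo, solo), 0)
  # a group with fewer terminal-buzz calls has a higher average frequency
  group <- data.frame(tf_khz = c(rep(39, 95), rep(19, 5)),
                      bw_khz = c(rep(8, 95), rep(20, 5)),
                      phase = c(rep("search", 95), rep("buzz2", 5)))
  expect_gt(emergent_frequency_shift(solo, group), 0)
  # log-replay oracle: phase-stratified recomputation of the same quantity
  f <- function(df) sum(tapply(df$tf_khz + df$bw_khz / 2, df$phase, sum)) / nrow(df)
  expect_equal(emergent_frequency_shift(solo, group),
               (f(group) - f(solo)) * 1000, tolerance = 1e-9)
  expect_equal(emergent_frequency_shift(solo, group, measure = "terminal"),
               (mean(group$tf_khz) - mean(solo$tf_khz)) * 1000)
})

test_that("attempt outcome fractions are exhaustive and sum to one", {
  att <- data.frame(outcome = c("capture", "miss", "miss", "lost_to_conspecific",
                                "conspecific_avoidance", "obstacle_avoidance"))
  fr <- attempt_outcome_fractions(att)
  expect_equal(sum(fr), 1)
  expect_equal(unname(fr["miss"]), 2 / 6)
  expect_named(fr, c("capture", "conspecific_avoidance", "lost_to_conspecific",
                     "obstacle_avoidance", "miss"))
})
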