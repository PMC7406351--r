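test_that("trials are deterministic given (config, seed)", {
  cfg <- scenario_config(n_bats = 2, n_prey = 5, regime = "random",
                         trial_seconds = 3)
  a <- run_trial(cfg, seed = 123)
  b <- run_trial(cfg, seed = 123)
  expect_identical(a$calls, b$calls)
  expect_identical(a$attempts, b$attempts)
  c <- run_trial(cfg, seed = 124)
  expect_false(identical(a$calls, c$calls))
})

test_that("invalid configurations are rejected with a message", {
  expect_error(scenario_config(n_bats = 0), "n_bats")
  expect_error(scenario_config(n_prey = 0), "n_prey")
  expect_error(scenario_config(dt = 0), "dt")
  expect_error(scenario_config(clutter_ts_offset_db = 50), "clutter")
  expect_error(run_trial(list(n_bats = 1)), "scenario_config")
  expect_error(run_grid(scenario_config(), sweep = list(bogus = 1:2)),
               "unknown sweep key")
})

test_that("trial invariants: positions inside arena, valid probabilities and phases", {
  cfg <- scenario_config(n_bats = 3, n_prey = 8, regime = "random",
                         trial_seconds = 4)
  tr <- run_trial(cfg, seed = 31)
  ar <- cfg$arena
  expect_true(all(tr$calls$x >= 0 & tr$calls$x <= ar$width))
  expect_true(all(tr$calls$y >= 0 & tr$calls$y <= ar$height))
  expect_true(all(tr$calls$phase %in% c("search", "approach", "buzz1", "buzz2")))
  expect_true(all(tr$calls$ipi_s >= 0.005 - 1e-9 & tr$calls$ipi_s <= 0.1 + 1e-9))
  pj <- tr$summary$jamming_probability
  expect_true(is.na(pj) || (pj >= 0 && pj <= 1))
  if (nrow(tr$attempts)) {
    fr <- attempt_outcome_fractions(tr$attempts)
    expect_equal(sum(fr), 1)
  }
  # decision loop runs once per IPI: consecutive emissions of a bat are
  # separated by that call's inter-pulse interval (up to tick rounding)
  for (b in 1:3) {
    cb <- tr$calls[tr$calls$bat == b, ]
    gaps <- diff(cb$t)
    expect_true(all(abs(gaps - head(cb$ipi_s, -1)) <= cfg$dt + 1e-9))
  }
})

test_that("search-phase terminal frequency is fixed per bat when the JAR is off", {
  for (reg in c("identical", "random")) {
    tr <- run_trial(scenario_config(n_bats = 3, n_prey = 5, regime = reg,
                                    trial_seconds = 3), seed = 17)
    sc <- tr$calls[tr$calls$phase == "search", ]
    per_bat <- tapply(sc$tf_khz, sc$bat, function(x) length(unique(x)))
    expect_true(all(per_bat == 1))
    if (reg == "identical") expect_true(all(sc$tf_khz == 39))
  }
})

test_that("a single bat with masking on never experiences jamming", {
  tr <- run_trial(scenario_config(n_bats = 1, n_prey = 5, trial_seconds = 4),
                  seed = 9)
  expect_false(any(tr$calls$focal_jammed))
  expect_equal(jamming_probability(tr$calls), 0)
})

test_that("grid runner sweeps declared keys and derives independent seeds", {
  base <- scenario_config(n_bats = 1, n_prey = 4, trial_seconds = 2)
  g <- run_grid(base, sweep = list(n_bats = c(1, 2)), replicates = 2, seed = 5)
  expect_equal(nrow(g$trials), 4)
  expect_equal(sort(unique(g$trials$n_bats)), c(1, 2))
  expect_equal(anyDuplicated(g$trials$seed), 0)
  # empty sweep runs the base scenario alone
  g1 <- run_grid(base, replicates = 2, seed = 5)
  expect_equal(nrow(g1$trials), 2)
  expect_equal(nrow(g$bats), sum(g$trials$n_bats))
})

test_that("metrics replayed from raw logs match the trial summary", {
  tr <- run_trial(scenario_config(n_bats = 2, n_prey = 6, regime = "random",
                                  trial_seconds = 4), seed = 77)
  rm_ <- replay_metrics(tr$calls, tr$attempts, trial_seconds = 4)
  s <- tr$summary
  expect_equal(rm_$jamming_probability, s$jamming_probability)
  expect_equal(rm_$captures_per_bat_10s, s$captures_per_bat_10s)
  expect_equal(rm_$attempts_per_bat_10s, s$attempts_per_bat_10s)
  expect_equal(rm_$outcome_fractions, s$outcome_fractions)
})

test_that("the filter-bank receiver runs end to end and classifies outcomes", {
  tr <- run_trial(scenario_config(n_bats = 2, n_prey = 4,
                                  receiver = "filterbank", regime = "random",
                                  trial_seconds = 1.5), seed = 21)
  expect_true(nrow(tr$calls) > 10)
  far <- tr$summary$false_alarm_rate
  expect_true(far >= 0 && far <= 1)
})
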