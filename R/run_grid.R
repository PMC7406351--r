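#' Run a grid of scenarios
#'
#' Expands a sweep specification over scenario parameters, runs `replicates`
#' trials per cell with independent seeds derived from the master seed, and
#' returns tidy per-trial and per-bat tables. Only declared scenario keys may
#' be swept.
#'
#' @param base A [scenario_config()] supplying every non-swept parameter.
#' @param sweep Named list of parameter value vectors, e.g.
#'   `list(n_bats = c(1, 5, 20))`. Allowed keys: `n_bats`, `n_prey`,
#'   `regime`, `receiver`, `masking`, `source_level_db`,
#'   `search_call_duration_ms`, `hearing_threshold_db`,
#'   `clutter_ts_offset_db`, `trial_seconds`. An empty sweep runs the base
#'   scenario alone.
#' @param replicates Trials per cell.
#' @param seed Master seed; per-trial seeds are drawn from it, so cells and
#'   replicates are mutually independent but the whole grid is reproducible.
#' @param keep_trials If `TRUE`, attach the full trial objects (memory-heavy).
#' @return List of class `echojam_grid` with `trials` (one row per trial:
#'   cell parameters, seed, summary statistics), `bats` (one row per
#'   bat-trial) and optionally `results` (trial objects).
#' @export
run_grid <- function(base, sweep = list(), replicates = 3, seed = 1,
                     keep_trials = FALSE) {
  allowed <- c("n_bats", "n_prey", "regime", "receiver", "masking",
               "source_level_db", "search_call_duration_ms",
               "hearing_threshold_db", "clutter_ts_offset_db", "trial_seconds")
  bad <- setdiff(names(sweep), allowed)
  if (length(bad)) stop("unknown sweep key(s): ", paste(bad, collapse = ", "))
  cells <- if (length(sweep)) expand.grid(sweep, stringsAsFactors = FALSE)
  else data.frame(.single = 1)[, 0, drop = FALSE]
  n_cells <- max(1L, nrow(cells))
  set.seed(seed)
  seeds <- matrix(sample.int(.Machine$integer.max - 1, n_cells * replicates),
                  n_cells, replicates)
  trials <- list(); bats <- list(); objs <- list()
  r <- 0L
  for (ci in seq_len(n_cells)) {
    cfg <- base
    if (ncol(cells)) for (nm in names(cells)) cfg[[nm]] <- cells[[nm]][ci]
    cfg <- do.call(scenario_config, cfg[setdiff(names(cfg), c("seed", "duration_experiment"))])
    for (rep_i in seq_len(replicates)) {
      r <- r + 1L
      tr <- run_trial(cfg, seed = seeds[ci, rep_i])
      s <- tr$summary
      row <- data.frame(cell = ci, replicate = rep_i, seed = seeds[ci, rep_i],
                        n_bats = cfg$n_bats, n_prey = cfg$n_prey,
                        regime = cfg$regime, receiver = cfg$receiver,
                        masking = cfg$masking,
                        source_level_db = cfg$source_level_db,
                        hearing_threshold_db = cfg$hearing_threshold_db,
                        captures_per_bat_10s = s$captures_per_bat_10s,
                        attempts_per_bat_10s = s$attempts_per_bat_10s,
                        jamming_probability = s$jamming_probability,
                        jam_search = s$jamming_by_phase$p_jam[1],
                        jam_approach = s$jamming_by_phase$p_jam[2],
                        false_alarm_rate = s$false_alarm_rate,
                        n_attempts = s$n_attempts)
      trials[[r]] <- row
      b <- s$bats
      b$cell <- ci; b$replicate <- rep_i
      b$n_bats <- cfg$n_bats; b$n_prey <- cfg$n_prey
      b$masking <- cfg$masking; b$regime <- cfg$regime
      bats[[r]] <- b
      if (keep_trials) objs[[r]] <- tr
    }
  }
  structure(list(trials = do.call(rbind, trials), bats = do.call(rbind, bats),
                 results = if (keep_trials) objs, seed = seed),
            class = "echojam_grid")
}

#' Recompute summary metrics from a per-call event log
#'
#' Replays the metrics from raw logs, independent of the accumulators used
#' during the simulation - the jamming probability, per-phase jamming, false
#' alarm rate and outcome fractions are recounted from the `calls` and
#' `attempts` tables alone.
#'
#' @param calls Per-call log (as in a trial's `calls` element or its CSV
#'   export).
#' @param attempts Attempt log.
#' @param trial_seconds Trial length used for rate normalization.
#' @return A list of recomputed metrics.
#' @export
replay_metrics <- function(calls, attempts, trial_seconds = 15) {
  nb <- length(unique(calls$bat))
  list(
    jamming_probability = jamming_probability(calls),
    jamming_by_phase = jamming_probability(calls, by_phase = TRUE),
    false_alarm_rate = mean(calls$false_alarm, na.rm = TRUE),
    outcome_fractions = attempt_outcome_fractions(attempts),
    captures_per_bat_10s =
      sum(attempts$outcome == "capture") / nb / (trial_seconds / 10),
    attempts_per_bat_10s = nrow(attempts) / nb / (trial_seconds / 10),
    mean_center_freq_khz = mean(call_frequency(calls, "center"))
  )
}
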