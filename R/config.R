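#' Scenario configuration
#'
#' All tunable parameters of a simulation trial. Defaults reproduce the
#' baseline study conditions: a 10 x 10 m arena, 0.5-ms simulation step,
#' search source level 110 dB-SPL at 0.1 m, 0 dB-SPL hearing threshold,
#' correlation receiver, identical call repertoires and no background
#' clutter.
#'
#' @param n_bats Number of bats (>= 1).
#' @param n_prey Number of prey (>= 1); constant within a trial (captured
#'   prey respawn immediately).
#' @param regime Frequency-assignment regime: `"identical"`, `"random"` or
#'   `"jar"` (random draws plus the active jamming avoidance response).
#' @param receiver `"correlation"` or `"filterbank"`.
#' @param masking If `FALSE`, the sensory no-masking null condition: bats
#'   detect prey as if alone (no masking signals are processed) but still
#'   avoid conspecifics and compete for prey.
#' @param source_level_db Search-call source level, dB-SPL at 0.1 m; the
#'   lower-phase levels shift by the same offset from the 110 dB default.
#' @param search_call_duration_ms Search-call duration (ms); changing it from
#'   the default 7 ms switches detection to the template-correlation
#'   threshold rule of the call-duration experiment unless
#'   `duration_experiment` is set explicitly.
#' @param hearing_threshold_db Auditory threshold, dB-SPL (0-30).
#' @param clutter_ts_offset_db Border-clutter target-strength offset in dB
#'   (0-40), or `NULL` for no clutter (the default study condition).
#' @param trial_seconds Simulated trial length (s). Metrics are normalized
#'   per 10 s.
#' @param dt Simulation step (s).
#' @param arena An [arena()].
#' @param duration_experiment Logical; force the 15 dB-SPL correlation
#'   detection-threshold variant on or off.
#' @param seed Optional integer seed recorded and used by [run_trial()].
#' @return A validated list of class `scenario_config`.
#' @export
scenario_config <- function(n_bats = 1, n_prey = 10,
                            regime = c("identical", "random", "jar"),
                            receiver = c("correlation", "filterbank"),
                            masking = TRUE,
                            source_level_db = 110,
                            search_call_duration_ms = 7,
                            hearing_threshold_db = 0,
                            clutter_ts_offset_db = NULL,
                            trial_seconds = 15,
                            dt = 5e-4,
                            arena = echojam::arena(),
                            duration_experiment = NULL,
                            seed = NULL) {
  regime <- match.arg(regime)
  receiver <- match.arg(receiver)
  if (!is.numeric(n_bats) || n_bats < 1 || n_bats != round(n_bats))
    stop("n_bats must be a positive integer")
  if (!is.numeric(n_prey) || n_prey < 1 || n_prey != round(n_prey))
    stop("n_prey must be a positive integer")
  if (dt <= 0) stop("dt must be positive")
  if (trial_seconds <= 0) stop("trial_seconds must be positive")
  if (!is.null(clutter_ts_offset_db) &&
      (clutter_ts_offset_db < 0 || clutter_ts_offset_db > 40))
    stop("clutter_ts_offset_db must lie in [0, 40]")
  if (is.null(duration_experiment))
    duration_experiment <- search_call_duration_ms != 7
  structure(list(
    n_bats = as.integer(n_bats), n_prey = as.integer(n_prey),
    regime = regime, receiver = receiver, masking = isTRUE(masking),
    source_level_db = source_level_db,
    search_call_duration_ms = search_call_duration_ms,
    hearing_threshold_db = hearing_threshold_db,
    clutter_ts_offset_db = clutter_ts_offset_db,
    trial_seconds = trial_seconds, dt = dt, arena = arena,
    duration_experiment = isTRUE(duration_experiment),
    seed = seed
  ), class = "scenario_config")
}

#' @export
print.scenario_config <- function(x, ...) {
  cat(sprintf(
    "scenario: %d bat(s), %d prey, %s regime, %s receiver, masking %s, %g s\n",
    x$n_bats, x$n_prey, x$regime, x$receiver,
    ifelse(x$masking, "on", "off"), x$trial_seconds))
  invisible(x)
}
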