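#' Jamming probability of pursued-prey echoes
#'
#' The fraction of echoes from the hunted (focal) prey that were blocked by
#' masking signals - explicitly not the fraction of jammed echoes among all
#' detected echoes, since each call can return several prey echoes but at
#' most one is pursued. The focal prey of a call is the bat's committed
#' target, or the closest audible prey while searching. Only audible
#' (pre-masking) focal echoes enter the denominator.
#'
#' @param calls A per-call log data frame with logical columns
#'   `focal_audible`, `focal_jammed` and (for `by_phase`) a `phase` column.
#' @param by_phase If `TRUE`, return one probability per phase as well.
#' @return The overall probability (scalar, `NA` if no pursued echoes), or a
#'   data frame with per-phase rows when `by_phase = TRUE`.
#' @export
jamming_probability <- function(calls, by_phase = FALSE) {
  p_of <- function(df) {
    den <- sum(df$focal_audible, na.rm = TRUE)
    if (den == 0) return(NA_real_)
    sum(df$focal_jammed & df$focal_audible, na.rm = TRUE) / den
  }
  if (!by_phase) return(p_of(calls))
  phases <- c("search", "approach", "buzz1", "buzz2")
  data.frame(phase = phases,
             p_jam = vapply(phases, function(ph)
               p_of(calls[calls$phase == ph, , drop = FALSE]), numeric(1)),
             n_echoes = vapply(phases, function(ph)
               sum(calls$focal_audible[calls$phase == ph], na.rm = TRUE),
               numeric(1)),
             row.names = NULL)
}

#' Masking effect
#'
#' Percent reduction of hunting performance relative to the no-masking null
#' condition: `100 * (1 - masked / unmasked)`. Negative values occur when the
#' masked performance estimate exceeds the unmasked one (possible at high
#' hearing thresholds where both are small and noisy).
#'
#' @param perf_masked Performance with masking.
#' @param perf_unmasked Performance without masking (> 0).
#' @return Masking effect in percent.
#' @export
masking_effect <- function(perf_masked, perf_unmasked) {
  if (any(perf_unmasked == 0)) stop("unmasked performance must be non-zero")
  100 * (1 - perf_masked / perf_unmasked)
}

#' Delta-method mean and SD of a ratio
#'
#' First-order (delta-method) moments of `u / v` for independent numerator
#' and denominator: mean `Eu / Ev` and SD
#' `Eu/Ev * sqrt(sd_u^2/Eu^2 + sd_v^2/Ev^2)`. Used to attach an SD to the
#' masking effect, which is a ratio of two noisy performance estimates.
#'
#' @param mean_u,sd_u Moments of the numerator.
#' @param mean_v,sd_v Moments of the denominator (`mean_v` non-zero).
#' @return List with `mean` and `sd` of the ratio.
#' @export
ratio_sd <- function(mean_u, sd_u, mean_v, sd_v) {
  if (mean_v == 0) stop("denominator mean must be non-zero")
  m <- mean_u / mean_v
  list(mean = m, sd = abs(m) * sqrt(sd_u^2 / mean_u^2 + sd_v^2 / mean_v^2))
}

#' Emitted call frequency
#'
#' Helper returning the frequency of each logged call in kHz under a chosen
#' measure: `"center"` (mean of the linear sweep, `terminal + bandwidth/2` -
#' the call's average frequency) or `"terminal"`.
#'
#' @param calls Per-call log with `tf_khz` and `bw_khz` columns.
#' @param measure `"center"` or `"terminal"`.
#' @return Numeric vector, kHz.
#' @export
call_frequency <- function(calls, measure = c("center", "terminal")) {
  measure <- match.arg(measure)
  if (measure == "center") calls$tf_khz + calls$bw_khz / 2 else calls$tf_khz
}

#' Emergent frequency shift of bats flying in groups
#'
#' With the JAR disabled, compares the mean frequency of the calls emitted in
#' group trials against solo trials (group minus solo, in Hz). Any positive
#' shift is emergent: it arises purely from the different behavioral-phase
#' composition near conspecifics (more search and avoidance calls, fewer
#' completed buzzes), not from an active frequency shift. The default
#' measure is the call's average (sweep-centre) frequency; the terminal
#' frequency is available but is dominated by the 19-kHz final-buzz calls.
#'
#' @param solo_calls Per-call log of solo trials.
#' @param group_calls Per-call log of group trials.
#' @param measure `"center"` (default) or `"terminal"`.
#' @return Shift in Hz (group minus solo).
#' @export
emergent_frequency_shift <- function(solo_calls, group_calls,
                                     measure = c("center", "terminal")) {
  (mean(call_frequency(group_calls, measure)) -
     mean(call_frequency(solo_calls, measure))) * 1000
}

#' Attempt-outcome fractions
#'
#' Fractions of capture attempts ending in each outcome of the exhaustive
#' taxonomy: capture, conspecific avoidance, prey lost to a conspecific,
#' obstacle (border) avoidance, and miss (insufficient maneuver or sensory
#' loss, including jamming).
#'
#' @param attempts Attempt log with an `outcome` column.
#' @return Named numeric vector of fractions summing to 1 (all zero/NaN if no
#'   attempts).
#' @export
attempt_outcome_fractions <- function(attempts) {
  lv <- c("capture", "conspecific_avoidance", "lost_to_conspecific",
          "obstacle_avoidance", "miss")
  tab <- table(factor(attempts$outcome, levels = lv))
  as.numeric(tab) / max(1, nrow(attempts)) -> fr
  names(fr) <- lv
  if (nrow(attempts) == 0) fr[] <- NA_real_
  fr
}

#' Summarize a trial
#'
#' Trial-level statistics: per-bat capture and attempt rates (per 10 s),
#' jamming probability overall and per phase, false-alarm rate, outcome
#' fractions, and mean emitted frequency.
#'
#' @param trial A result of [run_trial()].
#' @return A list of class `echojam_summary`; its `bats` element is a data
#'   frame with one row per bat.
#' @export
trial_summary <- function(trial) {
  calls <- trial$calls; att <- trial$attempts
  dur10 <- trial$config$trial_seconds / 10
  nb <- trial$config$n_bats
  per_bat <- data.frame(
    bat = seq_len(nb),
    captures_per_10s = vapply(seq_len(nb), function(b)
      sum(att$bat == b & att$outcome == "capture") / dur10, numeric(1)),
    attempts_per_10s = vapply(seq_len(nb), function(b)
      sum(att$bat == b) / dur10, numeric(1))
  )
  structure(list(
    bats = per_bat,
    captures_per_bat_10s = mean(per_bat$captures_per_10s),
    attempts_per_bat_10s = mean(per_bat$attempts_per_10s),
    jamming_probability = jamming_probability(calls),
    jamming_by_phase = jamming_probability(calls, by_phase = TRUE),
    false_alarm_rate = mean(calls$false_alarm, na.rm = TRUE),
    outcome_fractions = attempt_outcome_fractions(att),
    mean_center_freq_khz = mean(call_frequency(calls, "center")),
    mean_terminal_freq_khz = mean(call_frequency(calls, "terminal")),
    n_attempts = nrow(att)
  ), class = "echojam_summary")
}

#' @export
print.echojam_summary <- function(x, ...) {
  cat(sprintf("captures/bat/10s: %.2f   attempts/bat/10s: %.2f\n",
              x$captures_per_bat_10s, x$attempts_per_bat_10s))
  cat(sprintf("jamming probability (pursued echoes): %s\n",
              ifelse(is.na(x$jamming_probability), "NA",
                     sprintf("%.3f", x$jamming_probability))))
  fr <- x$outcome_fractions
  cat("attempt outcomes:",
      paste(sprintf("%s %.0f%%", names(fr), 100 * fr), collapse = ", "), "\n")
  invisible(x)
}
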