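#' Receiver parameters
#'
#' Parameters shared by the two auditory receiver models. The hearing
#' threshold (0 dB-SPL) gates which signals enter processing at all
#' ("pre-masking echoes"); the forward/backward masking windows and
#' thresholds implement the law of the first wave-front for the correlation
#' receiver; the filter-bank adds an 80-channel gammatone front end with a
#' 7 dB-SPL detection threshold on the de-chirped sum.
#'
#' @param hearing_threshold_db Auditory threshold, dB-SPL.
#' @param forward_window_s Forward masking window (masker before echo), s.
#' @param forward_threshold_db Forward detection threshold, dB: a masker
#'   correlation peak within the forward window jams the echo if it exceeds
#'   the self peak minus this margin.
#' @param backward_window_s Backward masking window (masker after echo), s.
#' @param backward_threshold_db Backward detection threshold, dB.
#' @param fb_threshold_db Filter-bank detection threshold on the de-chirped
#'   channel sum, dB-SPL.
#' @param n_channels Number of gammatone channels.
#' @param filter_order Gammatone filter order n.
#' @param b_factor Gammatone time constant as a fraction of the channel
#'   centre frequency (b = 0.15 fc).
#' @param corr_threshold_db Detection threshold of the chirp-correlation
#'   detection variant used in the call-duration experiment, dB-SPL,
#'   normalized so an 8-ms search call at this level just passes.
#' @param noise_db Ambient noise level, dB-SPL (the denominator floor of the
#'   SNR).
#' @param fs Waveform synthesis sample rate, Hz.
#' @param envelope Envelope detector of the filter-bank: `"lowpass"`
#'   (full-wave rectification + low-pass) or `"halfwave"` (half-wave
#'   rectification + 10 kHz low-pass).
#' @return A list of class `receiver_params`.
#' @export
receiver_params <- function(hearing_threshold_db = 0,
                            forward_window_s = 3e-3, forward_threshold_db = 5,
                            backward_window_s = 1e-3, backward_threshold_db = 0,
                            fb_threshold_db = 7, n_channels = 80,
                            filter_order = 4, b_factor = 0.15,
                            corr_threshold_db = 15, noise_db = 0, fs = 5e5,
                            envelope = c("lowpass", "halfwave")) {
  stopifnot(forward_window_s > 0, backward_window_s > 0)
  structure(list(hearing_threshold_db = hearing_threshold_db,
                 forward_window_s = forward_window_s,
                 forward_threshold_db = forward_threshold_db,
                 backward_window_s = backward_window_s,
                 backward_threshold_db = backward_threshold_db,
                 fb_threshold_db = fb_threshold_db,
                 n_channels = n_channels, filter_order = filter_order,
                 b_factor = b_factor, corr_threshold_db = corr_threshold_db,
                 noise_db = noise_db, fs = fs,
                 envelope = match.arg(envelope)),
            class = "receiver_params")
}

#' Drop signals below the auditory threshold
#'
#' Signals must cross the hearing threshold to take part in detection or
#' masking at all; survivors are the "pre-masking" echoes and the audible
#' maskers.
#'
#' @param signals Data frame with a `level_db` column (may be empty).
#' @param threshold_db Auditory threshold, dB-SPL.
#' @return The audible subset of `signals`.
#' @export
prefilter_audible <- function(signals, threshold_db = 0) {
  if (is.null(signals) || !nrow(signals)) return(signals)
  signals[signals$level_db >= threshold_db, , drop = FALSE]
}

#' Matched-filter (correlation) receiver
#'
#' The optimal-receiver reference model. For every audible echo of the bat's
#' own call the receiver compares the self-correlation peak (the echo through
#' its matched filter) against the cross-correlation peak of every audible
#' masker with the same template. A masker whose correlation peak falls
#' within 3 ms before the echo jams it if the peak exceeds the self peak
#' minus the 5 dB forward threshold; within 1 ms after the echo the margin is
#' 0 dB. Maskers outside both windows never interfere. Border clutter jams an
#' echo when the power sum of the clutter points falling inside the reception
#' window is at least as loud as the echo. The correlation receiver assumes
#' the bat discriminates prey echoes from maskers, so maskers are never
#' target candidates here.
#'
#' @param call List with the emitted call's `dur_ms`, `tf_khz`, `bw_khz`.
#' @param echoes Data frame of own-call prey echoes: columns `id`,
#'   `level_db`, `arrival_s`, `bearing_rad`.
#' @param maskers Optional data frame of masking signals: columns `level_db`,
#'   `arrival_s`, `dur_ms`, `tf_khz`, `bw_khz` (chirp parameters of the
#'   masking call).
#' @param clutter Optional [clutter_sum()] result (per-point delays/levels).
#' @param rp [receiver_params()].
#' @param duration_experiment If `TRUE`, detection additionally requires the
#'   template-correlation statistic `level + 10 log10(dur / 8 ms)` to exceed
#'   `corr_threshold_db` (15 dB-SPL), the detection rule of the call-duration
#'   experiment.
#' @return A data frame, one row per input echo: `id`, `level_db`,
#'   `arrival_s`, `bearing_rad`, `audible`, `jammed`, `detected`, `snr_db`,
#'   `masker_tf_khz` (terminal frequency of the strongest jamming masker, NA
#'   if none).
#' @export
correlation_receiver <- function(call, echoes, maskers = NULL, clutter = NULL,
                                 rp = receiver_params(),
                                 duration_experiment = FALSE) {
  n <- if (is.null(echoes)) 0L else nrow(echoes)
  out <- .fast_df(id = if (n) echoes$id else integer(),
                  level_db = if (n) echoes$level_db else numeric(),
                  arrival_s = if (n) echoes$arrival_s else numeric(),
                  bearing_rad = if (n) echoes$bearing_rad else numeric(),
                  audible = logical(n), jammed = logical(n),
                  detected = logical(n), snr_db = rep(NA_real_, n),
                  masker_tf_khz = rep(NA_real_, n))
  if (!n) return(out)
  out$audible <- echoes$level_db >= rp$hearing_threshold_db

  mk <- maskers
  if (!is.null(mk) && nrow(mk))
    mk <- mk[mk$level_db >= rp$hearing_threshold_db, , drop = FALSE]
  have_mk <- !is.null(mk) && nrow(mk) > 0

  peak_db <- peak_t <- NULL
  if (have_mk) {
    peak_db <- numeric(nrow(mk)); peak_t <- numeric(nrow(mk))
    for (j in seq_len(nrow(mk))) {
      xc <- chirp_xcorr_peak(call, list(dur_ms = mk$dur_ms[j],
                                        tf_khz = mk$tf_khz[j],
                                        bw_khz = mk$bw_khz[j]))
      peak_db[j] <- mk$level_db[j] + xc$ratio_db
      peak_t[j] <- mk$arrival_s[j] + xc$lag_s
    }
  }

  for (i in seq_len(n)) {
    if (!out$audible[i]) next
    self_db <- echoes$level_db[i]
    arr <- echoes$arrival_s[i]
    cross_lin <- 0
    jam <- FALSE; jam_tf <- NA_real_; jam_lvl <- -Inf
    if (have_mk) {
      dtp <- peak_t - arr
      fwd <- dtp >= -rp$forward_window_s & dtp <= 0
      bwd <- dtp > 0 & dtp <= rp$backward_window_s
      inwin <- fwd | bwd
      if (any(inwin)) cross_lin <- max(10^(peak_db[inwin] / 20))
      jam_f <- fwd & peak_db >= self_db - rp$forward_threshold_db
      jam_b <- bwd & peak_db >= self_db - rp$backward_threshold_db
      hits <- which(jam_f | jam_b)
      if (length(hits)) {
        jam <- TRUE
        k <- hits[which.max(peak_db[hits])]
        jam_tf <- mk$tf_khz[k]; jam_lvl <- peak_db[k]
      }
    }
    if (!is.null(clutter)) {
      din <- clutter$point_delay_s - arr
      inwin <- din >= -rp$forward_window_s & din <= rp$backward_window_s
      if (any(inwin)) {
        cl_db <- 10 * log10(sum(10^(clutter$point_level_db[inwin] / 10)))
        cross_lin <- max(cross_lin, 10^(cl_db / 20))
        if (cl_db >= self_db && cl_db > jam_lvl) {
          jam <- TRUE
          jam_tf <- call$tf_khz   # clutter is an echo of the bat's own call
        }
      }
    }
    out$jammed[i] <- jam
    out$masker_tf_khz[i] <- jam_tf
    out$snr_db[i] <- snr(self_db, cross_db = if (cross_lin > 0)
      20 * log10(cross_lin) else NULL, noise_db = rp$noise_db)
    detected <- !jam
    if (duration_experiment) {
      stat <- self_db + 10 * log10(call$dur_ms / 8)
      detected <- detected && stat >= rp$corr_threshold_db
    }
    out$detected[i] <- detected
  }
  out
}

#' Signal-to-noise-and-interference ratio
#'
#' The ratio of the desired signal's matched-filter (or filter-bank) peak to
#' the strongest interference response plus the ambient noise floor, in dB
#' (amplitude convention: dB-SPL levels map to linear pressures with
#' 0 dB-SPL = 1).
#'
#' @param self_db Self peak level, dB.
#' @param cross_db Interference peak level, dB, or `NULL` when no masker
#'   falls in the reception window.
#' @param noise_db Noise floor, dB-SPL.
#' @return SNR in dB.
#' @export
snr <- function(self_db, cross_db = NULL, noise_db = 0) {
  denom <- 10^(noise_db / 20) +
    if (is.null(cross_db)) 0 else sum(10^(cross_db / 20))
  20 * log10(10^(self_db / 20) / denom)
}
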