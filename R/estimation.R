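#' Standard deviation of the range estimate
#'
#' Ranging combines the two-way travel-time measurement with two error
#' sources: an SNR-dependent noise term `k1 / SNR` calibrated to 1 cm at an
#' SNR of 10 dB, and the bat's intrinsic timing jitter, `0.5 * c * TimeRes`
#' with TimeRes ~ N(0, 50 us) - a floor of 0.5 * 343 * 50e-6 ~ 0.86 cm.
#' The SNR enters in dB and is floored at 1 dB so the noise term stays
#' bounded for barely supra-noise detections.
#'
#' @param snr_db SNR in dB.
#' @param k1 Noise coefficient (m * dB); default 0.1 gives 1 cm at 10 dB.
#' @param time_res_sd Timing jitter SD (s).
#' @param c Speed of sound (m/s).
#' @return Range-error SD in metres.
#' @export
range_error_sd <- function(snr_db, k1 = 0.1, time_res_sd = 50e-6, c = 343) {
  snr_db <- pmax(snr_db, 1)
  sqrt((k1 / snr_db)^2 + (0.5 * c * time_res_sd)^2)
}

#' Noisy range estimate
#'
#' @param true_range True range (m).
#' @param snr_db SNR in dB (recycled).
#' @inheritParams range_error_sd
#' @return Estimated range(s), `true_range + N(0, sd)`.
#' @export
range_estimate <- function(true_range, snr_db, k1 = 0.1, time_res_sd = 50e-6,
                           c = 343) {
  sd <- range_error_sd(snr_db, k1, time_res_sd, c)
  true_range + stats::rnorm(length(true_range), 0, sd)
}

#' Standard deviation of the direction-of-arrival estimate
#'
#' The DOA error combines an SNR-dependent noise term (1 degree at 10 dB
#' SNR) with an angle-dependent term `k3 + k4 * sin(|phi|)` anchored at 1.5
#' degrees on-axis and 10 degrees at 90 degrees off-axis (so k3 = 1.5, k4 =
#' 8.5 degrees).
#'
#' @param phi True DOA (rad).
#' @param snr_db SNR in dB (floored at 1 dB).
#' @param k2 Noise coefficient (deg * dB); 10 gives 1 degree at 10 dB.
#' @param k3,k4 Angle-dependent coefficients (deg).
#' @return DOA-error SD in radians.
#' @export
doa_error_sd <- function(phi, snr_db, k2 = 10, k3 = 1.5, k4 = 8.5) {
  snr_db <- pmax(snr_db, 1)
  sd_deg <- sqrt((k2 / snr_db)^2 + (k3 + k4 * abs(sin(phi)))^2)
  sd_deg * pi / 180
}

#' Noisy direction-of-arrival estimate
#'
#' @param true_doa True DOA (rad, receiver frame).
#' @inheritParams doa_error_sd
#' @return Estimated DOA(s), `true_doa + N(0, sd)` (rad).
#' @export
doa_estimate <- function(true_doa, snr_db, k2 = 10, k3 = 1.5, k4 = 8.5) {
  sd <- doa_error_sd(true_doa, snr_db, k2, k3, k4)
  wrap_angle(true_doa + stats::rnorm(length(true_doa), 0, sd))
}
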