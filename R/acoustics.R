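#' Acoustic constants
#'
#' Physical constants of the acoustics chain: speed of sound, emitter (mouth)
#' and receiver (ear) piston radii, disc radii of the prey and clutter
#' reflectors, and the extra back-hemisphere attenuation of the modified
#' piston model (0 dB at +/-90 degrees growing linearly to 20 dB at 180).
#'
#' @param c Speed of sound (m/s).
#' @param a_mouth Mouth piston radius (m).
#' @param a_ear Ear piston radius (m).
#' @param r_prey Prey disc radius (m), a moth's wing length.
#' @param r_clutter Clutter-point disc radius (m), leaf-sized.
#' @param back_att_db Extra attenuation at 180 degrees (dB).
#' @return A list of class `acoustic_params`.
#' @export
acoustic_params <- function(c = 343, a_mouth = 3e-3, a_ear = 7e-3,
                            r_prey = 0.02, r_clutter = 0.03,
                            back_att_db = 20) {
  stopifnot(a_mouth > 0, a_ear > 0, r_prey > 0, r_clutter > 0)
  structure(list(c = c, a_mouth = a_mouth, a_ear = a_ear, r_prey = r_prey,
                 r_clutter = r_clutter, back_att_db = back_att_db),
            class = "acoustic_params")
}

#' Piston-model directivity gain
#'
#' Circular-piston gain `G0 * [2 J1(k a sin(phi)) / (k a sin(phi))]^2` with
#' `k = 2 pi / lambda`. The boresight limit (phi -> 0) is `G0`. The plain
#' piston is front/back symmetric; here signals from the back hemisphere
#' (|phi| > 90 degrees) receive an extra attenuation growing linearly in dB
#' from 0 at 90 degrees to 20 dB at 180 degrees. `G0` is 1 for the mouth
#' (referencing source levels at 0.1 m) and `4 pi (pi a^2) / lambda^2` for
#' the ear (aperture gain of a circular plane).
#'
#' @param phi Off-axis angle(s), radians.
#' @param f Frequency (Hz), > 0.
#' @param a Piston radius (m); defaults per `role`.
#' @param role `"mouth"` or `"ear"` (sets `G0` and the default radius).
#' @param params An [acoustic_params()].
#' @return Linear power gain, same length as `phi`.
#' @export
piston_gain <- function(phi, f, a = NULL, role = c("mouth", "ear"),
                        params = acoustic_params()) {
  stopifnot(all(f > 0))
  role <- match.arg(role)
  if (is.null(a)) a <- if (role == "mouth") params$a_mouth else params$a_ear
  g0 <- if (role == "mouth") 1 else 4 * pi * (pi * a^2) * (f / params$c)^2
  .pg(phi, f, a, g0, params$back_att_db, params$c)
}

# hot-path piston kernel (no argument matching, no ifelse copies)
.pg <- function(phi, f, a, g0, back_db, c_snd) {
  x <- (2 * pi * f / c_snd) * a * abs(sin(phi))
  small <- x < 1e-9
  x[small] <- 1e-9
  g <- (2 * besselJ(x, 1) / x)^2
  g[small] <- 1
  aw <- abs(wrap_angle(phi))
  back <- aw > pi / 2
  if (any(back)) {
    extra <- numeric(length(g))
    extra[back] <- back_db * (aw[back] - pi / 2) / (pi / 2)
    g <- g * 10^(-extra / 10)
  }
  g0 * g
}

#' Atmospheric absorption coefficient
#'
#' Linear-in-frequency approximation of the atmospheric attenuation of
#' ultrasound at 20 degrees C and 50% humidity:
#' `alpha = 3.8e-2 * f_kHz - 0.3` dB/m.
#'
#' @param f Frequency in Hz.
#' @return Attenuation in dB per metre.
#' @export
atmospheric_attenuation <- function(f) {
  3.8e-2 * (f / 1000) - 0.3
}

#' Disc target strength (sonar cross-section)
#'
#' A flat disc of radius `r` reflecting equally in all directions has
#' `sigma = 4 pi A^2 / lambda^2` with `A = pi r^2`; a reasonable approximation
#' for medium-sized insects (r = 2 cm, a moth's wing length).
#'
#' @param r Disc radius (m).
#' @param lambda Wavelength (m).
#' @return Cross-section in m^2.
#' @export
disc_target_strength <- function(r, lambda) {
  stopifnot(r > 0, lambda > 0)
  A <- pi * r^2
  4 * pi * A^2 / lambda^2
}

# shared level helper: clamp distances to the 0.1 m source-level reference
.ref_dist <- function(d) pmax(d, 0.1)

# directivity gain of a chirp: mean power gain over the sweep band. A pure
# tone sits in the piston nulls; a broadband sweep never does, so the level
# bookkeeping of chirped calls averages the pattern over `n_f` frequencies
# across the band (bw_hz = 0 reduces to the single-frequency pattern).
.band_gain <- function(phi, f, bw_hz, role, params, n_f = 5) {
  a <- if (role == "mouth") params$a_mouth else params$a_ear
  g0 <- function(fk) if (role == "mouth") 1 else
    4 * pi * (pi * a^2) * (fk / params$c)^2
  if (all(bw_hz <= 0))
    return(.pg(phi, f, a, g0(f), params$back_att_db, params$c))
  w <- seq(-0.5, 0.5, length.out = n_f)
  g <- 0
  for (j in seq_len(n_f)) {
    fk <- f + w[j] * bw_hz
    g <- g + .pg(phi, fk, a, g0(fk), params$back_att_db, params$c)
  }
  g / n_f
}

#' Received level and delay of the bat's own prey echo
#'
#' Two-way sonar equation: transmit gain of the mouth and receive gain of the
#' ear at the angle to the reflector, spherical spreading `lambda^2 /
#' ((4 pi)^3 D^4)`, two-way atmospheric absorption over `2 (D - 0.1)` m, and
#' the disc cross-section of the target. The delay is `2 D / c`.
#'
#' @param sl_db Source level, dB-SPL at 0.1 m.
#' @param f Call frequency (Hz; the sweep's centre frequency for level
#'   bookkeeping).
#' @param dist Distance to the reflector (m); clamped to >= 0.1 m inside the
#'   equation. Non-positive distances are an error.
#' @param bearing Angle between the bat's heading and the reflector (rad);
#'   the same angle sets the transmit and receive gains (monostatic).
#' @param r_target Reflector disc radius (m); defaults to the prey radius.
#' @param params An [acoustic_params()].
#' @return List with `level_db` and `delay_s` (vectors).
#' @export
own_echo <- function(sl_db, f, dist, bearing, r_target = NULL,
                     params = acoustic_params(), bw_hz = 0) {
  if (any(dist <= 0)) stop("invalid geometry: distance must be positive")
  if (is.null(r_target)) r_target <- params$r_prey
  lambda <- params$c / f
  d <- .ref_dist(dist)
  sigma <- disc_target_strength(r_target, lambda)
  gt <- .band_gain(bearing, f, bw_hz, "mouth", params)
  gr <- .band_gain(bearing, f, bw_hz, "ear", params)
  alpha <- atmospheric_attenuation(f)
  lvl <- sl_db + 10 * log10(gt * gr * lambda^2 * sigma / ((4 * pi)^3 * d^4)) -
    2 * alpha * (d - 0.1)
  list(level_db = lvl, delay_s = 2 * dist / params$c)
}

#' Received level and delay of a conspecific's call (direct path)
#'
#' One-way transmission equation: transmitter mouth gain toward the receiver,
#' receiver ear gain toward the transmitter, `(lambda / (4 pi D))^2`
#' spreading and one-way absorption over `D - 0.1` m. Delay `D / c`.
#'
#' @param sl_db Source level of the masking call (dB-SPL at 0.1 m).
#' @param f Frequency (Hz).
#' @param dist Transmitter-receiver distance (m).
#' @param bearing_tx Angle of the receiver as seen from the transmitter,
#'   relative to the transmitter's heading (rad).
#' @param bearing_rx Angle of the transmitter as seen from the receiver,
#'   relative to the receiver's heading (rad).
#' @param params An [acoustic_params()].
#' @return List with `level_db` and `delay_s`.
#' @export
conspecific_call <- function(sl_db, f, dist, bearing_tx, bearing_rx,
                             params = acoustic_params(), bw_hz = 0) {
  if (any(dist <= 0)) stop("invalid geometry: distance must be positive")
  lambda <- params$c / f
  d <- .ref_dist(dist)
  gt <- .band_gain(bearing_tx, f, bw_hz, "mouth", params)
  gr <- .band_gain(bearing_rx, f, bw_hz, "ear", params)
  alpha <- atmospheric_attenuation(f)
  lvl <- sl_db + 10 * log10(gt * gr * (lambda / (4 * pi * d))^2) -
    alpha * (d - 0.1)
  list(level_db = lvl, delay_s = dist / params$c)
}

#' Received level and delay of a conspecific call's echo off a reflector
#'
#' Bistatic sonar equation: transmitter mouth gain toward the reflector,
#' receiver ear gain toward the reflector, `lambda^2 / ((4 pi)^3 Dtx^2
#' Drx^2)` spreading, absorption over `Dtx + Drx - 0.2` m and the disc
#' cross-section. Delay `(Dtx + Drx) / c`. With transmitter = receiver it
#' reduces to the monostatic [own_echo()].
#'
#' @param sl_db Source level of the conspecific call (dB-SPL at 0.1 m).
#' @param f Frequency (Hz).
#' @param d_tx Transmitter-reflector distance (m).
#' @param d_rx Reflector-receiver distance (m).
#' @param bearing_tx Angle of the reflector from the transmitter's heading.
#' @param bearing_rx Angle of the reflector from the receiver's heading.
#' @param r_target Reflector disc radius (m); defaults to the prey radius.
#' @param params An [acoustic_params()].
#' @return List with `level_db` and `delay_s`.
#' @export
conspecific_echo <- function(sl_db, f, d_tx, d_rx, bearing_tx, bearing_rx,
                             r_target = NULL, params = acoustic_params(),
                             bw_hz = 0) {
  if (any(d_tx <= 0) || any(d_rx <= 0)) stop("invalid geometry: distance must be positive")
  if (is.null(r_target)) r_target <- params$r_prey
  lambda <- params$c / f
  dtx <- .ref_dist(d_tx); drx <- .ref_dist(d_rx)
  sigma <- disc_target_strength(r_target, lambda)
  gt <- .band_gain(bearing_tx, f, bw_hz, "mouth", params)
  gr <- .band_gain(bearing_rx, f, bw_hz, "ear", params)
  alpha <- atmospheric_attenuation(f)
  lvl <- sl_db + 10 * log10(gt * gr * lambda^2 * sigma /
                              ((4 * pi)^3 * dtx^2 * drx^2)) -
    alpha * (dtx + drx - 0.2)
  list(level_db = lvl, delay_s = (d_tx + d_rx) / params$c)
}

# distance from (x, y) along direction ang to the arena border
.ray_to_border <- function(x, y, ang, arena) {
  dx <- cos(ang); dy <- sin(ang)
  tx <- ifelse(dx > 1e-12, (arena$width - x) / dx,
               ifelse(dx < -1e-12, -x / dx, Inf))
  ty <- ifelse(dy > 1e-12, (arena$height - y) / dy,
               ifelse(dy < -1e-12, -y / dy, Inf))
  pmin(tx, ty)
}

#' Summed border-clutter echo
#'
#' The arena border is sampled along rays from the bat at 5.7-degree angular
#' spacing; each sampled point is a leaf-sized disc (3 cm radius) whose
#' target strength is raised by `ts_offset_db`. Only points within +/-90
#' degrees of the emission direction contribute. Per-point levels follow the
#' two-way sonar equation; the total is a non-coherent (power) sum, with the
#' per-point delays retained for reception-window tests. The bearing of the
#' summed signal is that of the loudest contributing point.
#'
#' @param x,y,heading Bat pose at emission.
#' @param arena An [arena()].
#' @param sl_db Call source level (dB-SPL at 0.1 m).
#' @param f Frequency (Hz).
#' @param ts_offset_db Target-strength offset in dB (0-40).
#' @param params An [acoustic_params()].
#' @return List with `level_db` (power sum), `bearing_rad`, and per-point
#'   vectors `point_level_db`, `point_delay_s`, `point_bearing_rad`.
#' @export
clutter_sum <- function(x, y, heading, arena, sl_db, f, ts_offset_db = 0,
                        params = acoustic_params()) {
  rel <- seq(-90, 90, by = 5.7) * pi / 180
  d <- .ray_to_border(x, y, heading + rel, arena)
  ok <- is.finite(d) & d > 0
  rel <- rel[ok]; d <- d[ok]
  e <- own_echo(sl_db, f, d, rel, r_target = params$r_clutter, params = params)
  lvl <- e$level_db + ts_offset_db
  total <- 10 * log10(sum(10^(lvl / 10)))
  list(level_db = total,
       bearing_rad = rel[which.max(lvl)],
       point_level_db = lvl,
       point_delay_s = e$delay_s,
       point_bearing_rad = rel)
}
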