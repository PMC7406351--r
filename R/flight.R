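#' Steering law: angular velocity and speed from the target angle
#'
#' A delayed linear adaptive steering law: the commanded angular velocity is
#' proportional to the angle between the bat's heading and its steering
#' target, `k_r * phi`, limited so that the centripetal acceleration
#' `speed * ang_vel` never exceeds `a_max` (4 m/s^2). The forward speed
#' follows a cosine law, `V_phase * cos(phi)`, floored at zero, so the bat
#' slows down (and can therefore turn tighter) when the target is far
#' off-axis. Both commands are issued once per inter-pulse interval and held
#' until the next emission.
#'
#' @param phi_target Angle to the steering target, radians in (-pi, pi\].
#' @param v_phase Phase-maximal speed (3.5 m/s search/approach, 2 m/s buzz).
#' @param k_r Steering gain (1/s). The default is large enough that the
#'   acceleration limit is usually the binding constraint.
#' @param a_max Maximal centripetal acceleration (m/s^2).
#' @return List with `speed` (m/s) and `ang_vel` (rad/s).
#' @export
steer <- function(phi_target, v_phase, k_r = 10, a_max = 4) {
  speed <- max(0, v_phase * cos(phi_target))
  # the a_max/v bound is evaluated at the held speed, floored at 0.5 m/s so
  # a near-stationary bat reorients at a bounded rate (<= 8 rad/s)
  w_max <- a_max / max(speed, 0.5)
  ang_vel <- sign(phi_target) * min(k_r * abs(phi_target), w_max)
  list(speed = speed, ang_vel = ang_vel)
}

# Closest predicted approach between two agents moving at constant velocity
# over the horizon h: min over tau in [0, h] of |r + w tau|.
min_predicted_distance <- function(rx, ry, wx, wy, h) {
  w2 <- pmax(wx^2 + wy^2, 1e-12)
  tau <- pmin(pmax(-(rx * wx + ry * wy) / w2, 0), h)
  sqrt((rx + wx * tau)^2 + (ry + wy * tau)^2)
}

#' Per-IPI action selection
#'
#' The decision loop runs once per inter-pulse interval, after the reception
#' of the previous call has been processed. Priorities: (1) avoid a
#' conspecific whose predicted path comes within 20 cm of the bat's own
#' predicted path over the next IPI, or the arena border if the predicted
#' position leaves a safety margin; (2) pursue the closest detected,
#' non-jammed prey; (3) continue the correlated-random-walk search.
#'
#' @param bat List with the bat's `x`, `y`, `heading`, `speed`, `ang_vel`.
#' @param detections Data frame of detected prey with columns `id`,
#'   `range_est` (m) and `doa_est` (rad, bat frame), or `NULL`.
#' @param neighbors List with vectors `x`, `y`, `vx`, `vy` of the other bats
#'   (may be empty).
#' @param arena An [arena()].
#' @param horizon Prediction horizon in seconds.
#' @param margin Border safety margin in metres.
#' @param avoiding Is the bat currently in an avoidance maneuver? Avoidance
#'   enters at a 20 cm predicted clearance and, to avoid chattering in and
#'   out of the maneuver, releases only once the predicted clearance exceeds
#'   `release`.
#' @param release Avoidance release clearance in metres (hysteresis).
#' @return A list with `action` (`"avoid_bat"`, `"avoid_border"`, `"pursue"`,
#'   `"search"`), `phi_target` (for avoid/pursue), and for pursuit `target`
#'   and `range_est`.
#' @export
decide_action <- function(bat, detections, neighbors, arena,
                          horizon = 0.1, margin = 0.2,
                          avoiding = FALSE, release = 0.4) {
  vx <- bat$speed * cos(bat$heading); vy <- bat$speed * sin(bat$heading)
  if (length(neighbors$x)) {
    d <- min_predicted_distance(neighbors$x - bat$x, neighbors$y - bat$y,
                                neighbors$vx - vx, neighbors$vy - vy, horizon)
    j <- which.min(d)
    if (d[j] < (if (avoiding) release else 0.2)) {
      phi <- wrap_angle(atan2(bat$y - neighbors$y[j], bat$x - neighbors$x[j]) - bat$heading)
      return(list(action = "avoid_bat", phi_target = phi))
    }
  }
  px <- bat$x + vx * horizon; py <- bat$y + vy * horizon
  if (px < margin || px > arena$width - margin || py < margin || py > arena$height - margin) {
    phi <- wrap_angle(atan2(arena$height / 2 - bat$y, arena$width / 2 - bat$x) - bat$heading)
    return(list(action = "avoid_border", phi_target = phi))
  }
  if (!is.null(detections) && nrow(detections)) {
    k <- which.min(detections$range_est)
    return(list(action = "pursue", target = detections$id[k],
                phi_target = detections$doa_est[k],
                range_est = detections$range_est[k]))
  }
  list(action = "search")
}
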