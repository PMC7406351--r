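#' Arena geometry
#'
#' The foraging ground is a flat rectangular area with reflective borders and
#' no interior obstacles. Coordinates are continuous, origin at one corner,
#' x to the right and y up; headings are measured counter-clockwise from +x.
#'
#' @param width,height Arena dimensions in metres (default 10 x 10).
#' @return An object of class `arena`.
#' @export
arena <- function(width = 10, height = 10) {
  if (!is.numeric(width) || !is.numeric(height) || width <= 0 || height <= 0)
    stop("arena dimensions must be positive")
  structure(list(width = width, height = height), class = "arena")
}

#' @export
print.arena <- function(x, ...) {
  cat(sprintf("arena: %.1f x %.1f m\n", x$width, x$height))
  invisible(x)
}

wrap_angle <- function(a) {
  # wrap to (-pi, pi]
  a <- (a + pi) %% (2 * pi) - pi
  a[a == -pi] <- pi
  a
}

wrap_heading <- function(a) a %% (2 * pi)

# fast data.frame constructor for hot paths (no checks, no name repair)
.fast_df <- function(...) {
  x <- list(...)
  structure(x, class = "data.frame",
            row.names = .set_row_names(length(x[[1]])))
}

#' Create a set of prey agents
#'
#' Prey fly a correlated random walk resembling a moth's flight path: linear
#' speed ~ N(1, 0.1) m/s bounded to \[0.8, 1.2\] m/s, and the angular velocity
#' is redrawn every 100 ms from N(0, 2) rad/s. Prey neither detect nor react
#' to bats.
#'
#' @param n Number of prey.
#' @param arena An [arena()].
#' @param t0 Spawn time in seconds (sets each prey's private 100-ms redraw
#'   grid).
#' @return A list of per-prey state vectors (`x`, `y`, `heading`, `speed`,
#'   `ang_vel`, `next_redraw`).
#' @export
init_prey <- function(n, arena, t0 = 0) {
  list(
    x = stats::runif(n, 0, arena$width),
    y = stats::runif(n, 0, arena$height),
    heading = stats::runif(n, 0, 2 * pi),
    speed = pmin(pmax(stats::rnorm(n, 1, 0.1), 0.8), 1.2),
    ang_vel = stats::rnorm(n, 0, 2),
    next_redraw = rep(t0 + 0.1, n)
  )
}

#' Advance prey by one time step
#'
#' Every 100 ms (on each prey's own grid) a speed increment ~ N(0, 0.1) m/s
#' and a new angular velocity ~ N(0, 2) rad/s are drawn; speed is clipped to
#' \[0.8, 1.2\] m/s. Between redraws the heading integrates at the current
#' angular velocity and the position advances along the heading.
#'
#' @param prey Prey state list as from [init_prey()].
#' @param t Current simulation time (s).
#' @param dt Time step (s), must be positive.
#' @param arena An [arena()]; prey reaching a border turn perpendicular to it
#'   (see [prey_boundary_turn()]).
#' @return Updated prey state list.
#' @export
step_prey <- function(prey, t, dt, arena) {
  if (!is.numeric(dt) || dt <= 0) stop("dt must be positive")
  redraw <- t >= prey$next_redraw
  if (any(redraw)) {
    k <- sum(redraw)
    prey$speed[redraw] <- pmin(pmax(prey$speed[redraw] + stats::rnorm(k, 0, 0.1), 0.8), 1.2)
    prey$ang_vel[redraw] <- stats::rnorm(k, 0, 2)
    prey$next_redraw[redraw] <- prey$next_redraw[redraw] + 0.1
  }
  prey$heading <- wrap_heading(prey$heading + prey$ang_vel * dt)
  prey$x <- prey$x + prey$speed * cos(prey$heading) * dt
  prey$y <- prey$y + prey$speed * sin(prey$heading) * dt
  prey_boundary_turn(prey, arena)
}

#' Turn prey at the arena border
#'
#' A prey at or beyond a border rotates its heading to pi/2 relative to that
#' border, i.e. onto the inward normal, so the next step re-enters the arena;
#' its position is clamped inside. Interior prey are untouched.
#'
#' @param prey Prey state list.
#' @param arena An [arena()].
#' @return Updated prey state list.
#' @export
prey_boundary_turn <- function(prey, arena) {
  hit <- prey$x <= 0
  if (any(hit)) { prey$heading[hit] <- 0;        prey$x[hit] <- 0 }
  hit <- prey$x >= arena$width
  if (any(hit)) { prey$heading[hit] <- pi;       prey$x[hit] <- arena$width }
  hit <- prey$y <= 0
  if (any(hit)) { prey$heading[hit] <- pi / 2;   prey$y[hit] <- 0 }
  hit <- prey$y >= arena$height
  if (any(hit)) { prey$heading[hit] <- 3 * pi / 2; prey$y[hit] <- arena$height }
  prey
}

#' Respawn a captured prey
#'
#' Prey density is constant within a trial: each capture immediately places a
#' new prey at a uniform random position with uniform heading and speed
#' ~ N(1, 0.1) m/s clipped to \[0.8, 1.2\] m/s.
#'
#' @param arena An [arena()].
#' @param t0 Current time (s); restarts the prey's 100-ms redraw grid.
#' @return A one-prey state list, combinable field-wise into an existing set.
#' @export
respawn_prey <- function(arena, t0 = 0) {
  list(
    x = stats::runif(1, 0, arena$width),
    y = stats::runif(1, 0, arena$height),
    heading = stats::runif(1, 0, 2 * pi),
    speed = min(max(stats::rnorm(1, 1, 0.1), 0.8), 1.2),
    ang_vel = stats::rnorm(1, 0, 2),
    next_redraw = t0 + 0.1
  )
}
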