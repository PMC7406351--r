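#' Run one simulation trial
#'
#' Simulates `n_bats` bats and `n_prey` prey in the arena for
#' `trial_seconds`, at a fixed 0.5-ms step. Each bat runs its decision loop
#' once per inter-pulse interval: receptions of the previous call are
#' processed through the configured receiver, the bat decides (avoid /
#' pursue / search), adjusts its echolocation parameters to the estimated
#' distance to its target, emits the next call and holds the new steering
#' command until the next emission. Captures occur within 5 cm of the prey;
#' captured prey respawn immediately at a random position.
#'
#' Echo and masker geometry is evaluated on per-IPI snapshots: own echoes use
#' the bat's pose at emission and prey positions at the decision time;
#' conspecific calls use the transmitter's logged emission pose.
#'
#' @param config A [scenario_config()].
#' @param seed Integer seed (defaults to `config$seed`); the trial is
#'   deterministic given `(config, seed)`.
#' @return An object of class `echojam_trial`: list with `config`, `seed`,
#'   `calls` (per-call log: emission parameters, phase, focal-prey echo
#'   audibility and jamming, detections, false alarms), `attempts` (one row
#'   per capture attempt with its outcome), and `summary`
#'   (a [trial_summary()]).
#' @export
run_trial <- function(config, seed = config$seed) {
  if (!inherits(config, "scenario_config"))
    stop("config must be a scenario_config()")
  if (!is.null(seed)) set.seed(seed)
  cfg <- config
  ar <- cfg$arena
  dt <- cfg$dt
  n_ticks <- ceiling(cfg$trial_seconds / dt)
  nb <- cfg$n_bats; np <- cfg$n_prey
  ap <- acoustic_params()
  rp <- receiver_params(hearing_threshold_db = cfg$hearing_threshold_db)
  sl_off <- cfg$source_level_db - 110
  sdur <- if (cfg$search_call_duration_ms != 7) cfg$search_call_duration_ms else NULL
  clutter_on <- !is.null(cfg$clutter_ts_offset_db) && cfg$masking
  c_snd <- ap$c

  prey <- init_prey(np, ar)
  tf_base <- assign_terminal_frequencies(nb, cfg$regime)

  bx <- stats::runif(nb, 0, ar$width); by <- stats::runif(nb, 0, ar$height)
  bh <- stats::runif(nb, 0, 2 * pi)
  bs <- rep(3.5, nb); bw_ <- rep(0, nb)           # speed, angular velocity
  target <- integer(nb)                            # 0 none, -1 fake, else prey id
  jar_hold <- integer(nb)
  next_emit <- stats::runif(nb, 0, 0.1)
  cur_ipi <- rep(0.1, nb)
  last_call <- integer(nb)
  att_active <- logical(nb); att_prey <- integer(nb); att_start <- numeric(nb)
  # Attempt bookkeeping. An attack on a prey is registered once the bat has
  # pursued it within attack range (approach or buzz) on two consecutive
  # decisions (a one-call flirtation is not an attack initiation). An
  # interrupted pursuit (momentary sensory loss, an avoidance jink, or a
  # brief switch to another candidate) leaves the attempt pending; it closes
  # - labeled with the latest interrupting cause - only if the bat fails to
  # re-commit to the same prey within att_gap_max seconds.
  att_gap_max <- 0.25
  att_pending <- rep(NA_real_, nb)
  att_cause <- character(nb)
  cm_tgt <- integer(nb); cm_count <- integer(nb); cm_t0 <- numeric(nb)
  avoiding <- logical(nb)
  # estimated target point (from the last reception); while pursuing, the
  # turn command is re-issued every model tick toward this point (the speed
  # is held per IPI), per the per-sample steering law
  tgx <- rep(NA_real_, nb); tgy <- rep(NA_real_, nb)


  # preallocated per-call log
  cap <- nb * (n_ticks %/% 8 + 50)
  L <- new.env(parent = emptyenv())
  L$n <- 0L
  for (nm in c("t", "x", "y", "heading", "ipi_s", "dur_ms", "tf_khz", "bw_khz",
               "sl_db", "focal_level_db", "focal_dist_m", "range_est_m"))
    assign(nm, numeric(cap), envir = L)
  for (nm in c("bat", "focal_prey", "call_target", "n_detected"))
    assign(nm, integer(cap), envir = L)
  for (nm in c("focal_audible", "focal_jammed", "false_alarm"))
    assign(nm, logical(cap), envir = L)
  L$phase <- character(cap)
  L$masker_tf_khz <- rep(NA_real_, cap)

  # attempts log
  A <- new.env(parent = emptyenv())
  A$n <- 0L
  A$bat <- integer(512); A$prey <- integer(512)
  A$t_start <- numeric(512); A$t_end <- numeric(512)
  A$outcome <- character(512)

  close_attempt <- function(i, outcome, t) {
    if (!att_active[i]) return(invisible())
    k <- A$n + 1L
    if (k > length(A$bat)) {
      for (nm in c("bat", "prey", "t_start", "t_end", "outcome"))
        assign(nm, c(get(nm, envir = A), vector(mode = typeof(get(nm, envir = A)),
                                                length = length(A$bat))), envir = A)
    }
    A$bat[k] <- i; A$prey[k] <- att_prey[i]
    A$t_start[k] <- att_start[i]; A$t_end[k] <- t; A$outcome[k] <- outcome
    A$n <- k
    att_active[i] <<- FALSE; att_prey[i] <<- 0L; att_pending[i] <<- NA_real_
  }

  call_chirp <- function(pc) list(dur_ms = L$dur_ms[pc], tf_khz = L$tf_khz[pc],
                                  bw_khz = L$bw_khz[pc])

  process_emission <- function(i, t) {
    pc <- last_call[i]
    detections <- NULL
    focal <- 0L; focal_aud <- FALSE; focal_jam <- FALSE
    focal_lvl <- NA_real_; jam_tf <- NA_real_
    false_alarm <- FALSE; fa_det <- NULL

    if (pc > 0L) {
      ex <- L$x[pc]; ey <- L$y[pc]; eh <- L$heading[pc]; et <- L$t[pc]
      fc <- (L$tf_khz[pc] + L$bw_khz[pc] / 2) * 1000
      dxp <- prey$x - ex; dyp <- prey$y - ey
      dp <- sqrt(dxp^2 + dyp^2); dp <- pmax(dp, 1e-4)
      php <- wrap_angle(atan2(dyp, dxp) - eh)
      oe <- own_echo(L$sl_db[pc], fc, dp, php, params = ap,
                     bw_hz = L$bw_khz[pc] * 1000)
      arr <- et + oe$delay_s
      audible <- oe$level_db >= rp$hearing_threshold_db

      focal <- if (target[i] > 0L) target[i] else if (any(audible))
        which(audible)[which.min(dp[audible])] else 0L
      if (focal > 0L) {
        focal_aud <- audible[focal]
        focal_lvl <- oe$level_db[focal]
        L$focal_dist_m[pc] <- dp[focal]
      }

      aidx <- which(audible)
      echoes <- .fast_df(id = aidx, level_db = oe$level_db[aidx],
                         arrival_s = arr[aidx], bearing_rad = php[aidx])

      maskers <- NULL
      if (cfg$masking && nb > 1L &&
          (nrow(echoes) > 0L || cfg$receiver == "filterbank")) {
        lo <- et - 0.06
        n_log <- L$n
        i0 <- findInterval(lo, L$t[seq_len(n_log)]) + 1L
        idx <- i0:n_log
        idx <- idx[L$bat[idx] != i]
        if (length(idx)) {
          txx <- L$x[idx]; txy <- L$y[idx]; txh <- L$heading[idx]
          fm <- (L$tf_khz[idx] + L$bw_khz[idx] / 2) * 1000
          ddx <- ex - txx; ddy <- ey - txy
          dd <- pmax(sqrt(ddx^2 + ddy^2), 1e-4)
          btx <- wrap_angle(atan2(ddy, ddx) - txh)
          brx <- wrap_angle(atan2(-ddy, -ddx) - eh)
          cc <- conspecific_call(L$sl_db[idx], fm, dd, btx, brx, params = ap,
                                 bw_hz = L$bw_khz[idx] * 1000)
          m_lvl <- cc$level_db; m_arr <- L$t[idx] + cc$delay_s
          m_dur <- L$dur_ms[idx]; m_tf <- L$tf_khz[idx]; m_bw <- L$bw_khz[idx]
          m_brg <- brx
          # bistatic echoes of conspecific calls off every prey
          nm_ <- length(idx)
          im <- rep(seq_len(nm_), each = np); ip <- rep(seq_len(np), nm_)
          dtx <- pmax(sqrt((prey$x[ip] - txx[im])^2 + (prey$y[ip] - txy[im])^2), 1e-4)
          drx <- dp[ip]
          ce <- conspecific_echo(L$sl_db[idx][im], fm[im], dtx, drx,
                                 wrap_angle(atan2(prey$y[ip] - txy[im],
                                                  prey$x[ip] - txx[im]) - txh[im]),
                                 php[ip], params = ap,
                                 bw_hz = L$bw_khz[idx][im] * 1000)
          keep <- ce$level_db >= rp$hearing_threshold_db
          m_lvl <- c(m_lvl, ce$level_db[keep])
          m_arr <- c(m_arr, L$t[idx][im][keep] + ce$delay_s[keep])
          m_dur <- c(m_dur, m_dur[im][keep]); m_tf <- c(m_tf, m_tf[im][keep])
          m_bw <- c(m_bw, m_bw[im][keep]); m_brg <- c(m_brg, php[ip][keep])
          # prune maskers that cannot reach any echo's reception window; the
          # filter-bank with no audible echo still hears maskers arriving
          # within plausible detection delays (false-alarm candidates)
          tdur <- L$dur_ms[pc] / 1000
          if (nrow(echoes)) {
            lo_a <- min(echoes$arrival_s) - rp$forward_window_s
            hi_a <- max(echoes$arrival_s) + rp$backward_window_s
          } else {
            lo_a <- et; hi_a <- et + 0.06
          }
          keep <- m_lvl >= rp$hearing_threshold_db &
            (m_arr + m_dur / 1000) >= lo_a & (m_arr - tdur) <= hi_a
          if (any(keep))
            maskers <- .fast_df(level_db = m_lvl[keep], arrival_s = m_arr[keep],
                                dur_ms = m_dur[keep], tf_khz = m_tf[keep],
                                bw_khz = m_bw[keep], bearing_rad = m_brg[keep])
        }
      }

      clut <- NULL
      if (clutter_on)
        clut <- clutter_sum(ex, ey, eh, ar, L$sl_db[pc], fc,
                            cfg$clutter_ts_offset_db, params = ap)

      if (nrow(echoes) || (cfg$receiver == "filterbank" && !is.null(maskers))) {
        if (cfg$receiver == "correlation") {
          rec <- correlation_receiver(call_chirp(pc), echoes, maskers, clut,
                                      rp, cfg$duration_experiment)
          det_ok <- rec$detected
          if (any(det_ok)) {
            ids <- rec$id[det_ok]
            rng <- range_estimate(dp[ids], rec$snr_db[det_ok])
            doa <- doa_estimate(php[ids], rec$snr_db[det_ok])
            detections <- .fast_df(id = ids, range_est = pmax(rng, 0),
                                   doa_est = doa)
          }
          if (focal > 0L && focal_aud) {
            k <- match(focal, rec$id)
            focal_jam <- isTRUE(rec$jammed[k])
            jam_tf <- rec$masker_tf_khz[k]
          }
        } else {
          fb <- filterbank_detect(call_chirp(pc), echoes, maskers, rp)
          dd <- fb$detections
          det_ok <- dd$detected
          if (any(det_ok)) {
            ids <- dd$id[det_ok]
            rng <- (dd$t_peak_s[det_ok] - et) * c_snd / 2
            doa <- doa_estimate(php[ids], pmax(dd$snr_db[det_ok], 1))
            detections <- .fast_df(id = ids, range_est = pmax(rng, 0.01),
                                   doa_est = doa)
          }
          if (focal > 0L && focal_aud) {
            k <- match(focal, dd$id)
            focal_jam <- isTRUE(dd$jammed[k])
            if (focal_jam && !is.null(maskers) && nrow(maskers))
              jam_tf <- maskers$tf_khz[which.min(abs(maskers$arrival_s - arr[focal]))]
          }
          if (fb$false_alarm) {
            false_alarm <- TRUE
            rng <- max((fa_t <- fb$fa_arrival_s - et) * c_snd / 2, 0.05)
            brg <- if (!is.null(maskers) && nrow(maskers))
              maskers$bearing_rad[which.min(abs(maskers$arrival_s - fb$fa_arrival_s))]
            else 0
            fa_det <- .fast_df(id = -1L, range_est = rng, doa_est = brg)
          }
        }
      }
      if (!is.null(fa_det))
        detections <- if (is.null(detections)) fa_det else rbind(detections, fa_det)

      # write reception outcome back onto the call that produced the echoes
      L$focal_prey[pc] <- focal
      L$focal_audible[pc] <- focal_aud
      L$focal_jammed[pc] <- focal_jam
      L$focal_level_db[pc] <- focal_lvl
      L$masker_tf_khz[pc] <- jam_tf
      L$n_detected[pc] <- if (is.null(detections)) 0L else nrow(detections)
      L$false_alarm[pc] <- false_alarm
    }

    # active JAR: react to jamming of the pursued prey's echo
    if (cfg$regime == "jar") {
      upd <- jar_update(tf_base[i], focal_aud && focal_jam, jam_tf, jar_hold[i])
      tf_base[i] <<- upd$tf_khz; jar_hold[i] <<- upd$hold
    }

    others <- setdiff(seq_len(nb), i)
    neigh <- list(x = bx[others], y = by[others],
                  vx = bs[others] * cos(bh[others]),
                  vy = bs[others] * sin(bh[others]))
    act <- decide_action(list(x = bx[i], y = by[i], heading = bh[i],
                              speed = bs[i], ang_vel = bw_[i]),
                         detections, neigh, ar, horizon = 0.1,
                         avoiding = avoiding[i])

    tf_off <- tf_base[i] - 39
    avoiding[i] <<- act$action == "avoid_bat"
    if (act$action == "avoid_bat" || act$action == "avoid_border") {
      tgx[i] <<- NA_real_; tgy[i] <<- NA_real_
      if (att_active[i]) {
        att_cause[i] <<- if (act$action == "avoid_bat") "conspecific_avoidance"
                         else "obstacle_avoidance"
        if (is.na(att_pending[i])) att_pending[i] <<- t
        else if (t - att_pending[i] > att_gap_max)
          close_attempt(i, att_cause[i], t)
      }
      target[i] <<- 0L
      pars <- phase_and_call_params(NULL, tf_off, sl_off, sdur)
      sv <- steer(act$phi_target, 3.5)
    } else if (act$action == "pursue") {
      tgt <- as.integer(act$target)
      target[i] <<- tgt
      if (pc > 0L) L$range_est_m[pc] <- act$range_est
      pars <- phase_and_call_params(act$range_est, tf_off, sl_off, sdur)
      if (tgt == cm_tgt[i]) cm_count[i] <<- cm_count[i] + 1L
      else { cm_tgt[i] <<- tgt; cm_count[i] <<- 1L; cm_t0[i] <<- t }
      if (att_active[i] && att_prey[i] == tgt) {
        att_pending[i] <<- NA_real_            # pursuit of the attempt prey resumes
      } else {
        if (att_active[i]) {
          # pursuing another candidate: the standing attempt stays pending
          if (is.na(att_pending[i])) { att_pending[i] <<- t; att_cause[i] <<- "miss" }
          if (pars$phase != "search" && cm_count[i] >= 2L)
            close_attempt(i, "miss", t)        # durable switch to a new target
          else if (t - att_pending[i] > att_gap_max)
            close_attempt(i, att_cause[i], t)
        }
        if (!att_active[i] && pars$phase != "search" && cm_count[i] >= 2L) {
          att_active[i] <<- TRUE; att_prey[i] <<- tgt; att_start[i] <<- cm_t0[i]
        }
      }
      vph <- if (pars$phase == "buzz1" || pars$phase == "buzz2") 2 else 3.5
      sv <- steer(act$phi_target, vph)
      tgx[i] <<- bx[i] + act$range_est * cos(bh[i] + act$phi_target)
      tgy[i] <<- by[i] + act$range_est * sin(bh[i] + act$phi_target)
    } else {
      if (att_active[i]) {
        if (is.na(att_pending[i])) {
          att_pending[i] <<- t; att_cause[i] <<- "miss"
        } else if (t - att_pending[i] > att_gap_max)
          close_attempt(i, att_cause[i], t)
      }
      target[i] <<- 0L
      tgx[i] <<- NA_real_; tgy[i] <<- NA_real_
      pars <- phase_and_call_params(NULL, tf_off, sl_off, sdur)
      w <- stats::rnorm(1, 0, 1)
      sv <- list(speed = 3.5, ang_vel = sign(w) * min(abs(w), 4 / 3.5))
    }
    bs[i] <<- sv$speed; bw_[i] <<- sv$ang_vel

    k <- L$n + 1L
    L$t[k] <- t; L$bat[k] <- i
    L$x[k] <- bx[i]; L$y[k] <- by[i]; L$heading[k] <- bh[i]
    L$ipi_s[k] <- pars$ipi_s; L$dur_ms[k] <- pars$dur_ms
    L$tf_khz[k] <- pars$tf_khz; L$bw_khz[k] <- pars$bw_khz
    L$sl_db[k] <- pars$sl_db; L$phase[k] <- pars$phase
    L$call_target[k] <- target[i]
    L$n <- k
    last_call[i] <<- k
    cur_ipi[i] <<- pars$ipi_s
    next_emit[i] <<- t + pars$ipi_s
  }

  t <- 0
  for (tick in seq_len(n_ticks)) {
    t <- (tick - 1) * dt
    # emissions + per-IPI decisions
    due <- which(next_emit <= t + 1e-12)
    for (i in due) process_emission(i, t)
    # prey kinematics
    prey <- step_prey(prey, t, dt, ar)
    # bat kinematics; pursuing bats re-aim at the estimated target point
    # every tick (turn rate still bounded by the 4 m/s^2 limit)
    pu <- which(!is.na(tgx))
    if (length(pu)) {
      phi_t <- wrap_angle(atan2(tgy[pu] - by[pu], tgx[pu] - bx[pu]) - bh[pu])
      wmax <- 4 / pmax(bs[pu], 0.5)
      bw_[pu] <- sign(phi_t) * pmin(10 * abs(phi_t), wmax)
    }
    bh <- wrap_heading(bh + bw_ * dt)
    bx <- bx + bs * cos(bh) * dt
    by <- by + bs * sin(bh) * dt
    # border safety: reflect inward (avoidance normally prevents this)
    out <- bx <= 0 | bx >= ar$width | by <= 0 | by >= ar$height
    if (any(out)) {
      for (i in which(out)) {
        bx[i] <- min(max(bx[i], 0), ar$width)
        by[i] <- min(max(by[i], 0), ar$height)
        bh[i] <- atan2(ar$height / 2 - by[i], ar$width / 2 - bx[i])
      }
    }
    # captures
    hunting <- which(target > 0L)
    if (length(hunting)) {
      dcap <- sqrt((prey$x[target[hunting]] - bx[hunting])^2 +
                     (prey$y[target[hunting]] - by[hunting])^2)
      for (j in which(dcap < 0.05)) {
        i <- hunting[j]; p <- target[i]
        if (p <= 0L) next  # prey already captured and respawned this tick
        if (!att_active[i] || att_prey[i] != p) {
          # capture before the two-call confirmation: register the attack now
          if (att_active[i]) close_attempt(i, "miss", t)
          att_active[i] <- TRUE; att_prey[i] <- p
          att_start[i] <- if (cm_tgt[i] == p) cm_t0[i] else t
        }
        close_attempt(i, "capture", t)
        # competitors committed to the same prey lose it; one that had
        # already broken off overtly (avoidance maneuver) keeps that label,
        # but a momentary sensory gap still counts as losing the prey
        losers <- which(att_active & att_prey == p)
        for (l in losers) {
          oc <- if (!is.na(att_pending[l]) && att_cause[l] != "miss")
            att_cause[l] else "lost_to_conspecific"
          close_attempt(l, oc, t)
        }
        target[target == p] <- 0L
        cm_count[cm_tgt == p] <- 0L
        nw <- respawn_prey(ar, t)
        for (nm in names(nw)) prey[[nm]][p] <- nw[[nm]]
      }
    }
  }

  n <- L$n
  calls <- data.frame(
    t = L$t[seq_len(n)], bat = L$bat[seq_len(n)], phase = L$phase[seq_len(n)],
    ipi_s = L$ipi_s[seq_len(n)], dur_ms = L$dur_ms[seq_len(n)],
    tf_khz = L$tf_khz[seq_len(n)], bw_khz = L$bw_khz[seq_len(n)],
    sl_db = L$sl_db[seq_len(n)], target = L$call_target[seq_len(n)],
    focal_prey = L$focal_prey[seq_len(n)],
    focal_audible = L$focal_audible[seq_len(n)],
    focal_jammed = L$focal_jammed[seq_len(n)],
    focal_level_db = L$focal_level_db[seq_len(n)],
    focal_dist_m = L$focal_dist_m[seq_len(n)],
    range_est_m = L$range_est_m[seq_len(n)],
    masker_tf_khz = L$masker_tf_khz[seq_len(n)],
    n_detected = L$n_detected[seq_len(n)],
    false_alarm = L$false_alarm[seq_len(n)],
    x = L$x[seq_len(n)], y = L$y[seq_len(n)], heading = L$heading[seq_len(n)]
  )
  na <- A$n
  attempts <- data.frame(bat = A$bat[seq_len(na)], prey = A$prey[seq_len(na)],
                         t_start = A$t_start[seq_len(na)],
                         t_end = A$t_end[seq_len(na)],
                         outcome = A$outcome[seq_len(na)])
  trial <- structure(list(config = cfg, seed = seed, calls = calls,
                          attempts = attempts), class = "echojam_trial")
  trial$summary <- trial_summary(trial)
  trial
}

#' @export
print.echojam_trial <- function(x, ...) {
  print(x$config)
  print(x$summary)
  invisible(x)
}
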