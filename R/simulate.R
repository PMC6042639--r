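GRAVITY <- 9.80665

# Minimal-jerk unit profiles on tau in [0, 1]: position runs 0 -> 1 with
# zero velocity/acceleration at both ends; rate integrates to exactly 1.
mj_pos <- function(tau) 10 * tau^3 - 15 * tau^4 + 6 * tau^5
mj_rate <- function(tau) 30 * (tau^2 - 2 * tau^3 + tau^4)

#' Default gesture kinematic parameters
#'
#' Per-kind sampling ranges for the simulator's hand-to-mouth gesture
#' templates. Every hand gesture is a minimal-jerk wrist-pitch rotation
#' (raise), a stationary hold (dwell), and the reverse rotation (lower);
#' kinds differ in their duration and pitch-excursion ranges. The
#' smoking defaults are drawn strictly inside the drag-detector bounds
#' (raise 0.3--0.7 s, dwell 0.4--8.0 s) so boundary behaviour is
#' unambiguous; drinking and eating overlap those bounds only partially,
#' which is what makes the temporal pattern stages necessary.
#'
#' @return named list of per-kind parameter ranges (seconds, radians).
#' @export
gesture_params <- function() {
  list(
    smoking   = list(raise = c(0.35, 0.65), dwell = c(1.0, 4.0),
                     lower = c(0.4, 0.8),   pitch = c(1.2, 1.6)),
    drink_sip = list(raise = c(0.5, 1.0),   dwell = c(1.0, 3.0),
                     lower = c(0.5, 1.0),   pitch = c(1.4, 1.9)),
    eat_bite  = list(raise = c(0.6, 1.2),   dwell = c(0.2, 0.6),
                     lower = c(0.5, 1.0),   pitch = c(0.9, 1.4)),
    walk      = list(duration = c(15, 60), swing_rad_s = c(1.0, 1.5),
                     cadence_hz = c(0.8, 1.0))
  )
}

draw_range <- function(range) runif(1L, range[1L], range[2L])

# Sample indices whose timestamps fall in [t0, t1), for a stream of
# n samples at rate_hz starting at t = 0.
seg_indices <- function(t0, t1, rate_hz, n) {
  i0 <- floor(t0 * rate_hz + 1e-9) + 1L
  i1 <- ceiling(t1 * rate_hz - 1e-9)
  if (i1 < i0) return(integer(0))
  seq.int(max(i0, 1L), min(i1, n))
}

# A scheduled gesture/walk table: kind, t_start plus per-kind params.
empty_schedule <- function() {
  tibble::tibble(kind = character(), t_start = numeric(),
                 raise_s = numeric(), dwell_s = numeric(),
                 lower_s = numeric(), pitch = numeric(),
                 duration_s = numeric(), swing = numeric(),
                 cadence = numeric(), phase = numeric())
}

schedule_row <- function(kind, t_start, raise_s = NA_real_, dwell_s = NA_real_,
                         lower_s = NA_real_, pitch = NA_real_,
                         duration_s = NA_real_, swing = NA_real_,
                         cadence = NA_real_, phase = NA_real_) {
  if (is.na(duration_s)) duration_s <- raise_s + dwell_s + lower_s
  tibble::tibble(kind = kind, t_start = t_start, raise_s = raise_s,
                 dwell_s = dwell_s, lower_s = lower_s, pitch = pitch,
                 duration_s = duration_s, swing = swing, cadence = cadence,
                 phase = phase)
}

draw_gesture <- function(kind, t_start, params) {
  p <- params[[kind]]
  # durations are drawn from strictly positive uniform ranges; re-draw
  # defensively if a custom range ever produces a non-positive value
  draw_pos <- function(range) {
    for (i in 1:100) {
      x <- draw_range(range)
      if (x > 0) return(x)
    }
    stop("simulation error: could not draw a positive duration", call. = FALSE)
  }
  schedule_row(kind, t_start,
               raise_s = draw_pos(p$raise), dwell_s = draw_pos(p$dwell),
               lower_s = draw_pos(p$lower), pitch = draw_range(p$pitch))
}

# Render a schedule into a 6-channel stream plus truth annotations.
# Background is a resting wrist (pitch 0, gravity on +z); hand gestures
# rotate the wrist about the y (pitch) axis; accelerometer channels are
# the gravity projection of the instantaneous pitch angle.
build_stream <- function(schedule, total_s, rate_hz = 100,
                         noise_sd_accel = 0.3, noise_sd_gyro = 0.05,
                         truth_rule = session_config()) {
  n <- floor(total_s * rate_hz + 1e-9)
  t <- (seq_len(n) - 1L) / rate_hz
  theta <- numeric(n)
  gy <- numeric(n)
  gx <- numeric(n); gz <- numeric(n)
  ax_x <- numeric(n); ay_x <- numeric(n); az_x <- numeric(n)
  ev <- list()
  add_ev <- function(label, t0, t1) {
    ev[[length(ev) + 1L]] <<- tibble::tibble(
      label = label, t_start = t0, t_end = t1, source = "truth")
  }
  if (nrow(schedule) > 0L) {
    schedule <- schedule[order(schedule$t_start), ]
  }
  for (k in seq_len(nrow(schedule))) {
    s <- schedule[k, ]
    if (s$kind == "walk") {
      idx <- seg_indices(s$t_start, s$t_start + s$duration_s, rate_hz, n)
      tl <- t[idx] - s$t_start
      gy[idx] <- gy[idx] + s$swing * sin(2 * pi * s$cadence * tl + s$phase)
      gz[idx] <- gz[idx] + 0.5 * s$swing * sin(2 * pi * s$cadence * tl + s$phase + 1)
      az_x[idx] <- az_x[idx] + 1.5 * sin(2 * pi * 2 * s$cadence * tl + s$phase)
      ax_x[idx] <- ax_x[idx] + 0.8 * sin(2 * pi * 2 * s$cadence * tl + s$phase + 0.5)
      add_ev("walk", s$t_start, s$t_start + s$duration_s)
      next
    }
    t_raise0 <- s$t_start
    t_dwell0 <- t_raise0 + s$raise_s
    t_lower0 <- t_dwell0 + s$dwell_s
    t_end <- t_lower0 + s$lower_s
    i_r <- seg_indices(t_raise0, t_dwell0, rate_hz, n)
    tau <- (t[i_r] - t_raise0) / s$raise_s
    gy[i_r] <- s$pitch / s$raise_s * mj_rate(tau)
    theta[i_r] <- s$pitch * mj_pos(tau)
    i_d <- seg_indices(t_dwell0, t_lower0, rate_hz, n)
    theta[i_d] <- s$pitch
    i_l <- seg_indices(t_lower0, t_end, rate_hz, n)
    tau <- (t[i_l] - t_lower0) / s$lower_s
    gy[i_l] <- -s$pitch / s$lower_s * mj_rate(tau)
    theta[i_l] <- s$pitch * (1 - mj_pos(tau))
    add_ev("raise", t_raise0, t_dwell0)
    add_ev("dwell", t_dwell0, t_lower0)
    add_ev("lower", t_lower0, t_end)
    add_ev(if (s$kind == "smoking") "drag" else s$kind, t_raise0, t_end)
  }
  noise <- function(sd) if (sd > 0) rnorm(n, 0, sd) else numeric(n)
  stream <- imu_stream(tibble::tibble(
    t = t,
    ax = GRAVITY * sin(theta) + ax_x + noise(noise_sd_accel),
    ay = ay_x + noise(noise_sd_accel),
    az = GRAVITY * cos(theta) + az_x + noise(noise_sd_accel),
    gx = gx + noise(noise_sd_gyro),
    gy = gy + noise(noise_sd_gyro),
    gz = gz + noise(noise_sd_gyro)), rate_hz = rate_hz)
  events <- if (length(ev) > 0L) event_intervals(do.call(rbind, ev)) else event_intervals()
  drags <- filter_events(events, label = "drag")
  if (nrow(drags) > 0L) {
    inst <- detect_smoking_instances(
      tibble::tibble(t_start = drags$t_start, t_end = drags$t_end),
      truth_rule)
    if (nrow(inst) > 0L) {
      events <- event_intervals(rbind(
        events,
        tibble::tibble(label = "smoking_instance", t_start = inst$t_start,
                       t_end = inst$t_end, source = "truth")))
    }
  }
  list(stream = stream, events = events)
}

#' Simulate a single cigarette drag
#'
#' Generates one raise/dwell/lower hand-to-mouth gesture flanked by short
#' idle lead-in and tail, together with its truth annotation (raise,
#' dwell, lower sub-intervals and the enclosing drag interval). The
#' gyroscope pitch channel (`gy`) integrates to `pitch_excursion_rad`
#' over the raise and to its negative over the lower.
#'
#' @param raise_s,dwell_s,lower_s segment durations in seconds; `NULL`
#'   draws from the smoking ranges in `params`.
#' @param pitch_excursion_rad wrist rotation amplitude in radians; `NULL`
#'   draws from `params`.
#' @param params gesture parameter set, see [gesture_params()].
#' @param noise_sd_accel,noise_sd_gyro per-channel Gaussian noise SD
#'   (m/s^2, rad/s).
#' @param rate_hz sampling rate.
#' @param lead_s,tail_s idle padding around the gesture.
#' @param seed integer seed; `NULL` uses the current RNG state.
#' @return list with elements `stream` (an [imu_stream()]) and `events`
#'   (truth [event_intervals()]).
#' @export
simulate_drag <- function(raise_s = NULL, dwell_s = NULL, lower_s = NULL,
                          pitch_excursion_rad = NULL, params = gesture_params(),
                          noise_sd_accel = 0.3, noise_sd_gyro = 0.05,
                          rate_hz = 100, lead_s = 1, tail_s = 1, seed = NULL) {
  run <- function() {
    g <- draw_gesture("smoking", lead_s, params)
    if (!is.null(raise_s)) g$raise_s <- raise_s
    if (!is.null(dwell_s)) g$dwell_s <- dwell_s
    if (!is.null(lower_s)) g$lower_s <- lower_s
    if (!is.null(pitch_excursion_rad)) g$pitch <- pitch_excursion_rad
    stopifnot(g$raise_s > 0, g$dwell_s > 0, g$lower_s > 0)
    g$duration_s <- g$raise_s + g$dwell_s + g$lower_s
    build_stream(g, total_s = lead_s + g$duration_s + tail_s,
                 rate_hz = rate_hz, noise_sd_accel = noise_sd_accel,
                 noise_sd_gyro = noise_sd_gyro)
  }
  if (is.null(seed)) run() else withr::with_seed(seed, run())
}

#' Describe a smoking-session scenario
#'
#' A scenario bundles the timing structure of one simulated smoking
#' session (a run of drags with bounded start-to-start gaps) with
#' confounder event rates and noise levels. Defaults place every drawn
#' drag strictly inside the detector's raise/dwell bounds and every gap
#' under the 80 s session bound, so a default session carries exactly
#' one truth smoking instance when `n_drags >= 6`.
#'
#' @param n_drags number of drags in the run (non-negative integer).
#' @param gap_range start-to-start inter-drag gap range in seconds.
#' @param gaps optional explicit vector of `n_drags - 1` start-to-start
#'   gaps, overriding `gap_range`.
#' @param confounder_rates named events-per-hour rates for
#'   `drink_sip`, `eat_bite`, `walk` placed outside the drag run.
#' @param total_duration_s total stream length; `NULL` sizes it to the
#'   drag run plus `tail_s`.
#' @param lead_in_s idle time before the first drag.
#' @param tail_s idle time after the last gesture.
#' @param noise_sd_accel,noise_sd_gyro channel noise SDs.
#' @param params gesture parameter set, see [gesture_params()].
#' @param rate_hz sampling rate.
#' @param truth_rule [session_config()] used to label truth smoking
#'   instances from truth drags.
#' @param seed integer seed.
#' @return a `session_scenario` list.
#' @export
session_scenario <- function(n_drags = 10, gap_range = c(20, 60), gaps = NULL,
                             confounder_rates = c(drink_sip = 0, eat_bite = 0,
                                                  walk = 0),
                             total_duration_s = NULL, lead_in_s = 10,
                             tail_s = 10, noise_sd_accel = 0.3,
                             noise_sd_gyro = 0.05, params = gesture_params(),
                             rate_hz = 100, truth_rule = session_config(),
                             seed = 1) {
  stopifnot(n_drags >= 0, is.null(gaps) || length(gaps) == max(n_drags - 1, 0))
  structure(list(n_drags = n_drags, gap_range = gap_range, gaps = gaps,
                 confounder_rates = confounder_rates,
                 total_duration_s = total_duration_s, lead_in_s = lead_in_s,
                 tail_s = tail_s, noise_sd_accel = noise_sd_accel,
                 noise_sd_gyro = noise_sd_gyro, params = params,
                 rate_hz = rate_hz, truth_rule = truth_rule, seed = seed),
            class = "session_scenario")
}

# Poisson placement of confounder gestures/walk bouts into a stream of
# length total_s, rejecting candidates that overlap already-placed
# events (2 s margin). Returns additional schedule rows.
place_confounders <- function(rates, total_s, occupied, params,
                              margin_s = 2, max_tries = 200) {
  rows <- empty_schedule()
  overlaps <- function(t0, t1, occ) {
    nrow(occ) > 0L && any(t0 < occ$t_end + margin_s & t1 > occ$t_start - margin_s)
  }
  for (kind in names(rates)) {
    rate <- rates[[kind]]
    if (rate <= 0) next
    n_ev <- rpois(1L, rate * total_s / 3600)
    for (i in seq_len(n_ev)) {
      placed <- FALSE
      for (try in seq_len(max_tries)) {
        if (kind == "walk") {
          p <- params$walk
          row <- schedule_row("walk", 0, duration_s = draw_range(p$duration),
                              swing = draw_range(p$swing_rad_s),
                              cadence = draw_range(p$cadence_hz),
                              phase = runif(1L, 0, 2 * pi))
        } else {
          row <- draw_gesture(kind, 0, params)
        }
        t0 <- runif(1L, 0, max(total_s - row$duration_s, 0))
        if (!overlaps(t0, t0 + row$duration_s, occupied)) {
          row$t_start <- t0
          rows <- rbind(rows, row)
          occupied <- rbind(occupied,
                            tibble::tibble(t_start = t0,
                                           t_end = t0 + row$duration_s))
          placed <- TRUE
          break
        }
      }
      if (!placed) {
        stop("placement error: could not place ", kind, " event ", i,
             " of ", n_ev, " without overlap", call. = FALSE)
      }
    }
  }
  rows
}

#' Simulate a smoking session with optional confounders
#'
#' Draws `n_drags` drag gestures with start-to-start gaps from the
#' scenario, places confounder gestures at the configured hourly rates
#' in the remaining time, renders the 6-axis stream, and labels truth
#' events including `smoking_instance` intervals derived from the truth
#' drags by the scenario's session rule.
#'
#' @param scenario a [session_scenario()].
#' @return list with `stream` and `events` (truth annotations).
#' @export
simulate_session <- function(scenario) {
  stopifnot(inherits(scenario, "session_scenario"))
  withr::with_seed(scenario$seed, {
    sch <- empty_schedule()
    t_cur <- scenario$lead_in_s
    for (k in seq_len(scenario$n_drags)) {
      g <- draw_gesture("smoking", t_cur, scenario$params)
      sch <- rbind(sch, g)
      if (k < scenario$n_drags) {
        gap <- if (!is.null(scenario$gaps)) scenario$gaps[k] else
          draw_range(scenario$gap_range)
        if (gap <= g$duration_s) {
          stop("placement error: inter-drag gap ", round(gap, 2),
               " s shorter than drag ", k, " duration", call. = FALSE)
        }
        t_cur <- t_cur + gap
      } else {
        t_cur <- t_cur + g$duration_s
      }
    }
    total_s <- if (is.null(scenario$total_duration_s)) {
      t_cur + scenario$tail_s
    } else {
      scenario$total_duration_s
    }
    if (nrow(sch) > 0L && total_s < max(sch$t_start + sch$duration_s)) {
      n_out <- sum(sch$t_start + sch$duration_s > total_s)
      stop("placement error: total_duration_s too short, ", n_out,
           " drag(s) do not fit", call. = FALSE)
    }
    occ <- tibble::tibble(t_start = sch$t_start,
                          t_end = sch$t_start + sch$duration_s)
    sch <- rbind(sch, place_confounders(scenario$confounder_rates, total_s,
                                        occ, scenario$params))
    build_stream(sch, total_s, rate_hz = scenario$rate_hz,
                 noise_sd_accel = scenario$noise_sd_accel,
                 noise_sd_gyro = scenario$noise_sd_gyro,
                 truth_rule = scenario$truth_rule)
  })
}

#' Simulate free-living wear
#'
#' Places whole smoking sessions, confounder gestures and walking bouts
#' as independent homogeneous Poisson processes over the recording,
#' enforcing non-overlap by rejection, over an idle background.
#'
#' @param duration_s recording length in seconds.
#' @param rates named events-per-hour vector with any of `smoking`,
#'   `drink_sip`, `eat_bite`, `walk` (missing kinds default to 0).
#' @param n_drags drags per placed smoking session.
#' @param gap_range start-to-start inter-drag gap range within a session.
#' @param params gesture parameter set.
#' @param noise_sd_accel,noise_sd_gyro channel noise SDs.
#' @param rate_hz sampling rate.
#' @param truth_rule [session_config()] for truth instance labelling.
#' @param seed integer seed.
#' @param signal if `FALSE`, skip waveform rendering and return only the
#'   truth events (`stream = NULL`); used for fast event-statistics work.
#' @return list with `stream` (or `NULL`) and `events`.
#' @export
simulate_free_living <- function(duration_s, rates = c(smoking = 1,
                                                       drink_sip = 4,
                                                       eat_bite = 20,
                                                       walk = 2),
                                 n_drags = 10, gap_range = c(20, 60),
                                 params = gesture_params(),
                                 noise_sd_accel = 0.3, noise_sd_gyro = 0.05,
                                 rate_hz = 100,
                                 truth_rule = session_config(), seed = 1,
                                 signal = TRUE) {
  stopifnot(duration_s > 0, all(rates >= 0))
  withr::with_seed(seed, {
    sch <- empty_schedule()
    occupied <- tibble::tibble(t_start = numeric(), t_end = numeric())
    # smoking sessions first (longest envelopes): draw the whole drag run,
    # then place its envelope uniformly with rejection
    n_smk <- if (!is.na(rates["smoking"]) && rates[["smoking"]] > 0) {
      rpois(1L, rates[["smoking"]] * duration_s / 3600)
    } else 0L
    for (i in seq_len(n_smk)) {
      run <- empty_schedule()
      t_cur <- 0
      for (k in seq_len(n_drags)) {
        g <- draw_gesture("smoking", t_cur, params)
        run <- rbind(run, g)
        t_cur <- t_cur + if (k < n_drags) draw_range(gap_range) else g$duration_s
      }
      env_len <- t_cur
      placed <- FALSE
      for (try in 1:200) {
        t0 <- runif(1L, 0, max(duration_s - env_len, 0))
        if (nrow(occupied) == 0L ||
            !any(t0 < occupied$t_end + 2 & t0 + env_len > occupied$t_start - 2)) {
          run$t_start <- run$t_start + t0
          sch <- rbind(sch, run)
          occupied <- rbind(occupied,
                            tibble::tibble(t_start = t0, t_end = t0 + env_len))
          placed <- TRUE
          break
        }
      }
      if (!placed) {
        stop("placement error: could not place smoking session ", i, " of ",
             n_smk, " without overlap", call. = FALSE)
      }
    }
    other <- rates[setdiff(names(rates), "smoking")]
    sch <- rbind(sch, place_confounders(other, duration_s, occupied, params))
    if (!signal) {
      out <- build_truth_only(sch, truth_rule)
      return(list(stream = NULL, events = out))
    }
    build_stream(sch, duration_s, rate_hz = rate_hz,
                 noise_sd_accel = noise_sd_accel,
                 noise_sd_gyro = noise_sd_gyro, truth_rule = truth_rule)
  })
}

# Truth annotations for a schedule without rendering the waveform.
build_truth_only <- function(schedule, truth_rule = session_config()) {
  ev <- list()
  for (k in seq_len(nrow(schedule))) {
    s <- schedule[k, ]
    if (s$kind == "walk") {
      ev[[length(ev) + 1L]] <- tibble::tibble(
        label = "walk", t_start = s$t_start,
        t_end = s$t_start + s$duration_s, source = "truth")
      next
    }
    t_d <- s$t_start + s$raise_s
    t_l <- t_d + s$dwell_s
    t_e <- t_l + s$lower_s
    lab <- if (s$kind == "smoking") "drag" else s$kind
    ev[[length(ev) + 1L]] <- tibble::tibble(
      label = c("raise", "dwell", "lower", lab),
      t_start = c(s$t_start, t_d, t_l, s$t_start),
      t_end = c(t_d, t_l, t_e, t_e), source = "truth")
  }
  events <- if (length(ev) > 0L) event_intervals(do.call(rbind, ev)) else
    event_intervals()
  drags <- filter_events(events, label = "drag")
  if (nrow(drags) > 0L) {
    inst <- detect_smoking_instances(
      tibble::tibble(t_start = drags$t_start, t_end = drags$t_end), truth_rule)
    if (nrow(inst) > 0L) {
      events <- event_intervals(rbind(
        events, tibble::tibble(label = "smoking_instance",
                               t_start = inst$t_start, t_end = inst$t_end,
                               source = "truth")))
    }
  }
  events
}
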