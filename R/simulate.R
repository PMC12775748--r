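# Synthetic dual-device night generator.
#
# Signal model: one latent vasomotor drive (baseline amplitude 1, modulated
# multiplicatively by respiration and by transient vasoconstriction dips)
# shapes the beat-to-beat amplitude of a quasi-periodic pulse waveform shared
# by both devices. The wrist record is the same physiological signal sampled
# on a clock offset by `clock_lag`, scaled by its device gain, with its own
# noise, motion artifacts, accelerometer channel and hourly sync pauses.

# Pulse template: two smooth lobes — a sharp systolic lobe (fast rise, the
# detected peak) plus a broader, smaller dicrotic lobe on the decay — scaled
# so peak-to-trough equals exactly 1 over one cycle.
pulse_template_grid <- local({
  p <- seq(0, 1, length.out = 2048L)
  raw <- exp(-((p - 0.22) / 0.09)^2) + 0.32 * exp(-((p - 0.55) / 0.16)^2)
  list(p = p, v = (raw - min(raw)) / (max(raw) - min(raw)),
       peak_phase = p[which.max(raw)])
})

pulse_template <- function(phase) {
  stats::approx(pulse_template_grid$p, pulse_template_grid$v,
                xout = phase, rule = 2)$y
}

# Multiplicative event factor at times t for an event table
# (start, end, depth). Smooth mode uses raised-cosine onset/recovery ramps of
# min(3 s, duration/4); rect mode is a flat dip (closed-form Mvasoc).
event_factor <- function(t, events, shape = "smooth") {
  f <- rep(1, length(t))
  if (is.null(events) || nrow(events) == 0L) return(f)
  for (i in seq_len(nrow(events))) {
    s <- events$start[i]; e <- events$end[i]; d <- events$depth[i]
    idx <- which(t >= s & t < e)
    if (!length(idx)) next
    if (shape == "rect") {
      w <- rep(1, length(idx))
    } else {
      ramp <- min(3, (e - s) / 4)
      tt <- t[idx]
      w <- rep(1, length(idx))
      on <- tt < s + ramp
      off <- tt > e - ramp
      w[on] <- 0.5 * (1 - cos(pi * (tt[on] - s) / ramp))
      w[off] <- 0.5 * (1 - cos(pi * (e - tt[off]) / ramp))
    }
    f[idx] <- f[idx] * (1 - d * w)
  }
  f
}

#' Latent beat-amplitude envelope of a simulated night
#'
#' Evaluates, at arbitrary true times, the dimensionless amplitude envelope
#' (respiratory modulation times vasoconstriction dips, baseline 1) that
#' drove a simulated night. Used to check that the extracted PPGamp series
#' tracks the ground truth.
#'
#' @param config The [sim_config()] used for the simulation.
#' @param truth The ground-truth list returned by [simulate_night()].
#' @param t Times (seconds, true/finger clock) at which to evaluate.
#' @return Numeric envelope values, baseline 1.
#' @export
latent_envelope <- function(config, truth, t) {
  resp <- 1 + config$resp_mod_depth * sin(2 * pi * config$resp_freq * t)
  resp * event_factor(t, truth$events, config$event_shape)
}

#' Simulate one night of paired finger and wrist PPG
#'
#' Generates a finger record and a wrist record sharing one latent vasomotor
#' drive, plus the ground truth needed to validate every pipeline stage:
#' injected events, the true clock lag, sync-gap intervals and true beat-peak
#' times. Identical config (including seed) gives bit-identical output.
#'
#' @param config A [sim_config()].
#' @return A list with elements `finger` and `wrist` ([ppg_record()]s) and
#'   `truth` (list: `events` data frame with columns start/end/depth,
#'   `true_lag`, `gap_intervals` matrix, `beat_times`).
#' @export
simulate_night <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  validate_sim_config(config)
  with_seed(config$seed, {
    dur <- config$duration

    ## vasoconstriction events: Poisson count, starts rejection-sampled to
    ## non-overlap (>= 1 s apart) so realized count equals the Poisson draw
    n_ev <- stats::rpois(1L, config$event_rate * dur / 3600)
    ## slow within-night vasomotor activity cycle (random phase per night):
    ## event starts are rejection-sampled proportional to it (count
    ## preserved) and event depths scale with it
    act_phase <- stats::runif(1, 0, 2 * pi)
    activity <- function(t)
      1 + config$activity_mod * sin(2 * pi * t / config$activity_cycle_s + act_phase)
    events <- data.frame(start = numeric(0), end = numeric(0), depth = numeric(0))
    if (n_ev > 0L) {
      durs <- rnorm_bounded(n_ev, config$event_dur_mean, config$event_dur_sd,
                            config$event_dur_bounds[1], config$event_dur_bounds[2])
      deps <- rnorm_bounded(n_ev, config$event_depth_mean, config$event_depth_sd,
                            config$event_depth_bounds[1], config$event_depth_bounds[2])
      amax <- 1 + config$activity_mod
      starts <- numeric(0); ends <- numeric(0)
      for (i in seq_len(n_ev)) {
        placed <- FALSE
        for (try in 1:1000) {
          s <- stats::runif(1, 0, max(dur - durs[i], 1e-9))
          if (stats::runif(1) > activity(s) / amax) next
          e <- s + durs[i]
          if (!length(starts) || all(e + 1 < starts | s > ends + 1)) {
            starts <- c(starts, s); ends <- c(ends, e); placed <- TRUE; break
          }
        }
        if (!placed)
          stop_vw("could not place %d non-overlapping events in %g s; reduce event_rate",
                  n_ev, dur, class = "vasowave_config_error")
      }
      deps <- pmin(pmax(deps[seq_along(starts)] * activity(starts),
                        config$event_depth_bounds[1]),
                   config$event_depth_bounds[2])
      ord <- order(starts)
      events <- data.frame(start = starts[ord], end = ends[ord],
                           depth = deps[ord])
    }

    ## shared beat sequence (true clock); extended beyond [0, dur] so the
    ## lag-shifted wrist grid stays in range
    mean_iv <- 60 / config$pulse_rate_bpm
    n_beats <- ceiling((dur + 120) / mean_iv * 1.5) + 10L
    bpm <- stats::rnorm(n_beats, config$pulse_rate_bpm, config$pulse_jitter_sd_bpm)
    bpm <- pmin(pmax(bpm, config$pulse_rate_bpm / 2), config$pulse_rate_bpm * 2)
    onsets <- -60 + cumsum(c(0, 60 / bpm[-n_beats]))
    periods <- c(diff(onsets), mean_iv)
    peak_times <- onsets + pulse_template_grid$peak_phase * periods
    in_night <- peak_times >= 0 & peak_times < dur

    physio <- function(t) {
      b <- findInterval(t, onsets)
      b[b < 1L] <- 1L
      b[b > length(onsets)] <- length(onsets)
      phase <- (t - onsets[b]) / periods[b]
      phase <- pmin(pmax(phase, 0), 1)
      env <- latent_envelope(config, list(events = events), t)
      env * pulse_template(phase)
    }

    make_record <- function(device) {
      fs <- config$sample_rate[[device]]
      gain <- config$device_gain[[device]]
      noise <- config$device_noise_sd[[device]]
      n <- floor(dur * fs)
      t_rec <- (seq_len(n) - 1L) / fs
      t_true <- if (device == "wrist") t_rec - config$clock_lag else t_rec
      x <- gain * physio(t_true)
      if (noise > 0) x <- x + stats::rnorm(n, 0, noise * gain)
      accel <- NULL
      if (device == "wrist") {
        accel <- abs(stats::rnorm(n, 0, 0.01))
        n_mb <- stats::rpois(1L, config$motion_artifact_rate * dur / 3600)
        if (n_mb > 0L) {
          for (j in seq_len(n_mb)) {
            s <- stats::runif(1, 0, dur)
            len <- stats::runif(1, 2, 5)
            idx <- which(t_rec >= s & t_rec < s + len)
            if (!length(idx)) next
            accel[idx] <- stats::runif(length(idx), 0.3, 1.0)
            x[idx] <- x[idx] + gain * stats::rnorm(length(idx), 0, 1.5)
          }
        }
      }
      rec <- ppg_record(x, fs, device_id = device, participant_id = "sim",
                        night_id = sprintf("seed%d", config$seed),
                        accel_magnitude = accel)
      rec
    }

    finger <- make_record("finger")
    wrist <- make_record("wrist")

    gaps <- matrix(numeric(0), ncol = 2,
                   dimnames = list(NULL, c("start", "end")))
    if (config$hourly_pause) {
      wrist <- mask_hourly_pauses(wrist, 3600, config$pause_s)
      k <- seq_len(max(0L, floor(dur / 3600)))
      if (length(k))
        gaps <- cbind(start = k * 3600 - config$pause_s, end = k * 3600)
    }

    list(finger = finger, wrist = wrist,
         truth = list(events = events, true_lag = config$clock_lag,
                      gap_intervals = gaps,
                      beat_times = peak_times[in_night]))
  })
}
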