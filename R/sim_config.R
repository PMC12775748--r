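#' Configuration for the synthetic dual-device night generator
#'
#' The generator emulates one night of paired finger/wrist nocturnal PPG: a
#' quasi-periodic pulse waveform at sleep heart rates whose beat-to-beat
#' amplitude is modulated by respiration, by slow transient vasoconstriction
#' dips (the events of interest), and by device-specific gain and noise; the
#' wrist clock is offset by an unknown lag within +/-30 s; the wristband
#' pauses 5 minutes each hour to sync and suffers motion-artifact bursts
#' visible in its accelerometer channel.
#'
#' Defaults describe a realistic night: 55 bpm mean pulse at 0.25 Hz
#' respiration, 40 vasoconstriction events per hour (about 10 per 15-minute
#' segment, matching typical nocturnal event counts) with fractional depths
#' around 0.35 and durations around 20 s, a finger sensor with roughly twice
#' the gain and half the relative noise of the wrist sensor, and sample rates
#' of 100 Hz (finger, medical-grade) vs 25 Hz (wrist, wearable).
#'
#' @param duration Night length in seconds.
#' @param pulse_rate_bpm Mean pulse rate, beats/min.
#' @param pulse_jitter_sd_bpm Beat-to-beat pulse-rate jitter SD, beats/min.
#' @param resp_freq Respiratory frequency, Hz (must exceed 0.15 Hz so the
#'   respiratory band is removable by the preprocessing filter).
#' @param resp_mod_depth Fractional amplitude modulation by respiration.
#' @param event_rate Vasoconstriction events per hour.
#' @param event_depth_mean,event_depth_sd Fractional amplitude drop per event
#'   (mean, SD), truncated to `event_depth_bounds` (open interval in (0,1)).
#' @param event_depth_bounds Length-2 bounds for event depths, inside (0,1).
#' @param event_dur_mean,event_dur_sd Event duration in seconds (mean, SD),
#'   truncated to `event_dur_bounds`.
#' @param event_dur_bounds Length-2 positive bounds for event durations.
#' @param event_shape `"smooth"` (raised-cosine onset/recovery, default) or
#'   `"rect"` (rectangular dips, which admit closed-form Mvasoc for tests).
#' @param activity_cycle_s Period of the slow within-night vasomotor
#'   activity cycle, seconds (default 5400, the ~90-min sleep-cycle
#'   timescale). Nocturnal autonomic activity waxes and wanes within a
#'   night; event density and depth follow this cycle.
#' @param activity_mod Fractional modulation of event density and depth by
#'   the activity cycle, in `[0, 1)` (default 0.5; 0 disables it). The
#'   total expected event count is unchanged (the cycle redistributes
#'   events, it does not add them).
#' @param device_gain Named numeric, arbitrary-units multiplier per device.
#' @param device_noise_sd Named numeric, white-noise SD per device as a
#'   fraction of that device's pulse amplitude.
#' @param clock_lag Wrist clock offset in seconds (wrist minus finger),
#'   within `[-30, 30]`; an event at true time t appears at record time
#'   `t + clock_lag` on the wrist.
#' @param hourly_pause Insert a wristband sync pause each hour?
#' @param pause_s Pause length in seconds.
#' @param motion_artifact_rate Wrist motion-artifact bursts per hour.
#' @param sample_rate Named numeric, sampling rate per device in Hz.
#' @param seed Integer seed; identical seed implies bit-identical output.
#' @return A validated `sim_config` list.
#' @export
sim_config <- function(duration = 8 * 3600,
                       pulse_rate_bpm = 55,
                       pulse_jitter_sd_bpm = 3,
                       resp_freq = 0.25,
                       resp_mod_depth = 0.10,
                       event_rate = 40,
                       event_depth_mean = 0.35,
                       event_depth_sd = 0.12,
                       event_depth_bounds = c(0.05, 0.85),
                       event_dur_mean = 20,
                       event_dur_sd = 8,
                       event_dur_bounds = c(5, 60),
                       event_shape = c("smooth", "rect"),
                       activity_cycle_s = 5400,
                       activity_mod = 0.5,
                       device_gain = c(finger = 2, wrist = 1),
                       device_noise_sd = c(finger = 0.02, wrist = 0.05),
                       clock_lag = -8,
                       hourly_pause = TRUE,
                       pause_s = 300,
                       motion_artifact_rate = 2,
                       sample_rate = c(finger = 100, wrist = 25),
                       seed = 1L) {
  event_shape <- match.arg(event_shape)
  cfg <- list(duration = duration, pulse_rate_bpm = pulse_rate_bpm,
              pulse_jitter_sd_bpm = pulse_jitter_sd_bpm,
              resp_freq = resp_freq, resp_mod_depth = resp_mod_depth,
              event_rate = event_rate,
              event_depth_mean = event_depth_mean,
              event_depth_sd = event_depth_sd,
              event_depth_bounds = as.numeric(event_depth_bounds),
              event_dur_mean = event_dur_mean, event_dur_sd = event_dur_sd,
              event_dur_bounds = as.numeric(event_dur_bounds),
              event_shape = event_shape,
              activity_cycle_s = activity_cycle_s,
              activity_mod = activity_mod,
              device_gain = device_gain, device_noise_sd = device_noise_sd,
              clock_lag = clock_lag, hourly_pause = isTRUE(hourly_pause),
              pause_s = pause_s,
              motion_artifact_rate = motion_artifact_rate,
              sample_rate = sample_rate, seed = as.integer(seed))
  validate_sim_config(cfg)
  class(cfg) <- "sim_config"
  cfg
}

validate_sim_config <- function(cfg) {
  chk <- function(ok, msg) if (!ok) stop_vw(msg, class = "vasowave_config_error")
  chk(cfg$duration > 0, "duration must be positive")
  chk(cfg$pulse_rate_bpm > 0 && cfg$pulse_jitter_sd_bpm >= 0,
      "pulse rate must be positive, jitter SD non-negative")
  chk(cfg$resp_freq > 0, "resp_freq must be positive")
  chk(cfg$resp_mod_depth >= 0 && cfg$resp_mod_depth < 1,
      "resp_mod_depth must be in [0, 1)")
  chk(cfg$event_rate >= 0, "event_rate must be non-negative")
  db <- cfg$event_depth_bounds
  chk(length(db) == 2L && db[1] > 0 && db[2] < 1 && db[1] < db[2],
      "event depth bounds must lie in (0,1) with lower < upper")
  dd <- cfg$event_dur_bounds
  chk(length(dd) == 2L && dd[1] > 0 && dd[1] < dd[2],
      "event duration bounds must be positive with lower < upper")
  chk(cfg$activity_cycle_s > 0 && cfg$activity_mod >= 0 && cfg$activity_mod < 1,
      "activity cycle must be positive and activity_mod in [0, 1)")
  chk(all(cfg$device_gain > 0), "device gains must be positive")
  chk(all(cfg$device_noise_sd >= 0), "device noise SDs must be non-negative")
  chk(abs(cfg$clock_lag) <= 30,
      "clock_lag must lie within the +/-30 s alignment search window")
  chk(all(cfg$sample_rate > 0), "sample rates must be positive")
  chk(all(c("finger", "wrist") %in% names(cfg$device_gain)) &&
        all(c("finger", "wrist") %in% names(cfg$device_noise_sd)) &&
        all(c("finger", "wrist") %in% names(cfg$sample_rate)),
      "device_gain, device_noise_sd and sample_rate need 'finger' and 'wrist' entries")
  if (cfg$hourly_pause)
    chk(cfg$pause_s > 0 && cfg$pause_s < 3600, "pause_s must be in (0, 3600)")
  invisible(cfg)
}
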