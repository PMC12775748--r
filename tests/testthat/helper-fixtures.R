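# Shared fixtures, built once per test run and cached (several tests reuse
# the same simulated night; simulation is the expensive step).

.fixture_env <- new.env(parent = emptyenv())

get_fixture <- function(name, fn) {
  if (!exists(name, envir = .fixture_env)) assign(name, fn(), envir = .fixture_env)
  get(name, envir = .fixture_env)
}

# Default paired half-hour night used across modules.
fx_night <- function() {
  get_fixture("night_default", function() {
    cfg <- sim_config(duration = 1800, seed = 42)
    list(cfg = cfg, sim = simulate_night(cfg))
  })
}

# Noise-free night (no respiration, no motion, no pauses): latent envelope
# is exactly the event structure.
fx_clean_night <- function() {
  get_fixture("night_clean", function() {
    cfg <- sim_config(duration = 1200, seed = 7,
                      device_noise_sd = c(finger = 0, wrist = 0),
                      resp_mod_depth = 0, motion_artifact_rate = 0,
                      hourly_pause = FALSE)
    list(cfg = cfg, sim = simulate_night(cfg))
  })
}

# Raw -> clean segments for one record under default parameters.
process_segments <- function(record, grid_dt = 0.5) {
  beats <- detect_beats(record)
  series <- build_amp_series(beats, grid_dt, record = record)
  lapply(segment_night(series), function(sg)
    if (sg$viable) clean_segment(sg) else sg)
}

# An amp_series at the "normalized" stage built directly from values
# (bypassing beat detection) for closed-form marker tests.
make_norm_segment <- function(values, dt = 0.5, t0 = 0, mask = NULL) {
  s <- amp_series(values, t0 = t0, dt = dt, mask = mask, stage = "raw")
  s <- amp_advance_stage(s, "capped")
  s <- amp_advance_stage(s, "normalized")
  new_seg <- vasowave:::new_segment(1L, t0, t0 + length(values) * dt, s)
  new_seg
}

# Greedy one-to-one matcher of detected vs true beat times within `tol` s.
match_beat_times <- function(detected, truth, tol = 0.1) {
  used <- rep(FALSE, length(truth))
  hits <- 0L
  for (t in detected) {
    j <- which(!used & abs(truth - t) <= tol)
    if (length(j)) { used[j[1]] <- TRUE; hits <- hits + 1L }
  }
  c(recall = hits / length(truth), precision = hits / length(detected))
}
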