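#' Detect individual pulses in a raw PPG recording
#'
#' Finds pulse peaks by local-maxima search on a lightly smoothed copy of the
#' waveform (0.1-s moving average), keeping the tallest peak within any
#' minimum inter-peak distance of `60 / hr_max_bpm` seconds. Each peak is
#' paired with the minimum of the preceding inter-beat interval (the falling
#' trough of the previous pulse), and its amplitude is the peak minus that
#' trough — the PPGamp of the pulse. Beats whose support overlaps masked
#' samples are dropped, as are beats with amplitude below
#' `prominence_frac` times the local (rolling-median) amplitude scale.
#'
#' @param record A [ppg_record()] with at least 10 s of unmasked signal.
#' @param hr_min_bpm,hr_max_bpm Admissible pulse-rate range, beats/min
#'   (defaults 40-180, covering sleep heart rates).
#' @param prominence_frac Minimum beat amplitude relative to the rolling
#'   median amplitude (default 0.3).
#' @return A data frame of class `beat_measures` with columns `peak_time`,
#'   `trough_time`, `amplitude`, `pulse_duration` (peak-to-peak to the next
#'   beat; `NA` for the last). A flatline record yields zero rows with a
#'   warning.
#' @export
detect_beats <- function(record, hr_min_bpm = 40, hr_max_bpm = 180,
                         prominence_frac = 0.3) {
  stopifnot(inherits(record, "ppg_record"))
  fs <- record$sample_rate
  x <- record$samples
  x[record$gap_mask] <- NA_real_
  ok <- !is.na(x)
  if (sum(ok) < 10 * fs)
    stop_vw("record has less than 10 s of unmasked signal",
            class = "vasowave_insufficient_data")
  empty <- data.frame(peak_time = numeric(0), trough_time = numeric(0),
                      amplitude = numeric(0), pulse_duration = numeric(0))
  class(empty) <- c("beat_measures", "data.frame")
  if (stats::sd(x[ok]) == 0) {
    warning("flatline record: no beats detected")
    return(empty)
  }

  xr <- x
  xr[!ok] <- stats::approx(which(ok), x[ok], xout = which(!ok), rule = 2)$y
  xs <- moving_average(xr, max(1L, round(0.1 * fs)))

  n <- length(xs)
  cand <- which(diff(sign(diff(xs))) < 0) + 1L  # strict local maxima
  if (!length(cand)) {
    warning("no local maxima found: no beats detected")
    return(empty)
  }
  min_dist <- max(1L, round(60 / hr_max_bpm * fs))
  # keep tallest peaks first, suppress neighbours within min_dist
  keep <- logical(n)
  blocked <- logical(n)
  for (i in cand[order(xs[cand], decreasing = TRUE)]) {
    if (blocked[i]) next
    keep[i] <- TRUE
    blocked[max(1L, i - min_dist):min(n, i + min_dist)] <- TRUE
  }
  peaks <- which(keep)
  if (length(peaks) < 2L) {
    warning("fewer than 2 pulse peaks detected")
    return(empty)
  }

  max_iv <- round(60 / hr_min_bpm * fs)
  measure <- function(pk) {
    troughs <- integer(length(pk))
    amps <- numeric(length(pk))
    for (j in seq_along(pk)) {
      lo <- if (j == 1L) max(1L, pk[j] - max_iv) else max(pk[j - 1L], pk[j] - max_iv)
      win <- lo:(pk[j] - 1L)
      if (!length(win)) { troughs[j] <- NA_integer_; next }
      troughs[j] <- win[which.min(xs[win])]
      amps[j] <- xs[pk[j]] - xs[troughs[j]]
    }
    list(troughs = troughs, amps = amps)
  }
  # rolling upper-quantile amplitude scale; the median would be dragged down
  # when secondary (dicrotic) maxima outnumber true systolic peaks
  roll_scale <- function(a, k = 51L, q = 0.9) {
    n_a <- length(a)
    half <- k %/% 2L
    vapply(seq_len(n_a), function(j) {
      stats::quantile(a[max(1L, j - half):min(n_a, j + half)], q,
                      names = FALSE, type = 7)
    }, numeric(1))
  }

  m <- measure(peaks)
  good <- !is.na(m$troughs) & m$amps > 0
  peaks <- peaks[good]
  amps <- m$amps[good]
  if (length(amps) >= 3L)
    peaks <- peaks[amps >= prominence_frac * roll_scale(amps)]
  # remeasure so each surviving peak pairs with the minimum of its true
  # preceding inter-beat interval (secondary maxima no longer split it);
  # the first peak has no preceding beat, so it is dropped
  m <- measure(peaks)
  troughs <- m$troughs
  # locations were found on the smoothed signal; refine extrema on the raw
  # waveform so amplitudes are not biased low by the smoothing
  half <- max(1L, round(0.05 * fs))
  refine <- function(idx, pick) vapply(idx, function(i) {
    if (is.na(i)) return(NA_integer_)
    win <- max(1L, i - half):min(n, i + half)
    win[pick(xr[win])]
  }, integer(1))
  peaks <- refine(peaks, which.max)
  troughs <- refine(troughs, which.min)
  amps <- xr[peaks] - xr[troughs]
  good <- !is.na(troughs) & amps > 0
  good[1L] <- FALSE
  bad_mask <- vapply(seq_along(peaks), function(j) {
    if (!good[j]) return(TRUE)
    any(record$gap_mask[troughs[j]:peaks[j]])
  }, logical(1))
  good <- good & !bad_mask
  peaks <- peaks[good]; troughs <- troughs[good]; amps <- amps[good]
  if (!length(peaks)) {
    warning("all candidate beats rejected")
    return(empty)
  }
  t <- record_times(record)
  out <- data.frame(peak_time = t[peaks], trough_time = t[troughs],
                    amplitude = amps,
                    pulse_duration = c(diff(t[peaks]), NA_real_))
  class(out) <- c("beat_measures", "data.frame")
  out
}

#' Resample beat amplitudes onto a uniform grid
#'
#' Places each beat's PPGamp at its peak time and linearly interpolates onto
#' a uniform grid. Grid points farther than 5 s from any detected beat
#' (e.g. inside signal-loss gaps) are quality-masked.
#'
#' @param beats A `beat_measures` frame from [detect_beats()] with >= 2 rows.
#' @param grid_dt Grid spacing in seconds (default 0.5, resolving both the
#'   0.15 Hz respiratory cutoff and 15-s baselines comfortably).
#' @param record Optional source [ppg_record()]; when it carries an
#'   accelerometer channel the magnitude is resampled onto the same grid and
#'   attached for the motion quality gate.
#' @return An `amp_series` object (fields `t0`, `dt`, `values`, `mask`,
#'   `stage = "raw"`, optional `accel`).
#' @export
build_amp_series <- function(beats, grid_dt = 0.5, record = NULL) {
  if (is.null(beats) || nrow(beats) < 2L)
    stop_vw("need at least 2 beats to build an amplitude series",
            class = "vasowave_insufficient_data")
  bt <- beats$peak_time
  t0 <- ceiling(bt[1] / grid_dt) * grid_dt
  tn <- floor(bt[length(bt)] / grid_dt) * grid_dt
  grid <- seq(t0, tn, by = grid_dt)
  vals <- stats::approx(bt, beats$amplitude, xout = grid, rule = 2)$y
  # distance from each grid point to the nearest beat
  idx <- findInterval(grid, bt)
  d_prev <- ifelse(idx >= 1L, grid - bt[pmax(idx, 1L)], Inf)
  d_next <- ifelse(idx < length(bt), bt[pmin(idx + 1L, length(bt))] - grid, Inf)
  mask <- pmin(d_prev, d_next) > 5
  accel <- NULL
  if (!is.null(record) && !is.null(record$accel_magnitude)) {
    rt <- record_times(record)
    accel <- stats::approx(rt, record$accel_magnitude, xout = grid, rule = 2)$y
  }
  amp_series(values = vals, t0 = t0, dt = grid_dt, mask = mask,
             stage = "raw", accel = accel)
}
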