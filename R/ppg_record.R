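#' Construct a raw PPG recording
#'
#' A `ppg_record` holds one night of raw waveform samples from one device on a
#' uniform time grid. Sample `i` (1-based) lives at time
#' `start_time + (i - 1) / sample_rate`; missing or invalid stretches are
#' masked in place via `gap_mask` rather than deleted, so downstream segment
#' indexing stays stable.
#'
#' @param samples Numeric vector of raw PPG samples (arbitrary units). Masked
#'   samples may be `NA`.
#' @param sample_rate Sampling rate in Hz (> 0).
#' @param device_id,participant_id,night_id Labels carried through the
#'   pipeline.
#' @param start_time Time of the first sample in seconds (recording-local;
#'   defaults to 0).
#' @param gap_mask Logical vector, same length as `samples`; `TRUE` marks a
#'   missing/invalid sample. Defaults to `is.na(samples)`.
#' @param accel_magnitude Optional numeric vector (same length) of
#'   accelerometer magnitude in g, used by the motion quality gate.
#' @return An object of class `ppg_record`.
#' @export
ppg_record <- function(samples, sample_rate, device_id = "unknown",
                       participant_id = "unknown", night_id = "night1",
                       start_time = 0, gap_mask = NULL,
                       accel_magnitude = NULL) {
  samples <- as.numeric(samples)
  if (length(samples) == 0L)
    stop_vw("a ppg_record needs at least one sample", class = "vasowave_schema_error")
  if (!is.numeric(sample_rate) || length(sample_rate) != 1L || sample_rate <= 0)
    stop_vw("sample_rate must be a single positive number", class = "vasowave_config_error")
  if (is.null(gap_mask)) gap_mask <- is.na(samples)
  gap_mask <- as.logical(gap_mask) | is.na(samples)
  if (length(gap_mask) != length(samples))
    stop_vw("gap_mask and samples must have equal length", class = "vasowave_schema_error")
  if (!is.null(accel_magnitude)) {
    accel_magnitude <- as.numeric(accel_magnitude)
    if (length(accel_magnitude) != length(samples))
      stop_vw("accel_magnitude and samples must have equal length",
              class = "vasowave_schema_error")
  }
  structure(
    list(samples = samples, sample_rate = as.numeric(sample_rate),
         device_id = device_id, participant_id = participant_id,
         night_id = night_id, start_time = as.numeric(start_time),
         gap_mask = gap_mask, accel_magnitude = accel_magnitude),
    class = "ppg_record")
}

#' @export
print.ppg_record <- function(x, ...) {
  dur <- length(x$samples) / x$sample_rate
  cat(sprintf("<ppg_record> %s / %s / %s\n", x$participant_id, x$night_id, x$device_id))
  cat(sprintf("  %d samples @ %g Hz (%.1f min), %.1f%% masked%s\n",
              length(x$samples), x$sample_rate, dur / 60,
              100 * mean(x$gap_mask),
              if (is.null(x$accel_magnitude)) "" else ", accel channel present"))
  invisible(x)
}

#' Sample times of a PPG recording
#'
#' @param record A [ppg_record()].
#' @return Numeric vector of per-sample times in seconds.
#' @export
record_times <- function(record) {
  record$start_time + (seq_along(record$samples) - 1L) / record$sample_rate
}

#' Recording duration in seconds
#' @param record A [ppg_record()].
#' @return Duration spanned by the sample grid, in seconds.
#' @export
record_duration <- function(record) length(record$samples) / record$sample_rate

#' Mask periodic device sync pauses
#'
#' Wristband recorders pause briefly at the end of every hour to sync data to
#' a phone; those stretches carry no signal. The pause is taken to occupy the
#' last `pause_s` seconds of each completed `period_s` interval, i.e. windows
#' `[k*period_s - pause_s, k*period_s)` for `k = 1, 2, ...` that fit inside
#' the recording.
#'
#' @param record A [ppg_record()].
#' @param period_s Pause period in seconds (default 3600, hourly).
#' @param pause_s Pause length in seconds (default 300); must satisfy
#'   `period_s > pause_s > 0`.
#' @return The record with pause windows added to `gap_mask`.
#' @export
mask_hourly_pauses <- function(record, period_s = 3600, pause_s = 300) {
  if (!(period_s > pause_s && pause_s > 0))
    stop_vw("require period_s > pause_s > 0", class = "vasowave_config_error")
  t <- record_times(record) - record$start_time
  dur <- record_duration(record)
  k <- seq_len(max(0L, floor(dur / period_s)))
  for (kk in k) {
    lo <- kk * period_s - pause_s
    hi <- kk * period_s
    record$gap_mask[t >= lo & t < hi] <- TRUE
  }
  record
}
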