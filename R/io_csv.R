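#' Read a wristband CSV export into a PPG record
#'
#' Wearable CSV exports carry one sample per row with (possibly jittery)
#' timestamps. Timestamps are snapped onto a uniform grid at the median
#' sampling interval; grid slots with no row become masked gaps. Jitter of a
#' timestamp beyond 25% of one sample period from its grid slot is treated as
#' a malformed file.
#'
#' @param path CSV file path. Expected dialect: header
#'   `time_s,ppg[,acc_x,acc_y,acc_z]` (names remappable via `column_map`),
#'   UTF-8, one sample per row; empty/`NA` ppg values are masked.
#' @param column_map Named list mapping roles to column names: `time`, `ppg`,
#'   and optionally `accel` (character vector of axis columns, combined into
#'   a magnitude).
#' @param device_id,participant_id,night_id Labels for the record.
#' @return A [ppg_record()].
#' @export
read_csv_record <- function(path,
                            column_map = list(time = "time_s", ppg = "ppg",
                                              accel = c("acc_x", "acc_y", "acc_z")),
                            device_id = "wrist", participant_id = "unknown",
                            night_id = "night1") {
  if (!file.exists(path))
    stop_vw("file not found: %s", path, class = "vasowave_schema_error")
  df <- tryCatch(utils::read.csv(path, check.names = FALSE),
                 error = function(e) stop_vw("cannot parse CSV %s: %s", path,
                                             conditionMessage(e),
                                             class = "vasowave_schema_error"))
  need <- c(column_map$time, column_map$ppg)
  if (nrow(df) == 0L || !all(need %in% names(df)))
    stop_vw("CSV %s lacks required columns (%s) or rows", path,
            paste(need, collapse = ", "), class = "vasowave_schema_error")
  t <- as.numeric(df[[column_map$time]])
  v <- as.numeric(df[[column_map$ppg]])
  if (anyNA(t) || any(diff(t) <= 0))
    stop_vw("time column in %s must be strictly increasing", path,
            class = "vasowave_parse_error")
  if (length(t) < 2L)
    stop_vw("CSV %s has fewer than 2 samples", path, class = "vasowave_schema_error")
  # sample period = modal inter-row interval (ties -> smallest); a plain
  # median is distorted when dropped rows make some diffs multiples of dt
  d <- diff(t)
  tb <- table(signif(d, 2))
  dt0 <- min(as.numeric(names(tb)[tb == max(tb)]))
  dt <- stats::median(d[abs(d - dt0) <= 0.25 * dt0])
  slots <- round((t - t[1]) / dt)
  if (any(abs((t - t[1]) - slots * dt) > 0.25 * dt))
    stop_vw("timestamps in %s jitter by more than 25%% of one sample period", path,
            class = "vasowave_parse_error")
  if (anyDuplicated(slots))
    stop_vw("duplicate timestamps in %s after grid snapping", path,
            class = "vasowave_parse_error")
  n <- max(slots) + 1L
  samples <- rep(NA_real_, n)
  samples[slots + 1L] <- v
  accel <- NULL
  acc_cols <- column_map$accel
  if (!is.null(acc_cols) && all(acc_cols %in% names(df))) {
    mat <- as.matrix(df[acc_cols])
    mag <- sqrt(rowSums(mat^2))
    accel <- rep(NA_real_, n)
    accel[slots + 1L] <- mag
    accel[is.na(accel)] <- 0
  }
  ppg_record(samples, sample_rate = 1 / dt, device_id = device_id,
             participant_id = participant_id, night_id = night_id,
             start_time = t[1], gap_mask = is.na(samples),
             accel_magnitude = accel)
}

#' Write a simulated or ingested record to a fixture file
#'
#' Serializes a [ppg_record()] as either the wristband CSV dialect
#' (`time_s,ppg[,acc_x,acc_y,acc_z]`; masked samples written as empty
#' fields) or a single-channel EDF file. Files round-trip through
#' [read_csv_record()] / [read_edf_record()] to an equal record (times
#' within one sample; values exact for CSV, within 16-bit quantization of
#' the physical range for EDF).
#'
#' @param record A [ppg_record()] with at least 2 samples.
#' @param path Output file path.
#' @param format `"csv"` or `"edf"`.
#' @return `path`, invisibly.
#' @export
write_fixture <- function(record, path, format = c("csv", "edf")) {
  format <- match.arg(format)
  if (!inherits(record, "ppg_record") || length(record$samples) < 2L)
    stop_vw("write_fixture needs a ppg_record with >= 2 samples",
            class = "vasowave_schema_error")
  if (format == "csv") {
    t <- record_times(record)
    v <- record$samples
    v[record$gap_mask] <- NA_real_
    df <- data.frame(time_s = t, ppg = v)
    if (!is.null(record$accel_magnitude)) {
      df$acc_x <- record$accel_magnitude
      df$acc_y <- 0
      df$acc_z <- 0
    }
    utils::write.csv(df, path, row.names = FALSE, quote = FALSE, na = "")
  } else {
    write_edf(record, path)
  }
  invisible(path)
}
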