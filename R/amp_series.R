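#' Uniformly sampled PPGamp series
#'
#' The beat-amplitude (PPGamp) time series on a uniform grid is the object
#' all downstream analysis consumes. `stage` records provenance and may only
#' advance in the documented order `raw -> capped -> normalized ->
#' detrended_filtered`; after detrending the series is zero-mean, and the
#' pre-detrend mean is kept in `level` so relative-drop event detection and
#' CV can re-offset it.
#'
#' @param values Numeric PPGamp values (finite wherever unmasked).
#' @param t0 Time of the first grid point, seconds.
#' @param dt Grid spacing, seconds (> 0).
#' @param mask Logical quality mask (`TRUE` = unusable point).
#' @param stage Provenance tag.
#' @param accel Optional accelerometer magnitude resampled onto the grid.
#' @param level Pre-detrend mean level (set by [detrend_and_filter()]).
#' @return An `amp_series` object.
#' @export
amp_series <- function(values, t0 = 0, dt = 0.5, mask = NULL,
                       stage = c("raw", "capped", "normalized",
                                 "detrended_filtered"),
                       accel = NULL, level = NULL) {
  stage <- match.arg(stage)
  values <- as.numeric(values)
  if (dt <= 0) stop_vw("grid_dt must be positive", class = "vasowave_config_error")
  if (is.null(mask)) mask <- is.na(values)
  mask <- as.logical(mask) | is.na(values)
  if (length(mask) != length(values))
    stop_vw("mask and values must have equal length", class = "vasowave_schema_error")
  if (any(!is.finite(values[!mask])))
    stop_vw("unmasked amp_series values must be finite", class = "vasowave_schema_error")
  structure(list(values = values, t0 = as.numeric(t0), dt = as.numeric(dt),
                 mask = mask, stage = stage, accel = accel, level = level),
            class = "amp_series")
}

#' @export
print.amp_series <- function(x, ...) {
  cat(sprintf("<amp_series> %d points @ %g s [%s], %.1f%% masked\n",
              length(x$values), x$dt, x$stage, 100 * mean(x$mask)))
  invisible(x)
}

#' Grid times of an amp series
#' @param series An [amp_series()].
#' @return Numeric vector of grid-point times in seconds.
#' @export
amp_times <- function(series) {
  series$t0 + (seq_along(series$values) - 1L) * series$dt
}

#' Slice an amp series to a half-open time interval
#' @param series An [amp_series()].
#' @param start,end Interval `[start, end)` in seconds.
#' @return The sliced `amp_series` (possibly zero-length).
#' @export
amp_slice <- function(series, start, end) {
  t <- amp_times(series)
  keep <- t >= start & t < end
  s <- series
  s$values <- series$values[keep]
  s$mask <- series$mask[keep]
  s$t0 <- if (any(keep)) t[keep][1] else start
  if (!is.null(series$accel)) s$accel <- series$accel[keep]
  s
}

# Advance the provenance tag, enforcing the documented order.
amp_advance_stage <- function(series, to) {
  order <- c(raw = 1L, capped = 2L, normalized = 3L, detrended_filtered = 4L)
  if (order[[to]] != order[[series$stage]] + 1L)
    stop_vw("stage may only advance %s -> %s in order (got %s -> %s)",
            names(order)[order[[series$stage]] + 1L], to, series$stage, to,
            class = "vasowave_stage_error")
  series$stage <- to
  series
}

# Values with the pre-detrend level restored (identity before detrending).
# Relative-drop detection and CV are meaningless around a zero-mean signal.
amp_values_leveled <- function(series) {
  v <- series$values
  if (identical(series$stage, "detrended_filtered") && !is.null(series$level))
    v <- v + series$level
  v[series$mask] <- NA_real_
  v
}
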