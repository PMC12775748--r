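# Preprocessing of the raw PPGamp series into the "clean" signal used by the
# vasoconstriction markers: 15-minute segmentation, automated signal-loss and
# motion gating, 98th-percentile outlier capping, 95th-percentile
# normalization, linear detrending and removal of respiratory influence
# (> 0.15 Hz) with a zero-phase low-pass. Fixed order:
# gate -> cap -> normalize -> detrend_and_filter.

new_segment <- function(index, start, end, series, viable = TRUE,
                        notes = character(0)) {
  structure(list(index = index, start = start, end = end, series = series,
                 viable = viable, notes = notes),
            class = "ppg_segment")
}

#' @export
print.ppg_segment <- function(x, ...) {
  cat(sprintf("<ppg_segment> #%d [%g, %g) s, %s%s\n", x$index, x$start, x$end,
              if (x$viable) "viable" else "non-viable",
              if (length(x$notes)) paste0(" (", paste(x$notes, collapse = ","), ")") else ""))
  invisible(x)
}

#' Divide a night's PPGamp series into consecutive 15-minute segments
#'
#' Emits `floor(duration / seg_len_s)` full segments tiling the night from
#' the first grid point; a trailing remainder shorter than `seg_len_s` is
#' kept for bookkeeping but flagged `short` and non-viable, so it is excluded
#' from all downstream statistics.
#'
#' @param series An [amp_series()].
#' @param seg_len_s Segment length in seconds (default 900).
#' @return List of `ppg_segment` objects (empty for an empty series).
#' @export
segment_night <- function(series, seg_len_s = 900) {
  stopifnot(inherits(series, "amp_series"))
  n <- length(series$values)
  if (n == 0L) return(list())
  total <- n * series$dt
  n_full <- floor(total / seg_len_s)
  segs <- vector("list", n_full)
  for (i in seq_len(n_full)) {
    s <- series$t0 + (i - 1) * seg_len_s
    segs[[i]] <- new_segment(i, s, s + seg_len_s,
                             amp_slice(series, s, s + seg_len_s))
  }
  rem_start <- series$t0 + n_full * seg_len_s
  if (rem_start < series$t0 + total - series$dt / 2) {
    segs[[n_full + 1L]] <- new_segment(n_full + 1L, rem_start, series$t0 + total,
                                       amp_slice(series, rem_start, series$t0 + total),
                                       viable = FALSE, notes = "short")
  }
  segs
}

#' Gate a segment on signal loss and motion
#'
#' Automated replacement for visual signal-loss screening: a segment is
#' marked non-viable when more than `max_masked_frac` of its points are
#' masked (`signal_loss`) or when more than `max_masked_frac` of its points
#' show accelerometer magnitude above `accel_thresh` (`motion`). In a
#' surviving segment, masked runs of at most 5 s are linearly interpolated
#' across; longer runs stay masked.
#'
#' @param segment A `ppg_segment`.
#' @param max_masked_frac Maximum tolerated masked/motion fraction
#'   (default 0.2).
#' @param accel_thresh Accelerometer magnitude threshold in g (default 0.1).
#' @return The gated segment.
#' @export
gate_signal_loss <- function(segment, max_masked_frac = 0.2, accel_thresh = 0.1) {
  s <- segment$series
  n <- length(s$values)
  if (n == 0L) { segment$viable <- FALSE; return(segment) }
  motion_pts <- if (!is.null(s$accel)) s$accel > accel_thresh else rep(FALSE, n)
  if (mean(s$mask) > max_masked_frac) {
    segment$viable <- FALSE
    segment$notes <- union(segment$notes, "signal_loss")
  }
  if (mean(motion_pts) > max_masked_frac) {
    segment$viable <- FALSE
    segment$notes <- union(segment$notes, "motion")
  }
  # motion-flagged points are unusable even in a viable segment
  s$mask <- s$mask | motion_pts
  if (segment$viable && any(s$mask) && !all(s$mask)) {
    max_run <- round(5 / s$dt)
    runs <- bool_runs(s$mask)
    ok <- which(!s$mask)
    for (r in seq_len(nrow(runs))) {
      len <- runs[r, "end"] - runs[r, "start"] + 1L
      if (len > max_run) next
      if (runs[r, "start"] == 1L || runs[r, "end"] == n) next  # no anchor
      idx <- runs[r, "start"]:runs[r, "end"]
      s$values[idx] <- stats::approx(ok, s$values[ok], xout = idx)$y
      s$mask[idx] <- FALSE
    }
  }
  segment$series <- s
  segment
}

#' Cap outliers at the segment's 98th percentile
#'
#' Replaces values exceeding the segment's 98th percentile (computed over
#' pre-capping unmasked values, linear-interpolation quantile) with that
#' percentile. Applied per segment, never per night.
#'
#' @param segment A viable `ppg_segment` (stage `raw`).
#' @param pctl Capping percentile (default 98).
#' @return The capped segment (stage `capped`).
#' @export
cap_outliers <- function(segment, pctl = 98) {
  s <- segment$series
  un <- !s$mask
  if (any(un)) {
    q <- stats::quantile(s$values[un], pctl / 100, names = FALSE, type = 7)
    s$values[un & s$values > q] <- q
  }
  segment$series <- amp_advance_stage(s, "capped")
  segment
}

#' Normalize a segment to its 95th percentile
#'
#' Divides by the segment's 95th percentile over unmasked values so the
#' resulting P95 is exactly 1 and the series is dimensionless; any positive
#' rescaling of the raw amplitudes cancels here. A degenerate segment
#' (non-positive percentile, e.g. flatline zeros) is marked non-viable.
#'
#' @param segment A `ppg_segment` at stage `capped`.
#' @param pctl Normalization percentile (default 95).
#' @return The normalized segment (stage `normalized`).
#' @export
normalize_segment <- function(segment, pctl = 95) {
  s <- segment$series
  already <- identical(s$stage, "normalized")  # idempotent: P95 is then 1
  un <- !s$mask
  q <- if (any(un)) stats::quantile(s$values[un], pctl / 100, names = FALSE, type = 7) else 0
  if (!is.finite(q) || q <= 0) {
    segment$viable <- FALSE
    segment$notes <- union(segment$notes, "degenerate")
    segment$series <- if (already) s else amp_advance_stage(s, "normalized")
    return(segment)
  }
  s$values <- s$values / q
  segment$series <- if (already) s else amp_advance_stage(s, "normalized")
  segment
}

#' Detrend and remove respiratory influence
#'
#' Removes the least-squares line fitted over unmasked points, then applies
#' a zero-phase (forward-backward) 4th-order Butterworth low-pass at
#' `cutoff_hz`, suppressing respiratory modulation (> 0.15 Hz) without
#' shifting event timing. The pre-detrend mean is stored as the series
#' `level`; the returned values are zero-mean residuals. Masked points are
#' interpolated for filtering and re-masked afterwards. A segment too short
#' for the filter's edge padding is marked non-viable.
#'
#' @param segment A viable `ppg_segment` at stage `normalized`.
#' @param cutoff_hz Low-pass cutoff in Hz (default 0.15); must be below the
#'   grid Nyquist frequency.
#' @return The filtered segment (stage `detrended_filtered`).
#' @export
detrend_and_filter <- function(segment, cutoff_hz = 0.15) {
  s <- segment$series
  if (!identical(s$stage, "normalized"))
    stop_vw("detrend_and_filter expects a normalized segment (got stage '%s')",
            s$stage, class = "vasowave_stage_error")
  if (cutoff_hz >= 1 / (2 * s$dt))
    stop_vw("cutoff %g Hz is not below the grid Nyquist %g Hz", cutoff_hz,
            1 / (2 * s$dt), class = "vasowave_config_error")
  n <- length(s$values)
  un <- !s$mask
  if (n < 2L || sum(un) < 10L) {
    segment$viable <- FALSE
    segment$notes <- union(segment$notes, "short")
    segment$series <- amp_advance_stage(s, "detrended_filtered")
    return(segment)
  }
  t <- amp_times(s)
  lev <- mean(s$values[un])
  fit <- stats::lm.fit(cbind(1, t[un]), s$values[un])
  line <- fit$coefficients[1] + fit$coefficients[2] * t
  v <- s$values - line
  v[!un] <- stats::approx(t[un], v[un], xout = t[!un], rule = 2)$y
  coefs <- butter_lowpass(4L, cutoff_hz, fs = 1 / s$dt)
  filt <- tryCatch(filtfilt_zero_phase(coefs$b, coefs$a, v),
                   vasowave_insufficient_data = function(e) NULL)
  if (is.null(filt)) {
    segment$viable <- FALSE
    segment$notes <- union(segment$notes, "short")
    segment$series <- amp_advance_stage(s, "detrended_filtered")
    return(segment)
  }
  s$values <- filt
  s$level <- lev
  segment$series <- amp_advance_stage(s, "detrended_filtered")
  segment
}

#' Run the full per-segment preprocessing chain
#'
#' Applies [gate_signal_loss()], [cap_outliers()], [normalize_segment()] and
#' [detrend_and_filter()] in their fixed order, skipping the numeric stages
#' for segments the gate rejects.
#'
#' @param segment A `ppg_segment` at stage `raw`.
#' @param max_masked_frac,accel_thresh,cap_pctl,norm_pctl,cutoff_hz Stage
#'   parameters; see the individual stage functions.
#' @return The cleaned segment (stage `detrended_filtered` when viable).
#' @export
clean_segment <- function(segment, max_masked_frac = 0.2, accel_thresh = 0.1,
                          cap_pctl = 98, norm_pctl = 95, cutoff_hz = 0.15) {
  segment <- gate_signal_loss(segment, max_masked_frac, accel_thresh)
  if (!segment$viable) return(segment)
  segment <- cap_outliers(segment, cap_pctl)
  segment <- normalize_segment(segment, norm_pctl)
  if (!segment$viable) return(segment)
  detrend_and_filter(segment, cutoff_hz)
}
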