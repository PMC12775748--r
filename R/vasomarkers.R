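# Vasoconstriction markers computed from the clean PPGamp:
# * Mvasoc — per detected event, (area of the drop below the preceding 15-s
#   baseline / event duration) / baseline level; nightly median as the index;
# * PPGampCV — SD/mean of PPGamp in a 5-minute sliding window every 30 s,
#   a rule-free surrogate for Mvasoc.

#' Mvasoc of a single vasoconstriction event
#'
#' The magnitude of vasoconstriction is the drop area below baseline divided
#' by the event duration, normalized by the baseline PPGamp level:
#' `(drop_area / duration) / baseline`. It is dimensionless and invariant to
#' rescaling the PPGamp (baseline and drop area scale together).
#'
#' @param drop_area Integral of `max(0, baseline - PPGamp)` over the event
#'   (dimensionless x seconds); must be non-negative.
#' @param duration Event duration in seconds (> 0).
#' @param baseline Baseline PPGamp level (> 0).
#' @return The Mvasoc value (>= 0).
#' @export
mvasoc_of_event <- function(drop_area, duration, baseline) {
  if (!all(duration > 0) || !all(baseline > 0))
    stop_vw("duration and baseline must be positive", class = "vasowave_domain_error")
  if (any(drop_area < 0))
    stop_vw("drop_area must be non-negative", class = "vasowave_domain_error")
  (drop_area / duration) / baseline
}

#' Detect vasoconstriction events in a clean segment
#'
#' A vasoconstriction event is a significant reduction of PPGamp below the
#' mean of the preceding `baseline_s` seconds. Detection triggers when the
#' signal falls below `baseline * (1 - depth_thresh)`; the onset is then
#' walked back to the last crossing of the baseline (so the whole excursion
#' is captured) and the offset is the first return to the baseline. Events
#' shorter than `min_dur_s` are discarded. Each event carries its baseline,
#' trapezoidal drop area and Mvasoc. Works on the detrended/filtered signal
#' with the pre-detrend level restored (relative drops are undefined around
#' a zero-mean signal); a `normalized` segment is accepted as-is.
#'
#' @param segment A viable `ppg_segment` (stage `normalized` or
#'   `detrended_filtered`).
#' @param baseline_s Baseline window length in seconds (default 15). Events
#'   starting earlier than `baseline_s` into the segment use the available
#'   prefix and are flagged `short_baseline`.
#' @param depth_thresh Fractional drop that triggers detection
#'   (default 0.15). The pivotal free parameter of the rule.
#' @param min_dur_s Minimum event duration in seconds (default 3).
#' @return A data frame of class `vaso_events` with columns `start`, `end`,
#'   `duration`, `baseline`, `drop_area`, `mvasoc`, `flag`; zero rows when
#'   the segment is too short or quiet.
#' @export
detect_vaso_events <- function(segment, baseline_s = 15, depth_thresh = 0.15,
                               min_dur_s = 3) {
  empty <- data.frame(start = numeric(0), end = numeric(0), duration = numeric(0),
                      baseline = numeric(0), drop_area = numeric(0),
                      mvasoc = numeric(0), flag = character(0))
  class(empty) <- c("vaso_events", "data.frame")
  if (!segment$viable) return(empty)
  s <- segment$series
  if (!s$stage %in% c("normalized", "detrended_filtered"))
    stop_vw("event detection expects a normalized or detrended_filtered segment",
            class = "vasowave_stage_error")
  v <- amp_values_leveled(s)
  dt <- s$dt
  n <- length(v)
  if (n * dt < baseline_s + min_dur_s) return(empty)
  t <- amp_times(s)
  w <- max(1L, round(baseline_s / dt))

  # rolling mean of the preceding w points (exclusive), NA-aware
  vv <- ifelse(is.na(v), 0, v)
  cnt <- as.numeric(!is.na(v))
  cs <- cumsum(vv); cc <- cumsum(cnt)
  roll_base <- function(i) {
    lo <- max(1L, i - w)
    m <- cc[i - 1L] - if (lo > 1L) cc[lo - 1L] else 0
    if (m < 1) return(NA_real_)
    (cs[i - 1L] - if (lo > 1L) cs[lo - 1L] else 0) / m
  }

  out <- empty
  i <- 2L
  while (i <= n) {
    if (is.na(v[i])) { i <- i + 1L; next }
    b <- roll_base(i)
    if (!is.na(b) && b > 0 && v[i] < b * (1 - depth_thresh)) {
      # walk onset back to the last baseline crossing
      on <- i
      while (on > 1L && !is.na(v[on - 1L]) && v[on - 1L] < b) on <- on - 1L
      b_ev <- roll_base(on)
      if (is.na(b_ev) || b_ev <= 0) b_ev <- b
      # refine once: the trigger-time baseline is depressed by the fall
      # itself, so re-walk the onset against the event baseline
      while (on > 1L && !is.na(v[on - 1L]) && v[on - 1L] < b_ev) on <- on - 1L
      b_ref <- roll_base(on)
      if (!is.na(b_ref) && b_ref > 0) b_ev <- b_ref
      flag <- if ((on - 1L) < w) "short_baseline" else ""
      off <- i
      while (off < n && !is.na(v[off + 1L]) && v[off + 1L] < b_ev) off <- off + 1L
      truncated <- off == n || is.na(v[min(off + 1L, n)])
      # offset index: first return to baseline (or truncation point)
      end_idx <- min(off + 1L, n)
      idx <- on:end_idx
      dur <- t[end_idx] - t[on]
      if (dur >= min_dur_s) {
        drop <- pmax(0, b_ev - v[idx])
        drop[is.na(drop)] <- 0
        area <- trapz(t[idx], drop)
        if (truncated) flag <- paste0(flag, if (nzchar(flag)) "," else "", "truncated")
        out <- rbind(out, data.frame(start = t[on], end = t[end_idx],
                                     duration = dur, baseline = b_ev,
                                     drop_area = area,
                                     mvasoc = mvasoc_of_event(area, dur, b_ev),
                                     flag = flag))
      }
      i <- end_idx + 1L
    } else {
      i <- i + 1L
    }
  }
  class(out) <- c("vaso_events", "data.frame")
  out
}

#' Sliding-window coefficient of variation of PPGamp (PPGampCV)
#'
#' Computes SD/mean of the PPGamp inside a sliding window of `window_s`
#' seconds, stepped every `step_s` seconds (window centers). SD is the
#' sample standard deviation over unmasked in-window points. A point is
#' invalid when more than 25% of its window is masked or the window mean is
#' non-positive. CV is invariant to positive rescaling of the series.
#'
#' @param series An [amp_series()] (or a `ppg_segment`, whose series is
#'   used); duration must be at least `window_s`. For a
#'   `detrended_filtered` series the pre-detrend level is restored first.
#' @param window_s Window length in seconds (default 300).
#' @param step_s Step between window centers in seconds (default 30).
#' @param max_masked_frac Maximum masked fraction per window (default 0.25).
#' @return A `cv_series` object: `centers`, `values`, `valid`, `window_s`,
#'   `step_s`.
#' @export
ppgamp_cv <- function(series, window_s = 300, step_s = 30,
                      max_masked_frac = 0.25) {
  if (inherits(series, "ppg_segment")) series <- series$series
  stopifnot(inherits(series, "amp_series"))
  n <- length(series$values)
  dur <- n * series$dt
  if (dur < window_s)
    stop_vw("series duration %g s is shorter than the %g s window", dur,
            window_s, class = "vasowave_insufficient_data")
  v <- amp_values_leveled(series)
  t <- amp_times(series)
  # centers where the full window fits inside the series support [t0, t0+dur)
  centers <- seq(series$t0 + window_s / 2,
                 series$t0 + dur - window_s / 2 + 1e-9, by = step_s)
  vals <- rep(NA_real_, length(centers))
  valid <- rep(FALSE, length(centers))
  half <- window_s / 2
  for (j in seq_along(centers)) {
    idx <- which(t >= centers[j] - half & t < centers[j] + half)
    w <- v[idx]
    if (!length(idx) || mean(is.na(w)) > max_masked_frac) next
    w <- w[!is.na(w)]
    if (length(w) < 2L) next
    m <- mean(w)
    if (m <= 0) next
    vals[j] <- stats::sd(w) / m
    valid[j] <- TRUE
  }
  structure(list(centers = centers, values = vals, valid = valid,
                 window_s = window_s, step_s = step_s),
            class = "cv_series")
}

#' @export
print.cv_series <- function(x, ...) {
  cat(sprintf("<cv_series> %d points every %g s (%g s window), %d valid\n",
              length(x$centers), x$step_s, x$window_s, sum(x$valid)))
  invisible(x)
}

# Concatenate per-segment cv_series into one night-level series.
bind_cv_series <- function(cv_list) {
  cv_list <- Filter(Negate(is.null), cv_list)
  if (!length(cv_list)) return(NULL)
  structure(list(centers = unlist(lapply(cv_list, `[[`, "centers")),
                 values = unlist(lapply(cv_list, `[[`, "values")),
                 valid = unlist(lapply(cv_list, `[[`, "valid")),
                 window_s = cv_list[[1]]$window_s,
                 step_s = cv_list[[1]]$step_s),
            class = "cv_series")
}

#' Summarize one night of vasoconstriction markers
#'
#' Pools events across viable segments and reports the nightly median Mvasoc
#' (the quantitative index of nocturnal vasoconstriction behaviour), the
#' median of valid PPGampCV points, and bookkeeping counts. With zero events
#' the median Mvasoc is undefined and reported as `NA`; the night is
#' retained.
#'
#' @param events_per_segment List of `vaso_events` frames, one per viable
#'   segment.
#' @param cv A `cv_series` for the night (may be `NULL`).
#' @param night_id,device_id Labels.
#' @param n_viable_segments Count of viable segments (defaults to the number
#'   of event frames supplied).
#' @return A one-row data frame of class `night_summary`: `night_id`,
#'   `device_id`, `n_events`, `median_mvasoc`, `median_cv`,
#'   `n_viable_segments`.
#' @export
summarize_night <- function(events_per_segment, cv, night_id = "night1",
                            device_id = "unknown",
                            n_viable_segments = length(events_per_segment)) {
  if (length(events_per_segment) < 1L)
    stop_vw("need at least one viable segment to summarize a night",
            class = "vasowave_insufficient_data")
  mv <- unlist(lapply(events_per_segment, function(e) e$mvasoc))
  cvv <- if (!is.null(cv)) cv$values[cv$valid] else numeric(0)
  out <- data.frame(night_id = night_id, device_id = device_id,
                    n_events = length(mv),
                    median_mvasoc = if (length(mv)) stats::median(mv) else NA_real_,
                    median_cv = if (length(cvv)) stats::median(cvv) else NA_real_,
                    n_viable_segments = n_viable_segments)
  class(out) <- c("night_summary", "data.frame")
  out
}
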