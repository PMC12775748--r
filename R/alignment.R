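# Cross-device alignment. The finger and wrist recorders run on independent
# clocks; corresponding clean PPGamp segments are synchronized by locating
# the maximum positive normalized cross-correlation within a +/-30-second
# lag window, after an autocorrelation check that each series carries
# physiological structure rather than white noise.

#' Autocorrelation check against white noise
#'
#' Passes when any autocorrelation at lags in `(0, max_lag_s]` exceeds the
#' white-noise 95% band in absolute value. Because `K` lags are examined
#' jointly, the per-lag bound is Bonferroni-adjusted,
#' `qnorm(1 - 0.025 / K) / sqrt(N)`, keeping the family-wise false-pass
#' rate on white noise near 5% (an unadjusted 1.96 band would let almost
#' every white-noise series through when K is large). A constant
#' (degenerate) series fails with reason `"degenerate"`.
#'
#' @param series An [amp_series()] with at least `2 * max_lag_s` of valid
#'   data.
#' @param max_lag_s Largest lag examined, seconds (default 30).
#' @return List: `statistic` (max |acf| over the examined lags), `passed`,
#'   `reason` (`"ok"`, `"white_noise"` or `"degenerate"`).
#' @export
autocorr_check <- function(series, max_lag_s = 30) {
  stopifnot(inherits(series, "amp_series"))
  v <- series$values
  v[series$mask] <- NA_real_
  n_valid <- sum(!is.na(v))
  if (n_valid * series$dt < 2 * max_lag_s)
    stop_vw("need at least %g s of valid data for the autocorrelation check",
            2 * max_lag_s, class = "vasowave_insufficient_data")
  if (stats::sd(v, na.rm = TRUE) == 0)
    return(list(statistic = NA_real_, passed = FALSE, reason = "degenerate"))
  max_lag <- max(1L, round(max_lag_s / series$dt))
  ac <- stats::acf(v, lag.max = max_lag, plot = FALSE, na.action = stats::na.pass,
                   demean = TRUE)$acf[-1]
  stat <- max(abs(ac), na.rm = TRUE)
  band <- stats::qnorm(1 - 0.025 / max_lag) / sqrt(n_valid)
  list(statistic = stat, passed = stat > band,
       reason = if (stat > band) "ok" else "white_noise")
}

#' Align a wrist segment to a finger segment by cross-correlation
#'
#' Evaluates the normalized (Pearson, per-lag mean-removed) cross-correlation
#' at every grid lag in `[-max_lag_s, +max_lag_s]` and takes the lag of the
#' maximum positive value; ties are broken toward the smallest `|lag|`.
#' `lag_s` is the wrist shift relative to the finger (negative = wrist
#' leads); the returned wrist series is shifted by `-lag_s` and re-windowed
#' to the overlapping support. A lag exactly at the window edge sets
#' `boundary_flag` (the true lag may lie outside the window) with a warning,
#' but the pair is retained. If no lag yields a positive correlation the
#' alignment fails and the pair should be excluded downstream.
#'
#' Both inputs must share the same grid spacing (the common `grid_dt` of the
#' amplitude extraction); lags are quantized to that grid.
#'
#' @param finger_seg,wrist_seg Viable `ppg_segment`s (clean PPGamp) that
#'   pass [autocorr_check()].
#' @param max_lag_s Half-width of the lag search window, seconds
#'   (default 30).
#' @param min_overlap Minimum complete pairs per lag (default 10).
#' @return List of class `alignment_result`: `lag_s`, `peak_xcorr`,
#'   `passed_autocheck` (length 2), `boundary_flag`, `success`, and
#'   `wrist_aligned` (the shifted wrist [amp_series()], `NULL` on failure).
#' @export
align_pair <- function(finger_seg, wrist_seg, max_lag_s = 30, min_overlap = 10L) {
  f <- if (inherits(finger_seg, "ppg_segment")) finger_seg$series else finger_seg
  w <- if (inherits(wrist_seg, "ppg_segment")) wrist_seg$series else wrist_seg
  if (abs(f$dt - w$dt) > 1e-9)
    stop_vw("finger and wrist series must share one grid spacing",
            class = "vasowave_config_error")
  ac_f <- autocorr_check(f, max_lag_s)
  ac_w <- autocorr_check(w, max_lag_s)
  dt <- f$dt
  K <- round(max_lag_s / dt)
  vf <- f$values; vf[f$mask] <- NA_real_
  vw <- w$values; vw[w$mask] <- NA_real_
  # place both on a common index frame via their start times
  off <- round((w$t0 - f$t0) / dt)
  nf <- length(vf); nw <- length(vw)
  lags <- -K:K
  r <- rep(NA_real_, length(lags))
  for (li in seq_along(lags)) {
    # pairing vf[i] with vw[i + k] compares times t and t + lag when
    # k = lag/dt - off (off = grid offset between the two start times)
    k <- lags[li] - off
    # pair vf[i] with vw[i + k] (wrist sample k grid steps later)
    i_lo <- max(1L, 1L - k)
    i_hi <- min(nf, nw - k)
    if (i_hi - i_lo + 1L < min_overlap) next
    a <- vf[i_lo:i_hi]
    b <- vw[(i_lo + k):(i_hi + k)]
    okp <- !is.na(a) & !is.na(b)
    if (sum(okp) < min_overlap) next
    if (stats::sd(a[okp]) == 0 || stats::sd(b[okp]) == 0) next
    r[li] <- stats::cor(a[okp], b[okp])
  }
  res <- list(lag_s = NA_real_, peak_xcorr = NA_real_,
              passed_autocheck = c(finger = ac_f$passed, wrist = ac_w$passed),
              boundary_flag = FALSE, success = FALSE, wrist_aligned = NULL)
  class(res) <- "alignment_result"
  pos <- which(!is.na(r) & r > 0)
  if (!length(pos)) return(res)
  best_r <- max(r[pos])
  cand <- pos[r[pos] >= best_r - 1e-12]
  best <- cand[which.min(abs(lags[cand]))]
  lag_s <- lags[best] * dt
  if (abs(lags[best]) == K) {
    warning("alignment lag sits at the search-window edge; true lag may lie outside")
    res$boundary_flag <- TRUE
  }
  res$lag_s <- lag_s
  res$peak_xcorr <- r[best]
  res$success <- TRUE
  # shift wrist onto the finger time base: aligned value at finger time t is
  # the wrist value at t + lag
  k <- lags[best] - off
  i_lo <- max(1L, 1L - k); i_hi <- min(nf, nw - k)
  shifted <- rep(NA_real_, nf)
  shifted[i_lo:i_hi] <- vw[(i_lo + k):(i_hi + k)]
  res$wrist_aligned <- amp_series(shifted, t0 = f$t0, dt = dt,
                                  mask = is.na(shifted), stage = w$stage,
                                  level = w$level)
  res
}

#' @export
print.alignment_result <- function(x, ...) {
  if (x$success)
    cat(sprintf("<alignment_result> lag %g s, peak r %.3f%s\n", x$lag_s,
                x$peak_xcorr, if (x$boundary_flag) " (boundary)" else ""))
  else cat("<alignment_result> FAILED (no positive cross-correlation)\n")
  invisible(x)
}
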