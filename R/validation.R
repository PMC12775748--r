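# Validation analyses: within-device Mvasoc-vs-PPGampCV correlations
# (overnight and peak r_wd), across-device PPGampCV correlations with the
# >=3-event segment inclusion rule (overnight and peak r_ad), and the
# nightly-medians regression.

#' Pearson correlation with a two-sided p-value
#'
#' Product-moment correlation with the usual t-transform:
#' `t = r * sqrt((n - 2) / (1 - r^2))` on `n - 2` degrees of freedom,
#' two-sided. A correlation of 0.05 or smaller p-value is treated as
#' statistically significant throughout the reports.
#'
#' @param x,y Numeric vectors, equal length `n >= 3`, both non-constant.
#' @return List with `r`, `p`, `n`.
#' @export
pearson_with_p <- function(x, y) {
  ok <- is.finite(x) & is.finite(y)
  x <- x[ok]; y <- y[ok]
  n <- length(x)
  if (n < 3L)
    stop_vw("need at least 3 complete pairs (got %d)", n,
            class = "vasowave_insufficient_data")
  if (stats::sd(x) == 0 || stats::sd(y) == 0)
    stop_vw("correlation undefined for a constant input",
            class = "vasowave_domain_error")
  r <- stats::cor(x, y)
  if (abs(r) >= 1) {
    p <- 0
  } else {
    tt <- r * sqrt((n - 2) / (1 - r^2))
    p <- 2 * stats::pt(-abs(tt), df = n - 2)
  }
  list(r = r, p = p, n = n)
}

#' Spearman variant used when `cor_method = "spearman"`
#' @noRd
rank_cor_with_p <- function(x, y, method = "pearson") {
  if (method == "spearman") {
    ok <- is.finite(x) & is.finite(y)
    return(pearson_with_p(rank(x[ok]), rank(y[ok])))
  }
  pearson_with_p(x, y)
}

#' Pair event Mvasoc values with the PPGampCV grid
#'
#' Builds the Mvasoc channel as a step series on the CV 30-s grid: each grid
#' point falling inside a detected event takes that event's Mvasoc; in
#' `zero_fill` mode (default) points outside any event are zero (no
#' vasoconstriction), while `event_only` mode restricts the pairing to grid
#' points inside events. Only grid points valid in both channels are kept.
#'
#' @param events A `vaso_events` frame.
#' @param cv A `cv_series`.
#' @param mode `"zero_fill"` or `"event_only"`.
#' @return Data frame with columns `center`, `mvasoc`, `cv` (possibly zero
#'   rows).
#' @export
pair_mvasoc_with_cv <- function(events, cv, mode = c("zero_fill", "event_only")) {
  mode <- match.arg(mode)
  centers <- cv$centers
  mv <- rep(if (mode == "zero_fill") 0 else NA_real_, length(centers))
  if (!is.null(events) && nrow(events) > 0L) {
    for (i in seq_len(nrow(events))) {
      inside <- centers >= events$start[i] & centers < events$end[i]
      mv[inside] <- events$mvasoc[i]
    }
  }
  keep <- cv$valid & !is.na(mv)
  data.frame(center = centers[keep], mvasoc = mv[keep], cv = cv$values[keep])
}

new_corr_report <- function(mode, per_segment, min_pairs) {
  inc <- per_segment$included
  pooled_x <- unlist(per_segment$x[inc])
  pooled_y <- unlist(per_segment$y[inc])
  overnight_r <- NA_real_; overnight_p <- NA_real_
  if (length(pooled_x) >= 3L && stats::sd(pooled_x) > 0 && stats::sd(pooled_y) > 0) {
    ov <- pearson_with_p(pooled_x, pooled_y)
    overnight_r <- ov$r; overnight_p <- ov$p
  }
  peak_r <- NA_real_; peak_segment <- NA_integer_
  cand <- which(inc & !is.na(per_segment$r))
  if (length(cand)) {
    peak_segment <- cand[which.max(per_segment$r[cand])]
    peak_r <- per_segment$r[peak_segment]
    peak_segment <- per_segment$segment[peak_segment]
  }
  per <- data.frame(segment = per_segment$segment, r = per_segment$r,
                    p = per_segment$p, n_pairs = per_segment$n_pairs,
                    included = per_segment$included,
                    exclusion_reason = per_segment$exclusion_reason)
  structure(list(mode = mode, overnight_r = overnight_r,
                 overnight_p = overnight_p, peak_r = peak_r,
                 peak_segment = peak_segment, per_segment = per,
                 n_included = sum(inc), min_pairs = min_pairs),
            class = "corr_report")
}

#' @export
print.corr_report <- function(x, ...) {
  cat(sprintf("<corr_report:%s> overnight r = %.3f (p = %.3g), peak r = %.3f (segment %s), %d/%d segments included\n",
              x$mode, x$overnight_r, x$overnight_p, x$peak_r,
              x$peak_segment, x$n_included, nrow(x$per_segment)))
  invisible(x)
}

#' Within-device correlation of Mvasoc and PPGampCV
#'
#' For each viable segment, pairs the segment's Mvasoc channel with its
#' PPGampCV values ([pair_mvasoc_with_cv()]) and computes a per-segment
#' correlation; the overnight r pools the pairs of all included segments
#' (the whole-night correlation), and the peak r is the maximum per-segment
#' r among included segments. Segments below `min_pairs` pairs are excluded
#' (`too_few_pairs`), non-viable segments as `not_viable`.
#'
#' @param segments List of `ppg_segment`s for the device.
#' @param events_by_segment List of `vaso_events`, parallel to `segments`.
#' @param cv_by_segment List of `cv_series`, parallel to `segments`.
#' @param min_pairs Minimum pairs for a per-segment r (default 10).
#' @param mode Pairing mode, see [pair_mvasoc_with_cv()].
#' @param cor_method `"pearson"` (default) or `"spearman"`.
#' @return A `corr_report` (mode `within_device`).
#' @export
within_device_report <- function(segments, events_by_segment, cv_by_segment,
                                 min_pairs = 10L, mode = "zero_fill",
                                 cor_method = c("pearson", "spearman")) {
  cor_method <- match.arg(cor_method)
  n_seg <- length(segments)
  ps <- list(segment = integer(n_seg), r = rep(NA_real_, n_seg),
             p = rep(NA_real_, n_seg), n_pairs = integer(n_seg),
             included = logical(n_seg),
             exclusion_reason = rep(NA_character_, n_seg),
             x = vector("list", n_seg), y = vector("list", n_seg))
  for (i in seq_len(n_seg)) {
    ps$segment[i] <- segments[[i]]$index
    if (!segments[[i]]$viable) { ps$exclusion_reason[i] <- "not_viable"; next }
    cv <- cv_by_segment[[i]]
    if (is.null(cv)) { ps$exclusion_reason[i] <- "not_viable"; next }
    pairs <- pair_mvasoc_with_cv(events_by_segment[[i]], cv, mode = mode)
    ps$n_pairs[i] <- nrow(pairs)
    if (nrow(pairs) < min_pairs) { ps$exclusion_reason[i] <- "too_few_pairs"; next }
    ps$included[i] <- TRUE
    ps$x[[i]] <- pairs$mvasoc
    ps$y[[i]] <- pairs$cv
    if (stats::sd(pairs$mvasoc) > 0 && stats::sd(pairs$cv) > 0) {
      ct <- rank_cor_with_p(pairs$mvasoc, pairs$cv, cor_method)
      ps$r[i] <- ct$r; ps$p[i] <- ct$p
    }
  }
  new_corr_report("within_device", ps, min_pairs)
}

#' Across-device cross-validation of PPGampCV
#'
#' Correlates the finger and (aligned) wrist PPGampCV per corresponding
#' segment. A segment pair enters the analysis only when at least
#' `min_events` vasoconstriction events were detected in the segment on BOTH
#' devices (`too_few_events` otherwise), alignment succeeded
#' (`alignment_failed`), both segments are viable (`not_viable`) and at
#' least `min_pairs` paired CV points exist (`too_few_pairs`). Overnight r
#' pools the pairs of all included segments; peak r is the best included
#' per-segment r.
#'
#' @param finger_segments,wrist_segments Parallel lists of `ppg_segment`s.
#' @param finger_events,wrist_events Parallel lists of `vaso_events`.
#' @param finger_cv List of `cv_series` for finger segments.
#' @param wrist_cv_aligned List of `cv_series` computed from the aligned
#'   wrist series (same time base as the finger).
#' @param alignments List of `alignment_result`s, parallel to segments.
#' @param min_events Event-count inclusion threshold per device per segment
#'   (default 3).
#' @param min_pairs Minimum paired CV points per segment (default 10).
#' @param cor_method `"pearson"` (default) or `"spearman"`.
#' @return A `corr_report` (mode `across_device`).
#' @export
across_device_report <- function(finger_segments, wrist_segments,
                                 finger_events, wrist_events,
                                 finger_cv, wrist_cv_aligned, alignments,
                                 min_events = 3L, min_pairs = 10L,
                                 cor_method = c("pearson", "spearman")) {
  cor_method <- match.arg(cor_method)
  n_seg <- length(finger_segments)
  ps <- list(segment = integer(n_seg), r = rep(NA_real_, n_seg),
             p = rep(NA_real_, n_seg), n_pairs = integer(n_seg),
             included = logical(n_seg),
             exclusion_reason = rep(NA_character_, n_seg),
             x = vector("list", n_seg), y = vector("list", n_seg))
  for (i in seq_len(n_seg)) {
    ps$segment[i] <- finger_segments[[i]]$index
    if (!finger_segments[[i]]$viable || !wrist_segments[[i]]$viable) {
      ps$exclusion_reason[i] <- "not_viable"; next
    }
    al <- alignments[[i]]
    if (is.null(al) || !isTRUE(al$success)) {
      ps$exclusion_reason[i] <- "alignment_failed"; next
    }
    ne_f <- if (is.null(finger_events[[i]])) 0L else nrow(finger_events[[i]])
    ne_w <- if (is.null(wrist_events[[i]])) 0L else nrow(wrist_events[[i]])
    if (ne_f < min_events || ne_w < min_events) {
      ps$exclusion_reason[i] <- "too_few_events"; next
    }
    cf <- finger_cv[[i]]; cw <- wrist_cv_aligned[[i]]
    if (is.null(cf) || is.null(cw)) { ps$exclusion_reason[i] <- "not_viable"; next }
    # pair by CV center on the shared (finger) time base
    m <- match(round(cf$centers, 6), round(cw$centers, 6))
    keep <- which(!is.na(m) & cf$valid & cw$valid[ifelse(is.na(m), 1L, m)])
    x <- cf$values[keep]; y <- cw$values[m[keep]]
    ps$n_pairs[i] <- length(x)
    if (length(x) < min_pairs) { ps$exclusion_reason[i] <- "too_few_pairs"; next }
    ps$included[i] <- TRUE
    ps$x[[i]] <- x; ps$y[[i]] <- y
    if (stats::sd(x) > 0 && stats::sd(y) > 0) {
      ct <- rank_cor_with_p(x, y, cor_method)
      ps$r[i] <- ct$r; ps$p[i] <- ct$p
    }
  }
  new_corr_report("across_device", ps, min_pairs)
}

#' Regression of nightly median Mvasoc on median PPGampCV
#'
#' Ordinary least squares of the nightly median Mvasoc on the nightly median
#' PPGampCV across nights — the summary-level check that the two markers
#' track each other night to night.
#'
#' @param summaries A data frame (rbind of [summarize_night()] rows) with
#'   columns `median_mvasoc` and `median_cv`; at least 3 nights with both
#'   medians defined and a non-constant predictor.
#' @return List: `slope`, `intercept`, `r_squared`, `n`.
#' @export
nightly_medians_regression <- function(summaries) {
  ok <- is.finite(summaries$median_mvasoc) & is.finite(summaries$median_cv)
  x <- summaries$median_cv[ok]
  y <- summaries$median_mvasoc[ok]
  if (length(x) < 3L)
    stop_vw("need at least 3 nights with defined medians (got %d)", length(x),
            class = "vasowave_insufficient_data")
  if (stats::sd(x) == 0)
    stop_vw("median PPGampCV has zero variance across nights",
            class = "vasowave_domain_error")
  fit <- stats::lm.fit(cbind(1, x), y)
  res <- fit$residuals
  r2 <- 1 - sum(res^2) / sum((y - mean(y))^2)
  list(slope = unname(fit$coefficients[2]),
       intercept = unname(fit$coefficients[1]),
       r_squared = r2, n = length(x))
}
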