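# Segmentation, quality gating, capping, normalization, detrend + filter.

test_that("segment_night tiles the night into 900-s segments plus a short remainder", {
  s <- amp_series(rnorm(7200) + 10, t0 = 0, dt = 0.5)
  segs <- segment_night(s)
  expect_length(segs, 4L)
  expect_true(all(vapply(segs, function(x) x$end - x$start, numeric(1)) == 900))
  expect_true(all(vapply(segs, `[[`, logical(1), "viable")))
  starts <- vapply(segs, `[[`, numeric(1), "start")
  expect_equal(starts, c(0, 900, 1800, 2700))

  s2 <- amp_series(rnorm(2000) + 10, t0 = 0, dt = 0.5)   # 1000 s
  segs2 <- segment_night(s2)
  expect_length(segs2, 2L)
  expect_true(segs2[[1]]$viable)
  expect_false(segs2[[2]]$viable)
  expect_identical(segs2[[2]]$notes, "short")

  expect_identical(segment_night(amp_series(numeric(0))), list())
})

test_that("signal-loss gate marks heavily masked or motion segments non-viable", {
  v <- rnorm(1800) + 10
  seg_ok <- vasowave:::new_segment(1L, 0, 900, amp_series(v, dt = 0.5))
  expect_true(gate_signal_loss(seg_ok)$viable)

  mask <- rep(FALSE, 1800); mask[1:540] <- TRUE   # 30% masked
  seg_bad <- vasowave:::new_segment(1L, 0, 900, amp_series(v, dt = 0.5, mask = mask))
  out <- gate_signal_loss(seg_bad, max_masked_frac = 0.2)
  expect_false(out$viable)
  expect_true("signal_loss" %in% out$notes)

  acc <- rep(0, 1800); acc[1:700] <- 0.5
  seg_mot <- vasowave:::new_segment(1L, 0, 900,
                                    amp_series(v, dt = 0.5, accel = acc))
  out2 <- gate_signal_loss(seg_mot, max_masked_frac = 0.2, accel_thresh = 0.1)
  expect_false(out2$viable)
  expect_true("motion" %in% out2$notes)
})

test_that("short masked runs are interpolated across, long runs stay masked", {
  v <- sin(seq(0, 90, by = 0.5))[1:180] + 2
  mask <- rep(FALSE, 180)
  mask[50:57] <- TRUE    # 4 s run: interpolated
  mask[100:140] <- TRUE  # 20.5 s run: stays masked
  seg <- vasowave:::new_segment(1L, 0, 90, amp_series(v, dt = 0.5, mask = mask))
  out <- gate_signal_loss(seg, max_masked_frac = 0.5)
  expect_false(any(out$series$mask[50:57]))
  expect_true(all(out$series$mask[100:140]))
  expect_false(any(out$series$mask[c(1:49, 58:99, 141:180)]))
})

test_that("outlier capping pins the maximum at the pre-cap 98th percentile", {
  seg <- vasowave:::new_segment(1L, 0, 50, amp_series(1:100, dt = 0.5))
  out <- cap_outliers(seg)
  p98 <- quantile(1:100, 0.98, names = FALSE)
  expect_equal(max(out$series$values), p98, tolerance = 1e-12)
  n_alter <- sum(1:100 > p98)
  expect_identical(sum(out$series$values != 1:100), n_alter)
  expect_identical(out$series$stage, "capped")

  const <- vasowave:::new_segment(1L, 0, 50, amp_series(rep(4, 100), dt = 0.5))
  expect_true(all(cap_outliers(const)$series$values == 4))
})

test_that("capping and normalization ignore masked points; masks persist", {
  v <- c(rep(1, 90), rep(1000, 10))   # the masked points are huge
  mask <- c(rep(FALSE, 90), rep(TRUE, 10))
  seg <- vasowave:::new_segment(1L, 0, 50, amp_series(v, dt = 0.5, mask = mask))
  out <- normalize_segment(cap_outliers(seg))
  expect_identical(out$series$mask, mask)
  expect_true(all(out$series$values[!mask] == 1))
})

test_that("normalization sets P95 to exactly 1 and is idempotent", {
  set.seed(1)
  seg <- vasowave:::new_segment(1L, 0, 450,
                                amp_series(rexp(900) + 0.5, dt = 0.5))
  n1 <- normalize_segment(cap_outliers(seg))
  v1 <- n1$series$values
  expect_equal(quantile(v1, 0.95, names = FALSE), 1, tolerance = 1e-12)
  n2 <- normalize_segment(n1)
  expect_equal(n2$series$values, v1, tolerance = 1e-12)

  flat <- vasowave:::new_segment(1L, 0, 50, amp_series(rep(0, 100), dt = 0.5))
  out <- normalize_segment(cap_outliers(flat))
  expect_false(out$viable)
  expect_true("degenerate" %in% out$notes)
})

test_that("stage transitions only happen in the documented order", {
  seg <- vasowave:::new_segment(1L, 0, 450, amp_series(rnorm(900) + 5, dt = 0.5))
  expect_error(normalize_segment(seg), class = "vasowave_stage_error")
  expect_error(detrend_and_filter(seg), class = "vasowave_stage_error")
  capped <- cap_outliers(seg)
  expect_error(cap_outliers(capped), class = "vasowave_stage_error")
})

test_that("Butterworth coefficients match the reference design", {
  # frozen from scipy.signal.butter(4, 0.15, fs=2) during development
  co <- butter_lowpass(4, 0.15, fs = 2)
  expect_equal(co$b,
               c(0.001782609992, 0.007130439968, 0.010695659952,
                 0.007130439968, 0.001782609992), tolerance = 1e-9)
  expect_equal(co$a,
               c(1, -2.7736823175, 3.0190386994, -1.5047650514, 0.2879304294),
               tolerance = 1e-9)
  expect_error(butter_lowpass(4, 1.1, fs = 2), class = "vasowave_config_error")
})

test_that("detrending removes a pure linear ramp", {
  ramp <- seq(1, 3, length.out = 1800)
  seg <- make_norm_segment(ramp)   # capping would flatten the ramp's top
  out <- detrend_and_filter(seg)
  expect_true(out$viable)
  expect_lt(max(abs(out$series$values)), 1e-6 * diff(range(ramp)))
  expect_identical(out$series$stage, "detrended_filtered")
  expect_equal(out$series$level, mean(ramp), tolerance = 1e-12)
})

test_that("the respiratory filter passes 0.05 Hz and rejects 0.30 Hz", {
  t <- seq(0, 899.5, by = 0.5)
  gain_at <- function(f) {
    x <- 5 + sin(2 * pi * f * t)
    seg <- vasowave:::new_segment(1L, 0, 900, amp_series(x, dt = 0.5))
    seg$series$stage <- "normalized"
    out <- detrend_and_filter(seg)
    interior <- 200:1600
    max(abs(out$series$values[interior]))
  }
  expect_gte(gain_at(0.05), 0.95)
  expect_lte(gain_at(0.30), 0.10)
})

test_that("zero-phase filtering does not shift event timing", {
  t <- seq(0, 899.5, by = 0.5)
  dip <- 1 - 0.5 * exp(-((t - 450) / 15)^2)
  seg <- vasowave:::new_segment(1L, 0, 900, amp_series(dip, dt = 0.5))
  seg$series$stage <- "normalized"
  out <- detrend_and_filter(seg)
  expect_equal(t[which.min(out$series$values)], 450, tolerance = 1)
})

test_that("the clean segment is invariant to positive rescaling of raw amplitudes", {
  set.seed(2)
  v <- 2 + cumsum(rnorm(1800, sd = 0.05))
  v <- v - min(v) + 1
  mk <- function(k) {
    seg <- vasowave:::new_segment(1L, 0, 900, amp_series(v * k, dt = 0.5))
    clean_segment(seg)
  }
  a <- mk(1); b <- mk(13.7)
  expect_equal(b$series$values, a$series$values, tolerance = 1e-10)
})

test_that("gate decisions match the dropout bookkeeping oracle exactly", {
  set.seed(9)
  n <- 14400   # 2 h at dt = 0.5
  v <- rnorm(n) + 10
  mask <- rep(FALSE, n)
  # inject ~20% dropout as scattered 60-s holes
  holes <- sample.int(n - 120, 24)
  for (h in holes) mask[h:(h + 119)] <- TRUE
  s <- amp_series(v, dt = 0.5, mask = mask)
  segs <- segment_night(s)
  gated <- lapply(segs, gate_signal_loss, max_masked_frac = 0.2)
  got <- vapply(gated, `[[`, logical(1), "viable")
  # oracle: a full segment survives iff its own masked fraction is <= 0.2
  want <- vapply(segs, function(sg) mean(sg$series$mask) <= 0.2, logical(1))
  expect_identical(got, want)
})
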