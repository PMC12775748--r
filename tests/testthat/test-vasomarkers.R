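# Mvasoc event detection, the Mvasoc formula, PPGampCV, night summaries.

test_that("mvasoc_of_event implements the normalized drop-area ratio", {
  expect_equal(mvasoc_of_event(5, 10, 1), 0.5)
  expect_equal(mvasoc_of_event(0, 10, 2), 0)
  expect_equal(mvasoc_of_event(3, 6, 2), 0.25)
  expect_error(mvasoc_of_event(5, 0, 1), class = "vasowave_domain_error")
  expect_error(mvasoc_of_event(5, 10, 0), class = "vasowave_domain_error")
  expect_error(mvasoc_of_event(-1, 10, 1), class = "vasowave_domain_error")
})

test_that("a rectangular dip yields mvasoc ~ depth/baseline (closed form)", {
  t <- seq(0, 179.5, by = 0.5)
  d <- 0.5
  v <- rep(1, length(t)); v[t >= 60 & t < 70] <- 1 - d
  seg <- make_norm_segment(v)
  ev <- detect_vaso_events(seg, depth_thresh = 0.2, min_dur_s = 2)
  expect_identical(nrow(ev), 1L)
  expect_equal(ev$duration, 10, tolerance = 0.1)
  expect_equal(ev$baseline, 1, tolerance = 1e-9)
  expect_lt(abs(ev$mvasoc - d) / d, 0.05)
})

test_that("a triangular dip yields mvasoc ~ depth/(2*baseline)", {
  t <- seq(0, 179.5, by = 0.5)
  d <- 0.4; T_ <- 20
  v <- rep(1, length(t))
  tri <- t >= 60 & t <= 60 + T_
  v[tri] <- 1 - d * (1 - abs((t[tri] - 70) / (T_ / 2)))
  seg <- make_norm_segment(v)
  ev <- detect_vaso_events(seg, depth_thresh = 0.15, min_dur_s = 3)
  expect_identical(nrow(ev), 1L)
  expect_lt(abs(ev$mvasoc - d / 2) / (d / 2), 0.05)
})

test_that("separated dips give independent events with their own baselines", {
  t <- seq(0, 299.5, by = 0.5)
  v <- rep(1, length(t))
  v[t >= 60 & t < 70] <- 0.6
  v[t >= 120 & t < 135] <- 0.7    # >= 15 s of recovery in between
  seg <- make_norm_segment(v)
  ev <- detect_vaso_events(seg, depth_thresh = 0.2, min_dur_s = 2)
  expect_identical(nrow(ev), 2L)
  expect_true(all(abs(ev$baseline - 1) < 1e-9))
  expect_true(ev$start[2] > ev$end[1])
  # brute-force scan oracle: no sample below threshold outside the two events
  outside <- !((t >= ev$start[1] & t < ev$end[1]) | (t >= ev$start[2] & t < ev$end[2]))
  expect_true(all(v[outside] >= 0.8))
})

test_that("quiet or short segments yield no events", {
  expect_identical(nrow(detect_vaso_events(make_norm_segment(rep(1, 360)))), 0L)
  short <- make_norm_segment(rep(1, 20))   # 10 s < baseline_s + min_dur_s
  expect_identical(nrow(detect_vaso_events(short)), 0L)
  nonviable <- make_norm_segment(rep(1, 360)); nonviable$viable <- FALSE
  expect_identical(nrow(detect_vaso_events(nonviable)), 0L)
})

test_that("events shorter than min_dur_s are discarded", {
  t <- seq(0, 179.5, by = 0.5)
  v <- rep(1, length(t)); v[t >= 60 & t < 61.5] <- 0.5
  seg <- make_norm_segment(v)
  expect_identical(nrow(detect_vaso_events(seg, min_dur_s = 3)), 0L)
  expect_identical(nrow(detect_vaso_events(seg, min_dur_s = 1)), 1L)
})

test_that("mvasoc is invariant to rescaling the clean PPGamp", {
  t <- seq(0, 299.5, by = 0.5)
  set.seed(4)
  v <- 1 + 0.02 * rnorm(length(t))
  v[t >= 100 & t < 125] <- v[t >= 100 & t < 125] - 0.4
  e1 <- detect_vaso_events(make_norm_segment(v))
  e2 <- detect_vaso_events(make_norm_segment(v * 7.3))
  expect_identical(nrow(e1), nrow(e2))
  expect_equal(e2$mvasoc, e1$mvasoc, tolerance = 1e-10)
  expect_equal(e2$baseline, e1$baseline * 7.3, tolerance = 1e-10)
})

test_that("PPGampCV is zero for constant series and scale-invariant", {
  s <- amp_series(rep(3, 1200), dt = 0.5)
  cv <- ppgamp_cv(s)
  expect_true(all(cv$valid))
  expect_true(all(cv$values == 0))

  set.seed(5)
  v <- rexp(1200) + 1
  a <- ppgamp_cv(amp_series(v, dt = 0.5))
  b <- ppgamp_cv(amp_series(v * 41.3, dt = 0.5))
  expect_identical(a$centers, b$centers)
  expect_equal(a$values, b$values, tolerance = 1e-12)
})

test_that("CV matches the two-point hand oracle sd(c(1,3))/mean = 0.7071", {
  s <- amp_series(c(1, 3), t0 = 0, dt = 150)
  cv <- ppgamp_cv(s, window_s = 300, step_s = 30)
  expect_true(any(cv$valid))
  expect_equal(unique(cv$values[cv$valid]), sqrt(2) / 2, tolerance = 1e-9)
})

test_that("CV windows are invalidated by masking and non-positive means", {
  v <- rep(1, 1200); mask <- rep(FALSE, 1200)
  mask[1:400] <- TRUE   # first windows > 25% masked
  cv <- ppgamp_cv(amp_series(v, dt = 0.5, mask = mask))
  expect_false(cv$valid[1])
  expect_true(cv$valid[length(cv$valid)])

  neg <- amp_series(rep(-1, 1200), dt = 0.5)
  cvn <- ppgamp_cv(neg)
  expect_false(any(cvn$valid))

  expect_error(ppgamp_cv(amp_series(rep(1, 100), dt = 0.5)),
               class = "vasowave_insufficient_data")
})

test_that("night summaries take medians over pooled events and valid CV", {
  ev <- function(m) data.frame(start = 0, end = 10, duration = 10,
                               baseline = 1, drop_area = m * 10, mvasoc = m,
                               flag = "")
  cv <- structure(list(centers = c(150, 180, 210),
                       values = c(0.1, 0.2, NA), valid = c(TRUE, TRUE, FALSE),
                       window_s = 300, step_s = 30), class = "cv_series")
  s <- summarize_night(list(ev(0.1), ev(0.2), ev(0.3)), cv,
                       night_id = "n1", device_id = "finger")
  expect_equal(s$median_mvasoc, 0.2)
  expect_equal(s$median_cv, 0.15)
  expect_identical(s$n_events, 3L)

  s1 <- summarize_night(list(ev(0.42)), cv)
  expect_equal(s1$median_mvasoc, 0.42)

  s0 <- summarize_night(list(ev(0.1)[0, ]), cv)
  expect_true(is.na(s0$median_mvasoc))
  expect_identical(s0$n_events, 0L)

  expect_error(summarize_night(list(), cv), class = "vasowave_insufficient_data")
})

test_that("median mvasoc and CV rise monotonically with injected intensity", {
  level <- seq_len(5)
  one_night <- function(l, sd) {
    cfg <- sim_config(duration = 1800, seed = 100 + 7 * l + sd,
                      event_rate = 10 + 10 * l,
                      event_depth_mean = 0.1 + 0.08 * l,
                      event_depth_sd = 0.03,
                      sample_rate = c(finger = 50, wrist = 25),
                      motion_artifact_rate = 0, hourly_pause = FALSE,
                      activity_mod = 0)
    sim <- simulate_night(cfg)
    segs <- process_segments(sim$finger)
    viable <- segs[vapply(segs, `[[`, logical(1), "viable")]
    evs <- lapply(viable, detect_vaso_events)
    cvs <- lapply(viable, ppgamp_cv)
    s <- summarize_night(evs, vasowave:::bind_cv_series(cvs))
    c(s$median_mvasoc, s$median_cv)
  }
  # mean over 3 seeded replicates per intensity level
  res <- t(vapply(level, function(l)
    rowMeans(vapply(1:3, function(sd) one_night(l, sd), numeric(2))),
    numeric(2)))
  expect_true(all(diff(res[, 1]) > 0))
  expect_true(all(diff(res[, 2]) > 0))
})
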