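# Correlation machinery and the validation reports.

test_that("pearson_with_p matches hand and reference oracles", {
  expect_equal(pearson_with_p(1:10, 1:10)$r, 1)
  expect_equal(pearson_with_p(1:10, -(1:10))$r, -1)

  x <- c(1, 2, 3, 4); y <- c(1, 2, 3, 5)
  res <- pearson_with_p(x, y)
  expect_equal(res$r, 0.9827, tolerance = 1e-4)
  ct <- cor.test(x, y)
  expect_equal(res$r, unname(ct$estimate), tolerance = 1e-12)
  expect_equal(res$p, ct$p.value, tolerance = 1e-12)

  set.seed(10)
  a <- rnorm(40); b <- 0.3 * a + rnorm(40)
  ct2 <- cor.test(a, b)
  res2 <- pearson_with_p(a, b)
  expect_equal(res2$r, unname(ct2$estimate), tolerance = 1e-12)
  expect_equal(res2$p, ct2$p.value, tolerance = 1e-12)

  expect_error(pearson_with_p(1:2, 2:3), class = "vasowave_insufficient_data")
  expect_error(pearson_with_p(rep(1, 10), 1:10), class = "vasowave_domain_error")
})

test_that("pairing holds event mvasoc over its interval on the CV grid", {
  cv <- structure(list(centers = seq(150, 750, by = 30),
                       values = seq(0.1, 0.3, length.out = 21),
                       valid = rep(TRUE, 21), window_s = 300, step_s = 30),
                  class = "cv_series")
  one <- data.frame(start = 0, end = 900, duration = 900, baseline = 1,
                    drop_area = 90, mvasoc = 0.1, flag = "")
  p <- pair_mvasoc_with_cv(one, cv)
  expect_identical(nrow(p), 21L)
  expect_true(all(p$mvasoc == 0.1))

  p0 <- pair_mvasoc_with_cv(one[0, ], cv, mode = "zero_fill")
  expect_identical(nrow(p0), 21L)
  expect_true(all(p0$mvasoc == 0))

  pe <- pair_mvasoc_with_cv(one[0, ], cv, mode = "event_only")
  expect_identical(nrow(pe), 0L)

  two <- data.frame(start = c(140, 400), end = c(200, 430),
                    duration = c(60, 30), baseline = 1,
                    drop_area = c(12, 9), mvasoc = c(0.2, 0.3), flag = "")
  cv$valid[3] <- FALSE
  p2 <- pair_mvasoc_with_cv(two, cv)
  # bookkeeping: pairs = valid grid points (zero-fill keeps all valid)
  expect_identical(nrow(p2), sum(cv$valid))
  expect_true(all(p2$mvasoc[p2$center >= 140 & p2$center < 200] == 0.2))
  expect_true(all(p2$mvasoc[p2$center >= 430] == 0))
})

make_cv <- function(values, valid = rep(TRUE, length(values))) {
  structure(list(centers = seq(150, by = 30, length.out = length(values)),
                 values = values, valid = valid, window_s = 300, step_s = 30),
            class = "cv_series")
}
stub_seg <- function(i, viable = TRUE) {
  vasowave:::new_segment(i, (i - 1) * 900, i * 900,
                         amp_series(rep(1, 10), dt = 0.5), viable = viable)
}

test_that("within_device_report pools pairs and tracks exclusions", {
  set.seed(11)
  cvs <- list(make_cv(runif(21, 0.05, 0.3)), make_cv(runif(21, 0.05, 0.3)),
              NULL)
  evs <- list(
    data.frame(start = c(150, 400), end = c(300, 500), duration = c(150, 100),
               baseline = 1, drop_area = c(30, 40), mvasoc = c(0.2, 0.4),
               flag = ""),
    data.frame(start = 920, end = 1100, duration = 180, baseline = 1,
               drop_area = 36, mvasoc = 0.2, flag = "")[0, ],
    NULL)
  segs <- list(stub_seg(1), stub_seg(2), stub_seg(3, viable = FALSE))
  rep_ <- within_device_report(segs, evs, cvs)
  expect_s3_class(rep_, "corr_report")
  expect_identical(rep_$mode, "within_device")
  per <- rep_$per_segment
  expect_identical(per$exclusion_reason[3], "not_viable")
  expect_true(all(per$included[1:2]))
  # oracle: overnight r recomputed by pooling the same pairs directly
  pairs <- rbind(pair_mvasoc_with_cv(evs[[1]], cvs[[1]]),
                 pair_mvasoc_with_cv(evs[[2]], cvs[[2]]))
  ov <- pearson_with_p(pairs$mvasoc, pairs$cv)
  expect_equal(rep_$overnight_r, ov$r, tolerance = 1e-12)
  expect_equal(rep_$overnight_p, ov$p, tolerance = 1e-12)
  # peak is the max included per-segment r
  expect_equal(rep_$peak_r, max(per$r[per$included], na.rm = TRUE),
               tolerance = 1e-12)
  expect_true(all(per$r[!is.na(per$r)] >= -1 & per$r[!is.na(per$r)] <= 1))
})

test_that("across_device_report applies the >=3-event rule and alignment gate", {
  set.seed(12)
  v <- runif(21, 0.05, 0.3)
  mk_ev <- function(n) if (n == 0) NULL else
    data.frame(start = seq_len(n) * 40, end = seq_len(n) * 40 + 20,
               duration = 20, baseline = 1, drop_area = 4, mvasoc = 0.2,
               flag = "")
  segs <- list(stub_seg(1), stub_seg(2), stub_seg(3))
  al_ok <- list(lag_s = 0, peak_xcorr = 0.9, success = TRUE)
  rep_ <- across_device_report(
    finger_segments = segs, wrist_segments = segs,
    finger_events = list(mk_ev(2), mk_ev(5), mk_ev(4)),
    wrist_events = list(mk_ev(5), mk_ev(5), mk_ev(4)),
    finger_cv = list(make_cv(v), make_cv(v), make_cv(v)),
    wrist_cv_aligned = list(make_cv(v), make_cv(v), make_cv(v * 2 + 0.01)),
    alignments = list(al_ok, al_ok, NULL),
    min_events = 3)
  per <- rep_$per_segment
  expect_identical(per$exclusion_reason[1], "too_few_events")
  expect_identical(per$exclusion_reason[3], "alignment_failed")
  expect_true(per$included[2])
  expect_equal(per$r[2], 1, tolerance = 1e-12)   # identical CV both devices
  expect_equal(rep_$overnight_r, 1, tolerance = 1e-12)
})

test_that("the event-count rule is bookkeeping only: included r values unchanged", {
  set.seed(13)
  v1 <- runif(21, 0.05, 0.3); v2 <- runif(21, 0.05, 0.3)
  w1 <- v1 + rnorm(21, sd = 0.02); w2 <- v2 + rnorm(21, sd = 0.02)
  segs <- list(stub_seg(1), stub_seg(2))
  mk_ev <- function(n) data.frame(start = seq_len(n) * 40,
                                  end = seq_len(n) * 40 + 20, duration = 20,
                                  baseline = 1, drop_area = 4, mvasoc = 0.2,
                                  flag = "")
  al_ok <- list(lag_s = 0, peak_xcorr = 0.9, success = TRUE)
  args <- list(finger_segments = segs, wrist_segments = segs,
               wrist_events = list(mk_ev(5), mk_ev(5)),
               finger_cv = list(make_cv(v1), make_cv(v2)),
               wrist_cv_aligned = list(make_cv(w1), make_cv(w2)),
               alignments = list(al_ok, al_ok))
  strict <- do.call(across_device_report,
                    c(args, list(finger_events = list(mk_ev(2), mk_ev(5)),
                                 min_events = 3)))
  loose <- do.call(across_device_report,
                   c(args, list(finger_events = list(mk_ev(2), mk_ev(5)),
                                min_events = 0)))
  expect_false(strict$per_segment$included[1])
  expect_true(all(loose$per_segment$included))
  expect_lte(strict$n_included, loose$n_included)
  expect_equal(strict$per_segment$r[2], loose$per_segment$r[2], tolerance = 1e-12)
})

test_that("nightly medians regression matches the least-squares oracle", {
  col <- data.frame(median_mvasoc = c(0.1, 0.2, 0.3, 0.4),
                    median_cv = c(0.05, 0.10, 0.15, 0.20))
  fit <- nightly_medians_regression(col)
  expect_equal(fit$r_squared, 1, tolerance = 1e-12)
  expect_equal(fit$slope, 2, tolerance = 1e-12)

  hand <- data.frame(median_mvasoc = c(0, 1, 2.1), median_cv = c(0, 1, 2))
  fit2 <- nightly_medians_regression(hand)
  # closed form: R^2 = Sxy^2 / (Sxx * Syy) = 4.41 / 4.41333...
  expect_equal(fit2$r_squared, 0.99924471, tolerance = 1e-7)
  lmfit <- lm(median_mvasoc ~ median_cv, data = hand)
  expect_equal(fit2$slope, unname(coef(lmfit)[2]), tolerance = 1e-12)
  expect_equal(fit2$r_squared, summary(lmfit)$r.squared, tolerance = 1e-12)

  expect_error(nightly_medians_regression(hand[1:2, ]),
               class = "vasowave_insufficient_data")
  flat <- data.frame(median_mvasoc = c(0.1, 0.2, 0.3), median_cv = rep(0.1, 3))
  expect_error(nightly_medians_regression(flat), class = "vasowave_domain_error")
})

test_that("reports are bit-reproducible for identical inputs", {
  fx <- fx_night()
  fin <- get_fixture("proc_finger_default", function()
    process_night(fx$sim$finger, run_config()))
  a <- within_device_report(fin$segments, fin$events, fin$cv_by_segment)
  b <- within_device_report(fin$segments, fin$events, fin$cv_by_segment)
  expect_identical(a$overnight_r, b$overnight_r)
  expect_identical(a$per_segment, b$per_segment)
})
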