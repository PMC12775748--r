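# End-to-end pipeline: simulate (or ingest) -> extract -> preprocess ->
# markers -> align -> validate, reproducibly under one config + seed, with
# CSV outputs and a JSON run manifest.

#' Pipeline run configuration
#'
#' Bundles every stage parameter; the defaults reproduce the published
#' constants of the method: 900-s segments, 98th-percentile capping,
#' 95th-percentile normalization, 0.15 Hz respiratory cutoff, 15-s event
#' baseline, 300-s/30-s CV window and step, +/-30-s lag window, and the
#' 3-event across-device inclusion rule.
#'
#' @param seed Integer master seed; per-night simulation seeds are derived
#'   from it.
#' @param n_nights Number of simulated nights.
#' @param night_duration_s Length of each simulated night, seconds.
#' @param sim_args Named list of overrides passed to [sim_config()].
#' @param grid_dt PPGamp grid spacing, s.
#' @param hr_min_bpm,hr_max_bpm,prominence_frac Beat-detector parameters.
#' @param seg_len_s Segment length, s.
#' @param max_masked_frac,accel_thresh Quality-gate parameters.
#' @param cap_pctl,norm_pctl,cutoff_hz Preprocessing parameters.
#' @param baseline_s,depth_thresh,min_dur_s Event-detection parameters.
#' @param window_s,step_s PPGampCV window and step, s.
#' @param max_lag_s Alignment search half-window, s.
#' @param min_events Across-device per-segment event threshold.
#' @param min_pairs Minimum pairs for a per-segment correlation.
#' @param cor_method `"pearson"` or `"spearman"`.
#' @param pairing_mode Mvasoc-to-grid pairing mode.
#' @return A validated `run_config` list.
#' @export
run_config <- function(seed = 1L, n_nights = 3L, night_duration_s = 3600,
                       sim_args = list(), grid_dt = 0.5,
                       hr_min_bpm = 40, hr_max_bpm = 180, prominence_frac = 0.3,
                       seg_len_s = 900, max_masked_frac = 0.2,
                       accel_thresh = 0.1, cap_pctl = 98, norm_pctl = 95,
                       cutoff_hz = 0.15, baseline_s = 15, depth_thresh = 0.15,
                       min_dur_s = 3, window_s = 300, step_s = 30,
                       max_lag_s = 30, min_events = 3L, min_pairs = 10L,
                       cor_method = "pearson", pairing_mode = "zero_fill") {
  cfg <- as.list(environment())
  stopifnot(cfg$n_nights >= 1, cfg$night_duration_s > 0, cfg$grid_dt > 0,
            cfg$seg_len_s > 0, cfg$window_s > 0, cfg$step_s > 0,
            cfg$max_lag_s > 0, cfg$min_events >= 0)
  class(cfg) <- "run_config"
  cfg
}

#' Process one device-night from raw record to markers
#'
#' Runs beat detection, PPGamp extraction, segmentation, the preprocessing
#' chain, event detection and PPGampCV for a single [ppg_record()].
#'
#' @param record A [ppg_record()].
#' @param cfg A [run_config()].
#' @return List: `series` (raw [amp_series()]), `segments` (cleaned),
#'   `events` (per segment), `cv_by_segment`, `cv` (night-level
#'   `cv_series`), `summary` ([summarize_night()] row), `n_beats`.
#' @export
process_night <- function(record, cfg = run_config()) {
  beats <- detect_beats(record, cfg$hr_min_bpm, cfg$hr_max_bpm,
                        cfg$prominence_frac)
  series <- build_amp_series(beats, cfg$grid_dt, record = record)
  segs <- segment_night(series, cfg$seg_len_s)
  segs <- lapply(segs, function(sg) {
    if (!sg$viable) return(sg)
    clean_segment(sg, cfg$max_masked_frac, cfg$accel_thresh, cfg$cap_pctl,
                  cfg$norm_pctl, cfg$cutoff_hz)
  })
  events <- lapply(segs, function(sg) {
    if (!sg$viable) return(NULL)
    detect_vaso_events(sg, cfg$baseline_s, cfg$depth_thresh, cfg$min_dur_s)
  })
  cvs <- lapply(segs, function(sg) {
    if (!sg$viable) return(NULL)
    tryCatch(ppgamp_cv(sg, cfg$window_s, cfg$step_s),
             vasowave_insufficient_data = function(e) NULL)
  })
  viable <- vapply(segs, `[[`, logical(1), "viable")
  summary <- summarize_night(events[viable], bind_cv_series(cvs),
                             night_id = record$night_id,
                             device_id = record$device_id,
                             n_viable_segments = sum(viable))
  list(series = series, segments = segs, events = events,
       cv_by_segment = cvs, cv = bind_cv_series(cvs), summary = summary,
       n_beats = nrow(beats))
}

# Align every corresponding viable segment pair and compute the aligned
# wrist CV on the finger time base.
align_night <- function(fin, wri, cfg) {
  n <- min(length(fin$segments), length(wri$segments))
  alignments <- vector("list", n)
  wrist_cv_aligned <- vector("list", n)
  for (i in seq_len(n)) {
    fs <- fin$segments[[i]]; ws <- wri$segments[[i]]
    if (!fs$viable || !ws$viable) next
    al <- tryCatch(suppressWarnings(align_pair(fs, ws, cfg$max_lag_s)),
                   vasowave_insufficient_data = function(e) NULL)
    alignments[[i]] <- al
    if (!is.null(al) && isTRUE(al$success))
      wrist_cv_aligned[[i]] <- tryCatch(
        ppgamp_cv(al$wrist_aligned, cfg$window_s, cfg$step_s),
        vasowave_insufficient_data = function(e) NULL)
  }
  list(alignments = alignments, wrist_cv_aligned = wrist_cv_aligned)
}

#' Run the full simulated-cohort pipeline
#'
#' For each night: simulate a paired finger/wrist recording, write the
#' fixtures (`finger.edf`, `wrist.csv`, `truth.json`), read them back
#' through the format readers, process both devices, align segments, and
#' compute within- and across-device reports. Writes `nightly_summary.csv`,
#' `within_device.csv`, `across_device.csv`, `events.csv`, `cv.csv` and
#' `manifest.json` under `out_dir`. Rerunning with an identical config
#' produces byte-identical CSV outputs.
#'
#' @param cfg A [run_config()].
#' @param out_dir Output directory (created if needed).
#' @return Invisibly, a list with the per-night results and the paths of
#'   the written artifacts.
#' @export
run_pipeline <- function(cfg = run_config(), out_dir) {
  stopifnot(inherits(cfg, "run_config"))
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  nights <- list()
  summary_rows <- list(); wd_rows <- list(); ad_rows <- list()
  event_rows <- list(); cv_rows <- list()

  for (night in seq_len(cfg$n_nights)) {
    night_id <- sprintf("night%02d", night)
    sim_args <- utils::modifyList(
      list(duration = cfg$night_duration_s, seed = cfg$seed * 1000L + night),
      cfg$sim_args)
    scfg <- do.call(sim_config, sim_args)
    sim <- simulate_night(scfg)
    ndir <- file.path(out_dir, night_id)
    dir.create(ndir, showWarnings = FALSE)
    f_path <- file.path(ndir, "finger.edf")
    w_path <- file.path(ndir, "wrist.csv")
    write_fixture(sim$finger, f_path, "edf")
    write_fixture(sim$wrist, w_path, "csv")
    jsonlite::write_json(
      list(events = sim$truth$events, true_lag = sim$truth$true_lag,
           gap_intervals = as.data.frame(sim$truth$gap_intervals)),
      file.path(ndir, "truth.json"), auto_unbox = TRUE, digits = NA)

    finger <- read_edf_record(f_path, "PPG", night_id = night_id)
    wrist <- read_csv_record(w_path, night_id = night_id)
    fin <- process_night(finger, cfg)
    wri <- process_night(wrist, cfg)
    aln <- align_night(fin, wri, cfg)

    wd_f <- within_device_report(fin$segments, fin$events, fin$cv_by_segment,
                                 cfg$min_pairs, cfg$pairing_mode, cfg$cor_method)
    wd_w <- within_device_report(wri$segments, wri$events, wri$cv_by_segment,
                                 cfg$min_pairs, cfg$pairing_mode, cfg$cor_method)
    ad <- across_device_report(fin$segments, wri$segments, fin$events,
                               wri$events, fin$cv_by_segment,
                               aln$wrist_cv_aligned, aln$alignments,
                               cfg$min_events, cfg$min_pairs, cfg$cor_method)

    summary_rows[[night]] <- data.frame(
      night = night_id,
      n_segments = length(fin$segments),
      finger_events = fin$summary$n_events,
      wrist_events = wri$summary$n_events,
      finger_median_mvasoc = fin$summary$median_mvasoc,
      wrist_median_mvasoc = wri$summary$median_mvasoc,
      finger_median_cv = fin$summary$median_cv,
      wrist_median_cv = wri$summary$median_cv)
    wd_rows[[night]] <- data.frame(
      night = night_id, device = c("finger", "wrist"),
      overnight_r = c(wd_f$overnight_r, wd_w$overnight_r),
      overnight_p = c(wd_f$overnight_p, wd_w$overnight_p),
      peak_r = c(wd_f$peak_r, wd_w$peak_r),
      n_segments_included = c(wd_f$n_included, wd_w$n_included))
    ad_rows[[night]] <- data.frame(
      night = night_id, overnight_r = ad$overnight_r,
      overnight_p = ad$overnight_p, peak_r = ad$peak_r,
      n_segments_included = ad$n_included,
      n_excluded_too_few_events = sum(ad$per_segment$exclusion_reason %in%
                                        "too_few_events"))
    for (dev in c("finger", "wrist")) {
      res <- if (dev == "finger") fin else wri
      for (i in seq_along(res$events)) {
        ev <- res$events[[i]]
        if (is.null(ev) || nrow(ev) == 0L) next
        event_rows[[length(event_rows) + 1L]] <-
          cbind(night = night_id, device = dev, segment = i,
                ev[c("start", "end", "duration", "baseline", "drop_area",
                     "mvasoc")])
      }
      if (!is.null(res$cv))
        cv_rows[[length(cv_rows) + 1L]] <- data.frame(
          night = night_id, device = dev, center_s = res$cv$centers,
          cv = res$cv$values, valid = res$cv$valid)
    }
    nights[[night]] <- list(finger = fin, wrist = wri, alignment = aln,
                            within_device = list(finger = wd_f, wrist = wd_w),
                            across_device = ad, truth = sim$truth)
  }

  summaries <- do.call(rbind, summary_rows)
  artifacts <- c(nightly_summary = "nightly_summary.csv",
                 within_device = "within_device.csv",
                 across_device = "across_device.csv",
                 events = "events.csv", cv = "cv.csv")
  utils::write.csv(summaries, file.path(out_dir, artifacts["nightly_summary"]),
                   row.names = FALSE)
  utils::write.csv(do.call(rbind, wd_rows),
                   file.path(out_dir, artifacts["within_device"]),
                   row.names = FALSE)
  utils::write.csv(do.call(rbind, ad_rows),
                   file.path(out_dir, artifacts["across_device"]),
                   row.names = FALSE)
  utils::write.csv(do.call(rbind, event_rows),
                   file.path(out_dir, artifacts["events"]), row.names = FALSE)
  utils::write.csv(do.call(rbind, cv_rows),
                   file.path(out_dir, artifacts["cv"]), row.names = FALSE)

  regression <- NULL
  med <- data.frame(median_mvasoc = summaries$finger_median_mvasoc,
                    median_cv = summaries$finger_median_cv)
  if (sum(stats::complete.cases(med)) >= 3 && stats::sd(med$median_cv, na.rm = TRUE) > 0)
    regression <- nightly_medians_regression(med)

  cfg_json <- jsonlite::toJSON(cfg[setdiff(names(cfg), "sim_args")],
                               auto_unbox = TRUE, digits = NA)
  cfg_file <- file.path(out_dir, "config.json")
  writeLines(cfg_json, cfg_file)
  manifest <- list(package = "vasowave",
                   version = as.character(utils::packageVersion("vasowave")),
                   seed = cfg$seed,
                   config_md5 = unname(tools::md5sum(cfg_file)),
                   n_nights = cfg$n_nights,
                   artifacts = as.list(artifacts),
                   nightly_medians_regression = regression)
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  invisible(list(nights = nights, summaries = summaries,
                 regression = regression, out_dir = out_dir,
                 artifacts = file.path(out_dir, artifacts)))
}
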