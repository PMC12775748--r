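---
title: "Quantifying nocturnal vasoconstriction from PPG amplitude: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying nocturnal vasoconstriction from PPG amplitude: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(vasowave)
```

## The physiological signal

Each heartbeat pushes a pulse of blood into the microvasculature; a
photoplethysmography (PPG) sensor sees it as one pulse of optical
absorption. The peak-to-trough height of that pulse — the **PPGamp** — is
proportional to the pulsatile arteriolar blood volume. When sympathetic
outflow constricts the peripheral vessels, PPGamp drops transiently, for
seconds to tens of seconds. Counting and sizing those drops over a night
yields an index of nocturnal autonomic vasoreactivity, of particular
interest in sickle cell disease, where vasoconstriction reduces
microvascular flow and raises the risk of vaso-occlusion.

vasowave computes two markers from the cleaned PPGamp signal:

* **Mvasoc** — per detected event, the area of the drop below the preceding
  15-second baseline, divided by the event duration, normalized by the
  baseline level: `(drop_area / duration) / baseline`. Dimensionless and
  scale-free. The nightly **median Mvasoc** is the summary index.
* **PPGampCV** — the coefficient of variation (SD/mean) of PPGamp in a
  5-minute sliding window, stepped every 30 s. It requires no event rule and
  tracks Mvasoc closely, which is why it serves as the cross-device
  surrogate.

## The processing chain

1. **Beat detection** (`detect_beats`): local-maxima search on a lightly
   smoothed copy of the waveform (0.1-s moving average), minimum inter-peak
   distance `60/hr_max_bpm` (default 180 bpm), each peak paired with the
   minimum of the preceding inter-beat interval. Peak and trough positions
   are then refined on the raw waveform so smoothing does not bias the
   amplitude. Beats with amplitude below `prominence_frac = 0.3` of the
   rolling 90th-percentile amplitude are rejected — the 90th percentile
   (not the median) because secondary dicrotic maxima can outnumber true
   systolic peaks. The first peak has no preceding interval and is dropped.
2. **Gridding** (`build_amp_series`): amplitudes placed at peak times,
   linearly interpolated onto a 0.5-s grid (`grid_dt`); points farther than
   5 s from any beat are quality-masked. 0.5 s resolves both the 0.15 Hz
   filter band and the 15-s baselines with margin.
3. **Segmentation** (`segment_night`): consecutive 15-minute segments; a
   trailing remainder is kept for bookkeeping but flagged `short` and
   non-viable.
4. **Quality gate** (`gate_signal_loss`): a segment is non-viable when more
   than `max_masked_frac = 0.2` of it is masked or accelerometer magnitude
   exceeds `accel_thresh = 0.1` g on more than that fraction of points. This
   replaces the manual/visual screening used with clinical recordings so
   the pipeline is reproducible; both thresholds are config-exposed. Masked
   runs of at most 5 s are interpolated across.
5. **Capping and normalization**: values above the segment's 98th
   percentile are replaced by it; the segment is then divided by its 95th
   percentile (linear-interpolation quantile, computed over unmasked points
   only). After normalization the signal is dimensionless and any constant
   sensor gain cancels.
6. **Detrend + respiratory filter** (`detrend_and_filter`): least-squares
   line removed, then a zero-phase (forward-backward) 4th-order Butterworth
   low-pass at 0.15 Hz removes respiratory amplitude modulation. Zero phase
   is essential: a causal filter would shift event timing and corrupt both
   the 15-s baselines and the cross-device lag estimate. The pre-detrend
   mean is stored as `level` and restored before event detection and CV,
   because relative drops and CV are meaningless around a zero-mean signal.

## Event detection and its free parameters

A vasoconstriction event is a *significant* reduction below the preceding
15-s baseline. The exact statistical rule used with the original clinical
index is not public; here the rule is: trigger when the signal falls below
`baseline * (1 - depth_thresh)` with `depth_thresh = 0.15`, walk the onset
back to the last crossing of the baseline, and end at the first return to
baseline; events shorter than `min_dur_s = 3` s are discarded. The onset
walk-back matters: triggering alone would clip the early part of the
excursion and bias Mvasoc low (for a triangular dip, by nearly half).
`depth_thresh` and `min_dur_s` are the pivotal free parameters and both are
exposed in every interface. Detected event counts and Mvasoc magnitudes
shift with them; correlation-based conclusions (the validation surfaces)
are insensitive over a reasonable range.

Closed forms used as oracles: a rectangular dip of depth `d` on baseline
`b` has Mvasoc `d/b`; a triangular dip has `d/(2b)`.

## Cross-device alignment

The wrist and finger recorders run on independent clocks with an unknown
offset within ±30 s. Per segment, the normalized cross-correlation is
evaluated at every 0.5-s lag in ±30 s and the lag of maximum positive
correlation wins; ties break toward the smallest |lag|, a lag exactly at
the window edge is flagged (the true lag may lie outside), and a pair with
no positive correlation at any lag is excluded. Both inputs must first pass
an autocorrelation check that they carry serial structure at all. Because
K ≈ 60 lags are examined, the white-noise band is Bonferroni-adjusted,
`qnorm(1 - 0.025/K)/sqrt(N)`: with a plain per-lag 1.96/sqrt(N) band, white
noise would *pass* the check about 95% of the time, which would defeat its
purpose.

One subtlety found the hard way: the two amplitude series start at their
respective first detected beats, so their grids are offset; the lag search
must subtract that offset, not add it, or every recovered lag is biased by
twice the first-beat time difference.

## Validation analyses

* **Within-device** (`within_device_report`): per viable segment, the
  Mvasoc channel (each event's value held over its interval, zero
  elsewhere — `zero_fill`; an `event_only` mode restricts pairs to points
  inside events) is paired with the segment's PPGampCV on the 30-s grid and
  correlated (Pearson by default, Spearman via config). The *overnight*
  r pools the pairs of all included segments; the *peak* r is the best
  per-segment r among segments with at least 10 pairs.
* **Across-device** (`across_device_report`): finger vs aligned-wrist
  PPGampCV per segment, including a pair only when **both** devices
  detected at least 3 events in that segment, alignment succeeded, and at
  least 10 paired CV points exist. Exclusions are bookkeeping only: they
  never change an included segment's r.
* **Nightly medians** (`nightly_medians_regression`): OLS of median Mvasoc
  on median PPGampCV across nights.

No multiple-testing correction is applied, matching per-night reporting
practice; treat per-segment p-values descriptively.

## The synthetic world

No clinical recordings ship with this package, so every claim is tested on
a generator (`simulate_night`) whose defaults are the stated world:

* 55 bpm mean pulse with 3 bpm beat-to-beat jitter; an asymmetric pulse
  template (sharp systolic lobe plus a smaller dicrotic lobe) normalized to
  unit peak-to-trough;
* respiration at 0.25 Hz modulating amplitude by 10%;
* 40 vasoconstriction events/hour (about 10 per 15-minute segment, the
  order of magnitude reported for nocturnal recordings), fractional depths
  ~N(0.35, 0.12) truncated to (0.05, 0.85), durations ~N(20 s, 8 s)
  truncated to (5, 60) s, raised-cosine onset/recovery (a rectangular test
  mode exists because it admits closed-form Mvasoc);
* a slow within-night activity cycle (period 5400 s, the ~90-min
  sleep-cycle timescale; fractional modulation 0.5, random phase) that
  redistributes event density and scales depths without changing the
  expected count. Real nights show exactly this kind of within-night
  waxing and waning of vasomotor activity; without it the Mvasoc/PPGampCV
  within-night correlation would be near zero by construction, which no
  real recording shows;
* device asymmetry: finger gain 2, 2% noise, 100 Hz; wrist gain 1, 5%
  noise, 25 Hz, plus an accelerometer channel, motion-artifact bursts
  (2/hour) and a 5-minute sync pause at the end of every hour;
* a wrist clock offset (`clock_lag`, default −8 s) implemented as a pure
  delay of the shared drive.

What the generator does **not** emulate: non-stationary heart-rate trends,
arrhythmia, waveform morphology changes with vasomotor state, baseline
wander, colored sensor noise, or device gain drift. A green test therefore
establishes that the pipeline recovers what this model injects — not that
it is robust to every artifact of real wearables.

## Acceptance checks and compute scaling

The acceptance suite asserts: closed-form Mvasoc within 5%; CV correctness
(constant → 0, scale invariance to 1e-12, the two-point hand oracle
0.7071); preprocessing invariants (cap/normalize percentile identities,
ramp removal below 1e-6 of range, filter gain ≥ 0.95 at 0.05 Hz and ≤ 0.10
at 0.30 Hz); lag recovery within one grid step in ≥ 95% of 100 seeded
paired simulations; a 20-night cohort in which nightly median Mvasoc and
PPGampCV correlate at r ≥ 0.7 and the within-device overnight correlation
is positive and significant in ≥ 90% of nights; across-device overnight
correlation positive and significant in every simulated paired night with
the 3-event rule enforced; a 5% type-I error for `pearson_with_p`
(1000 reps, n = 100); and byte-identical pipeline reruns under a fixed
seed.

Sizes the criteria do not fix were chosen once for a 1-CPU budget and not
revisited: 900-s (single-segment) pairs for lag recovery, 2-hour nights for
the 20-night cohort (wristband device, the device of the longitudinal
analyses) and for the paired-night runs, 1-hour nights for the determinism
rerun. Replicate counts stated by the criteria (100 simulations, 20 nights,
1000 replicates, n = 100) are used verbatim.

## Numerical choices and edge cases

* Quantiles are linear-interpolation (R type 7) everywhere.
* The Butterworth design (bilinear transform) reproduces the reference
  implementation's coefficients to 1e-9; filtering uses odd-reflection
  padding, and a segment too short for the padding is marked non-viable.
* An event running into a segment boundary or a masked run is truncated
  there and flagged; segments are processed independently.
* An event starting less than 15 s into a segment uses the available
  baseline prefix and is flagged `short_baseline`.
* A flatline or non-positive segment cannot be normalized and is marked
  `degenerate`, not an error.
* EDF has no missing-value encoding; masked samples are written at a
  digital sentinel (−32768; data occupy −32767..32767) and the true sample
  count rides in the reserved header field, so gap structure and length
  round-trip exactly. Non-integer sampling rates are rejected for EDF.
* With zero events a night's median Mvasoc is reported as `NA` and the
  night is retained.

## Known limitations

* The "significant reduction" rule is a declared default, not a
  reconstruction of the original clinical algorithm's supplement.
* Whether PPGampCV should be computed on the filtered or unfiltered
  PPGamp is not settled; both modes exist, filtered is the default.
* Per-segment correlation counts can legitimately differ between the
  within-device and across-device analyses (each applies its own inclusion
  rule), so their segment totals need not match.
* The simulator's respiratory modulation is strictly periodic; real
  respiratory rate wander would slightly blur the respiratory band edge.
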