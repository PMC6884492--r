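---
title: "Methods: remote gait asymmetry analysis from thigh-worn sensors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: remote gait asymmetry analysis from thigh-worn sensors}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(remotegait)
```

This vignette documents the models, parameter choices and numerical
decisions behind `remotegait`, and what the synthetic-data tests do and do
not establish.

## Signal model and sensing assumptions

One sensor per thigh, on the rectus femoris, records tri-axial
acceleration (default 31.25 Hz, ±16 g) and surface EMG (default 250 Hz).
Acceleration is expressed in g and includes the gravitational reaction, so
a vertically oriented, static thigh reads +1 g along its long axis. All
event logic operates on the cranial-caudal (CC) projection; event times
therefore carry the accelerometer's ~32 ms sample resolution (contact
crossings are linearly interpolated between samples). Accel and sEMG
streams are aligned on their shared time base; sub-sample offsets between
the two modalities are ignored at this resolution.

## Anatomical calibration

* **CC axis** — mean acceleration over a quiet standing trial, normalized.
  Guards: per-axis SD ≤ 0.05 g (motion), mean norm in [0.8, 1.2] g
  (bad gravity estimate). The proximal direction is taken anti-gravity,
  assuming an upright thigh during the trial.
* **AP axis** — first principal component of the acceleration projected
  onto the plane orthogonal to CC, per 4-s window (or per bout in the
  stride-analysis stage, where continuity across a bout matters more than
  window-level adaptivity). PCA is sign-ambiguous; we pick the sign that
  makes the AP channel's skewness non-negative and inherit the previous
  window's sign when |skewness| < 0.1. This rule is deterministic and
  continuity-preserving; the original platform's exact sign convention is
  not public, so this is a documented substitute. Windows with transverse
  variance below 1e-6 g² are flagged axis-indeterminate and fall back to
  the previous frame (or a deterministic default axis at the start).
* **ML axis** — CC × AP, giving a right-handed orthonormal triad; the
  projection preserves per-sample vector norms to numerical precision.

## Walking-bout identification

Windows are 4 s, non-overlapping, aligned to the start of the common time
span; a trailing partial window is discarded (partial windows are never
analyzed). Six canonical features are always computed (25th CC quantile,
CC–AP cross-correlation, bilateral CC correlation, AP skewness, AP power
fraction below 0.25 Hz, AP median; each averaged over legs where
applicable); the registry accepts additional features. Zero-variance
channels yield correlation features of 0 with a flag rather than NaN.

Feature screening uses the two-class, one-feature Davies–Bouldin index
`(S1 + S2) / |m1 − m2|` with mean-absolute-deviation dispersions and
centroid distance — the simplest faithful instantiation for univariate
screening; features below the threshold (default 2) are kept, ordered by
index. Coincident class means score +Inf and are never selected.

The classifier is a soft-margin Gaussian-kernel SVM trained by a
Platt-style SMO solver written for this package (no SVM library is
assumed): C = 1, kernel width from the median-squared-distance heuristic
on standardized training features, tolerance 1e-3, deterministic
second-choice fallbacks so a fit is bit-reproducible for identical input.
Posteriors come from a Platt sigmoid fitted to the training decision
values with smoothed targets. Features are standardized with statistics
estimated on training data only; in leave-one-subject-out validation both
the standardization and the Davies–Bouldin selection are re-run inside
each fold, which the test suite verifies with a poisoning check
(corrupting a held-out subject's features must not change that fold's
model). When a fold's selection is empty — possible on shuffled-label or
degenerate data — the fold falls back to the single smallest-index feature
instead of aborting, so pooled metrics remain defined; the user-facing
`select_features()` still raises an error in that case.

The operating point follows the published platform: windows labeled
walking with posterior ≥ 0.8 (the ROC point closest to (0, 1) in the
original study) are merged; runs of ≥ 2 consecutive windows (≥ 8 s) form
walking bouts. Bouts containing clipped samples — ≥ 3 consecutive samples
within 1% of a rail on any channel; the original report removed clipped
bouts without stating its criterion — are dropped.

## Stride segmentation

Cadence per bout and leg comes from a Welch PSD (Hann window, 50%
overlap, 4-s segments, 8× zero padding, per-segment mean removal) of the
CC channel: `f_stride` is the strongest local maximum in the physiologic
0.5–1.4 Hz band, `f_step` the strongest in [1.5, 2.5]·`f_stride` (the
constraint suppresses harmonic confusion). A peak must exceed 3× the
median in-band power computed with bins within ±0.3 Hz of the peak
excluded — the exclusion matters because a 4-s Hann mainlobe spreads
substantial leakage across the narrow stride band — otherwise the bout is
skipped with a cadence error (this is what rejects non-gait signals that
slip through classification).

Events use a bank of 4th-order Butterworth lowpass filters (5 Hz,
`f_step`, `f_stride` cutoffs) applied forward-backward for zero phase;
filter order and family are implementation choices (only "lowpass
filters" is published). Foot off is a local minimum of the
f_stride-filtered trace at least 0.05 g below its mean (the depth guard
rejects flat signals), confirmed by a minimum of the f_step-filtered trace
within ±0.25/`f_step`; with CC proximal and +1 g standing value, the swing
trough is a minimum — the published figure marks both extremum types
without binding them, so the choice is fixed here and configurable. Foot
contact is the first upward 1 g crossing of the 5 Hz-filtered trace after
each foot off; cycles without a crossing before the next foot off are
discarded. Strides run contact-to-contact per leg; retention requires
stride time in [0.91, 1.57] s and duty factor in [0.44, 0.73], and a bout
enters the analysis only with ≥ 2 retained strides **per leg** (whether
the published two-stride minimum is per leg or pooled is ambiguous; per
leg is the stricter reading).

## Asymmetry analysis

The sEMG envelope is band-pass 20–100 Hz (cascaded 4th-order Butterworth
high/lowpass), full-wave rectified, then lowpass 6 Hz, all zero-phase.
Acceleration channels are lowpass filtered at 6 Hz. Each retained
stride's channels are linearly interpolated onto a 101-point grid
(0–100% of the gait cycle, endpoints inclusive), sample 0 at foot
contact, stance/swing boundary at each stride's own duty factor (not a
fixed 60%).

"Mean normalized sEMG" needs a normalization constant the original text
delegates to a reference: free-living data offer no maximal-contraction
trial, so envelopes are normalized per leg per day by the 95th percentile
of the envelope over all retained strides — robust to spikes and
symmetric across legs. Discrete indices (duty factor, stance sEMG, swing
sEMG) use `|I − H| / |H|`; a zero healthy-leg value makes the index
undefined and drops the record with a log entry. Waveform indices use
`(1 − r)/2` on the ensemble means over **all** retained strides of the
bout (long bouts are not chunked into 8-s pieces; the published
per-8-s-bout phrasing is ambiguous and chunking would only add variance).
The composite is the arithmetic mean of the seven indices. Outlier
records are removed per subject when the composite falls outside
median ± 1.5·IQR (no criterion is published; records are kept or dropped
whole, and subjects with fewer than 4 records pass through).

## Synthetic data: what it emulates

The generator states a world in which the published event definitions are
exactly true, then asks whether the pipeline recovers it:

* **CC cycle.** A continuous stance-hump / swing-trough shape (hump
  0.20 g, trough 0.40 g, trough skew cascade 0.65→0.20) truncated to 4
  stride harmonics with Lanczos smoothing. For this family the first
  upward zero after the trough of the ideal shape sits at the stride
  boundary, so the "detected" duty factor equals the phase of the
  fundamental's minimum; the shape's breakpoint is root-solved at
  simulation time so that this phase equals the requested duty factor,
  and the cycle is rotated so the 1 g contact crossing sits at phase 0.
  This solve is part of the construction (it makes the injected ground
  truth self-consistent with the event definitions), not a calibration
  against test outcomes. The family reaches duty factors in (0.40, 0.80)
  — slightly narrower than the nominal physiologic range, and amply
  covering the retention bounds [0.44, 0.73]; a solution must also keep a
  ≥ 0.06 g stance peak so sensor noise cannot suppress the contact
  crossing.
* **Asymmetries.** The injured leg gets its own duty factor
  (`df_ratio` × healthy), a scaled stance sEMG burst
  (`emg_amp_ratio`), and AP-waveform decorrelation: a pure 3rd stride
  harmonic — exactly orthogonal to the two-harmonic AP base over the
  cycle — mixed with a weight root-solved on the 101-point grid so the
  expected `(1 − r)/2` equals the requested value. Decorrelation goes
  into AP, not CC, so injected pattern asymmetry does not disturb
  CC-based event detection.
* **sEMG.** Burst-modulated band-limited (20–100 Hz) unit-variance noise;
  activation has an early-stance burst (0.35 mV) and a larger early-swing
  burst (0.70 mV, keeping the 95th-percentile normalization anchored in
  swing) over a 0.05 mV baseline.
* **Noise and artifacts.** White accelerometer noise (default 0.03 g,
  a realistic MEMS figure at this bandwidth), optional injected clipping
  runs at the 16 g rail, per-leg sensor mounting tilt (default 8°).
* **Other activities.** Sitting, standing and lying are static postures
  with slow wobble; stairs and crutch gait reuse the cycle waveform with
  a smoothed random-rate phase (irregular stride timing), slower cycles,
  smaller amplitude, and — for swing-through crutching — both legs in
  phase instead of half a cycle apart. These choices make the canonical
  features informative but imperfect in physically motivated ways.

Everything is seeded (`withr::with_seed`), so identical configurations
are bit-reproducible.

**What a green test does not establish.** The generator contains no
musculoskeletal forward model: no impact transients, soft-tissue
artifact, turning, slopes, or pathological compensation strategies, and
its activity classes are far cleaner than free-living life. Green
recovery tests validate the pipeline's contracts — that the published
definitions are implemented correctly and recover a world in which they
hold — not clinical performance on real recordings.

## Numerical choices and degenerate inputs

* Butterworth designs via bilinear transform, validated against frozen
  reference coefficients at 1e-9; zero-phase filtering uses odd edge
  extension (3× filter length).
* Welch spectra refine peaks by parabolic interpolation on log power,
  giving cadence resolution well below the ±0.05 Hz test tolerance.
* Recordings shorter than 4 s yield zero windows (not an error); a day
  with no qualifying bouts yields a zero-stride summary (one study
  patient had exactly this outcome).
* Correlation of zero-variance channels is 0 + flag in features, and an
  error (record dropped) in waveform asymmetry, where a zero-variance
  ensemble mean signals a degenerate bout rather than symmetric gait.
* Group summaries check normality per group (Kolmogorov–Smirnov against
  the fitted normal), then one-way ANOVA with Tukey post-hoc, or
  Kruskal–Wallis when normality fails; effect sizes are absolute Cohen's
  d with the qualitative bands weak < 0.25 ≤ small < 0.5 ≤ medium <
  1.0 ≤ large; α = 0.05; no multiplicity correction beyond Tukey.
  Groups with n < 2 are excluded and reported.

## Known limitations

* CSV is the only on-disk dialect (long format plus JSON metadata
  sidecar); no HDF5 reader is available in the supported dependency set.
* The 152-feature bank of the original platform is represented by its six
  selected features plus an extensible registry, not reproduced.
* Gyroscope-aided calibration and event detection, knee kinematics, and
  co-contraction indices are out of scope.
* The simulator's duty-factor domain is (0.40, 0.80); values below 0.40
  cannot be realized by the waveform family (and are rejected by the
  stride constraints anyway).
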