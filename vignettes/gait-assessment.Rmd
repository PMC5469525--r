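---
title: "Acceleration-based gait assessment: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Acceleration-based gait assessment: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(gaitscore)
```

## The problem and the model

Clinical gait assessment of children with cerebral palsy is usually
observational (GMFCS/GMFM-style scales), which is time-consuming and
partly subjective. This package implements an instrumented alternative:
three inertial measurement units — one on the lower trunk near the
body's centre of mass, one on each thigh — record tri-axial
acceleration and angular velocity at 100 Hz during a short straight
walk of about 30 strides, and the pipeline condenses the recording into
a 0–100 score of how closely the subject's gait acceleration pattern
resembles that of healthy adults.

The model rests on three assumptions worth stating explicitly:

* **The waist AP signal is step-periodic with impact peaks.** During
  steady walking the trunk behaves approximately like an inverted
  pendulum, so each heel strike produces a positive peak in the
  anterior–posterior acceleration at the waist. Segmentation relies
  entirely on this; gait without discernible contact peaks (severe
  shuffling, non-straight walking) is out of scope.
* **Healthy gait acceleration waveforms are stereotyped across
  subjects** on six of the nine channels (SI and AP at waist and both
  thighs), which justifies a single reference waveform (the CGG) and
  reference feature values. The ML channels are low-amplitude and
  subject-specific and are excluded by the channel-stability analysis
  (`channel_stability()`, threshold mean pairwise r ≥ 0.75).
* **Orientation drift is negligible over a 30-stride walk.** The
  orientation filter is plain gyroscope integration from a static
  initialization; there is no magnetometer fusion or Kalman/Madgwick
  correction. Over ~40 s with consumer-grade gyros this is adequate;
  for longer recordings it would not be.

## Pipeline stages and their tunables

All tunables live in `gait_config()`; the table lists the ones that
matter, with units and defaults.

| parameter | default | meaning |
|---|---|---|
| `M` | 100 | phase points per normalized stride |
| `filter_order`, `filter_cutoff` | 50, 20 Hz | FIR low-pass design; body-movement energy lies below 20 Hz |
| `channel_threshold` | 0.75 | mean inter-subject correlation required of a representative channel |
| `end_trim` | 2 cycles | gait initiation/termination transients dropped per end |
| `n_aggs`, `cycles_per_agg` | 4, 3 | AGGs per subject, cycles per AGG |
| `peak_threshold_sd` | 0.2 | heel-strike peaks must exceed mean + 0.2 sd of the AP-W series |
| `refractory_frac` | 0.3 | minimum peak spacing, in step periods |
| `symmetry_band` | 0.3–0.7 | step-lag search band for As, as fractions of M |
| `gamma` | 1 | grey distinguishing coefficient |
| `weights` | 0.2 × 5 | feature weights in the correlation degree |
| `h_cap` | 1e6 | harmonic-ratio sentinel when odd energy vanishes |

### Preprocessing

The initial quaternion comes from the 5 s standing phase: the mean
static accelerometer vector fixes the sensor's tilt (it must be within
20% of g in magnitude, otherwise the sensor was moving or is
miscalibrated and an error is raised). Heading is unobservable from
gravity, so the sensor's declared forward axis — part of the placement
metadata, reflecting the axis-alignment step done when mounting — is
mapped to global AP after projecting off the vertical. Integration uses
the exact per-sample exponential map (rotate by ω·dt, renormalize);
at 100 Hz the first-order scheme's error is far below the sensor noise
floor. Gravity is deliberately **not** subtracted: the SI channels keep
their +g mean, and every downstream statistic that would be biased by a
constant offset (Pearson, variance ratio, harmonics, autocorrelation)
is location-adjusted or computed on mean-centered cycles.

The low-pass filter is a Hamming windowed-sinc design of the stated
order, rescaled to exactly unit DC gain, and applied forward–backward.
Zero-phase application is a deliberate choice: a causal FIR of order 50
would delay every peak by 25 samples and bias heel-strike timing; the
forward–backward pass keeps peak positions unbiased at the cost of a
squared magnitude response (which only sharpens the cutoff).

### Segmentation

The step period is the lag of the first local autocorrelation peak
(biased estimator, normalized; search band 0.4–2.0 s) exceeding 0.2; if
no such peak exists the series is declared aperiodic and segmentation
refuses to guess. Peaks must be sliding-window maxima over 0.75 step
periods *and* exceed mean + 0.2 sd of the series; ties on plateaus keep
the first sample; detections closer than 0.3 step periods keep the
higher peak. Strides pair alternate events without overlap
(events 1→3, 3→5, …), anchored at the first detection — overlapping
strides would share two of their three cycles with their neighbours and
destroy the independence the variance ratio assumes. "Several cycles at
the start and end moments" are removed as exactly two per end, a
compromise between discarding initiation/termination transients and
keeping ≥ 20 of 30 strides; the subsequent duration rule (> 2× or
< 0.5× the mean of the others, applied iteratively, worst offender
first, until stable) handles missed or spurious contacts.

### Cycle normalization

Cycles are resampled by linear interpolation with samples mapped to the
closed unit interval (`seq(0, 1, length.out = L)` onto
`seq(0, 1, length.out = M)`). The half-open alternative (sample i at
phase (i−1)/L) needs extrapolation beyond the last sample whenever
M > L at the tail, and linear extrapolation can overshoot the observed
range; the closed mapping is exact on affine signals, is the identity
when L = M, and never leaves the data's range. Each channel is then
mean-centered (`center_channels`, default on) so that SI's gravity
offset does not dominate averages and comparisons; Pearson and the
variance ratio are unaffected by centering, and the harmonic and
symmetry statistics require it anyway.

### Features

* **P** sums the six per-channel Pearson correlations between AGG and
  CGG; constant channels (pathologically flat signals) contribute 0
  with a warning rather than NaN.
* **V** sums Hershler–Milner variance ratios; the per-channel ratio is
  within-phase variance over the AGG's three source cycles, normalized
  by M(n−1), divided by total variance about the grand mean, normalized
  by Mn−1. All-identical values give 0 by convention.
* **N** counts strict sign changes of the first difference per channel;
  runs of exactly equal adjacent samples are compressed first, so a
  plateau counts as at most one extremum.
* **H** is computed per waist channel from the DFT of the
  stride-normalized waveform: harmonic n is n cycles per stride, even
  harmonics (2, 4, …, 20) are step-frequency content, odd harmonics
  asymmetric content. When the odd sum is below 1e-12 the ratio is
  unbounded and capped at `h_cap` with a warning — a finite sentinel
  keeps the grey normalization usable.
* **S**: an AGG channel holds exactly one period of the gait pattern,
  so the step-regularity autocorrelation is computed on the stride
  tiled twice and normalized at lag zero; As is the maximum over the
  step-lag band, capped at 1. Computing the unbiased estimator on the
  bare single stride instead would shrink the averaging window to M/2
  samples at the step lag, inflating the statistic's variance enough
  that even white noise averages an As above 0.3; on the doubled stride
  the same estimator is well-behaved, returns exactly 1 for
  half-stride-periodic channels, and preserves the asymmetry ordering.

### Grey relational scoring

Training takes the 4·m AGG-level feature rows of m healthy subjects.
Xref is the column mean; the comprehensive generating transform maps a
value x to x/Xref below the reference and 2 − x/Xref above it, so 1 is
"at the healthy mean" and both directions of deviation look alike;
values beyond 2·Xref go negative and are intentionally not clamped —
they simply produce large deviations. R is the column mean of the
normalized training matrix, and minAbs/maxAbs are the global extrema of
|Z − R| over the training rows.

Two numerical decisions deserve attention:

* **The ξ clamp.** A test row's deviation can fall below the training
  minAbs, which would push the raw coefficient above 1 and the score
  above 100, contradicting the definition of the correlation degree as
  lying in [0, 1]. The denominator therefore floors |Z − R| at minAbs;
  the raw unclamped coefficients are returned alongside (`xi_raw`) for
  audit. With the clamp, a test set whose normalized rows equal R
  scores exactly 100, and every finite input scores within [0, 100].
* **Non-monotonicity in raw features.** Because the two-branch
  transform folds both sides of Xref below 1 while R (a mean of
  deviations) sits below 1, the score peaks at x = R·Xref, not at
  x = Xref: moving a feature from Xref toward R·Xref *raises* the
  score slightly before the decline begins. The score is monotone in
  the normalized deviation |Z − R|, which is the quantity the model
  actually compares; users inspecting per-feature contributions should
  read the `Z` and `xi` matrices of the assessment object, not raw
  feature offsets from Xref.

Degenerate cases: a zero column mean in training is an error (the
transform divides by Xref); maxAbs = 0 (all training rows identical)
yields 0/1 coefficients with a warning; fewer than four test AGGs are
averaged over the available rows with a warning.

## The synthetic generator

`generate_recording()` exists so that every stage — including the
quaternion frame transform — can be validated end to end without
recorded data. The stride template is an analytic harmonic construction
fit to the landmark structure of healthy gait acceleration: waist AP
peaks at 0% and ~50% (the two heel strikes) with loading valleys after
each, waist SI foot-flat peaks near 6% and 55% with slow regions at
25–40% and 75–90%, thigh SI support bursts mirrored at half stride, and
antisymmetric thigh AP trends. It is *not* data-derived. Pathology is
injected at the waveform level:

* **asymmetry** a: smooth left/right amplitude modulation (1 ± a/2)
  plus a right-step timing delay of 0.1·a stride — lowers S (and P);
* **tremor_amp**: band-limited 6–15 Hz ripple, scaled per channel —
  the band lies below the 20 Hz cutoff so it survives preprocessing and
  is visible to N and H;
* **cycle_noise**: per-stride duration jitter plus smooth per-cycle
  waveform perturbations — raises V.

Sensor realism: the global-frame signal (gravity added on SI) is
rotated into fixed, deliberately tilted per-sensor frames with known
orientation and zero angular velocity, so preprocessing must undo a
genuine tilt and the round trip is exact to numerical precision. A 6 s
quiet-standing lead-in precedes the walk; amplitude ramps over the half
stride before the first heel strike and a cosine deceleration taper
after the last recorded contact keep the signal continuous without
creating impact peaks outside the ground-truth event list.

The generator's healthy defaults (0.93 strides/s, 30 strides) match
self-selected adult walking; the severity ladder (healthy → mild →
moderate → severe) moves all three pathology parameters up and the
stride frequency down in engineering-chosen ranges that claim ordinal
meaning only. What the generator does **not** emulate: real tremor
spectra and their coupling to gait phase, scissor-gait kinematics,
turning, sensor mounting slippage, gyroscope noise and drift, and the
inter-subject waveform variability of real cohorts (healthy synthetic
subjects share one template). Passing tests therefore demonstrate
algorithmic correctness and the intended qualitative orderings, not
clinical validity on real recordings.

## Problem sizes used by the tests

The test suite and the acceptance script run entirely on synthetic
data at deliberately modest sizes: recordings of 30 strides at 100 Hz
(~4,000 samples), training cohorts of 3–4 healthy subjects, assessment
cohorts of 4–5 subjects per severity level with 20 seeded replicates
for the ordering checks, 20-point single-parameter ladders for the
monotonicity correlations, and 100-instance oracle sweeps for the
feature and grey-model formulas. These sizes were chosen as the
smallest at which the stochastic properties under test are stable.

## Known limitations

* Left/right labeling of alternating peaks is not observable from the
  waist AP signal alone; stride parity is anchored at the first
  detected event, so "left" and "right" in downstream output are
  conventional, not anatomical.
* Scores are relative to the training cohort; no mapping to GMFCS or
  any clinical scale is provided or implied.
* The harmonic ratio of a very smooth, nearly noise-free gait is
  numerically large (odd energy near zero) and dominates Xref's H
  column; with real, noisier data this is not expected, but users
  fitting models on synthetic healthy cohorts should be aware that H's
  reference value is large and its normalized deviations correspondingly
  compressed.
* Walks much shorter than ~15 strides cannot supply the 12 pruned
  cycles four AGGs require; the pipeline degrades to fewer AGGs with a
  warning.
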