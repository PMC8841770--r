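---
title: "Wavelet-domain motion-artifact removal for thoracic EIT: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Wavelet-domain motion-artifact removal for thoracic EIT}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(eitclean)
```

## Signal model and procedure

A single EIT channel is modelled as an additive mixture
`x_measured(n) = x_breathing(n) + x_motion(n)`: a quasi-periodic
respiratory/cardiac oscillation plus one of three motion-artifact classes
(slow baseline drift, a persistent step-like baseline shift, or transient
spikes). The multilevel discrete wavelet transform with the Daubechies db8
filter bank (16 taps, 8 vanishing moments) maps the signal to one
approximation band `a_L` and detail bands `d_1` (finest) … `d_L`. At a
20 Hz frame rate the dyadic bands are, approximately:

| band  | frequency range (Hz) | content at defaults        |
|-------|----------------------|----------------------------|
| a_6   | 0 – 0.156            | baseline drift             |
| d_6   | 0.156 – 0.3125       | respiratory fundamental    |
| d_5   | 0.3125 – 0.625       | respiratory harmonics      |
| d_4   | 0.625 – 1.25         | cardiac fundamental        |
| d_1–d_4 | 0.625 – 10         | spike transients, step edges |

Each artifact class is handled by manipulating the coefficients in which it
concentrates, followed by synthesis:

* **Drift** (`remove_baseline_drift`): zero `a_6`, rebuild. This is a
  linear projection (an equivalent high-pass at `fs/2^(L+1)` ≈ 0.156 Hz).
* **Steps** (`detect_steps` / `correct_steps`): coefficients of `d_1` with
  magnitude above the robust threshold `tau = k * MAD(d_1)/0.6745` mark
  abrupt changes; candidates are mapped back to sample indices, merged
  within `min_event_separation`, classified step-vs-spike by persistence of
  the median offset across the change point, and steps are corrected by
  subtracting the offset estimate from all samples at and after the change
  point.
* **Spikes** (`remove_spikes`): coefficients in levels 1–4 whose magnitude
  exceeds the per-level robust threshold are zeroed
  (`spike_mode = "threshold_local"`), or the whole levels are zeroed
  (`"zero_global"`).

`clean_channel` composes the stages (default order drift → step → spike)
and `clean_frames` applies the composition independently to each of the
208 channels of a frame series.

## Tunable parameters

All knobs live in `cleaning_config()`:

* `drift_level = 6` — approximation depth whose band is removed; at other
  sampling rates `drift_level_for(fs, f_cut)` computes
  `floor(log2(fs/(2 f_cut)))`.
* `step_detection_level = 1` — abrupt changes are sharpest in the finest
  band, which also gives the best temporal resolution (2 samples per
  coefficient).
* `spike_levels = 1:4` — covers 0.625–10 Hz; deeper levels would start
  eating the respiratory band.
* `threshold_k = 5` — the usual conservative outlier multiplier on the
  MAD-based sigma estimate (0.6745 converts MAD to a Gaussian sigma). At
  `k = 5` the false-trigger probability per Gaussian coefficient is below
  1e-6, which is what makes artifact-free records pass through unmodified.
* `step_offset_window = 40` samples (2 s at 20 Hz) — median window for the
  offset estimate. The persistence check is additionally evaluated over
  twice this window whenever it fits inside the record, because 40 samples
  is half a default breathing period and the median of a half cycle of the
  oscillation is phase-dependent (bias up to ≈ 0.3 signal units), whereas a
  full cycle is nearly unbiased; the offset estimate is taken from the
  widest fitting window.
* `min_event_separation = 40` samples — candidate detections closer than
  this are merged, keeping the largest |d_1| (one event per physical
  movement).
* `spike_mode = "threshold_local"` — default, because globally zeroing
  d_1–d_4 at 20 Hz deletes the ~1 Hz cardiac component living in d_4;
  `"zero_global"` is retained as an option for comparison, and its cardiac
  cost is asserted in the test suite.

## Boundary handling

Three extension modes are implemented for the decomposition itself:
`"symmetric"` (half-sample reflection, the default), `"antireflect"`
(point reflection about the boundary value, first-derivative continuous)
and `"periodic"` (circular, exactly energy-conserving for even lengths).
All three reconstruct to machine precision.

Reflection of an oscillation at an arbitrary phase produces a derivative
kink at the record edge, and the resulting leakage into `a_6` is the
dominant error of plain wavelet detrending: it is concentrated in the
outermost few hundred samples. The drift stage therefore first extends the
record at each end by `filter_length * 2^L` samples using a local linear
trend (least squares over the outermost two periods) plus a periodic tiling
of the detrended residual, with the period taken from the periodogram peak
in the 0.1–0.5 Hz respiratory band. For a quasi-periodic breathing signal
this padding is value- and slope-continuous, so the drift estimate stays
clean up to the edges; when no prominent respiratory peak exists (e.g. pure
noise, constant records) the stage falls back to the bare reflective
transform. Step detection ignores candidates within one filter support of
either record edge for the same reason: coefficients there respond to the
extension, not to data.

## Numerical and design choices

* **Perfect reconstruction** is asserted at 1e-8 relative maximum error
  (measured: machine precision) over random signals of length 32–5000, and
  the filter-bank implementation is checked against an independent
  plain-loop convolution oracle at 1e-10 on length-64 inputs.
* **Coefficient indexing** follows the convention that `d_1` is the finest
  level. The map from a level-1 coefficient index to a sample index,
  `sample = 2 i - delay`, uses a delay calibrated once per wavelet from the
  filter bank's own response to an ideal step; this keeps step localization
  within ±1 sample in the tests rather than the ±8 guaranteed by the
  half-support argument.
* **Step correction after drift removal**: when the drift stage has already
  run, the residual step artifact is the high-pass projection of an ideal
  step, so after subtracting the offset the drift projection is re-applied
  (projection is linear, so this equals subtracting a projected step
  template). This keeps the composed pipeline nearly idempotent, which is
  asserted as PRD < 0.05 between a cleaned record and its re-cleaned
  version.
* **Step-vs-spike threshold** reuses the d_1 threshold `tau` in signal
  units (one tuning knob, `threshold_k`).
* **PRD convention**: `prd()` is the ratio of sums of squares × 100, with
  the classical square-root variant behind `root = TRUE`. `r_squared()` is
  the plain variance ratio about the reference mean — deliberately not the
  regression coefficient of determination, and not clipped, so values
  above 1 (an artifact adds variance) are meaningful.
* **Degenerate inputs**: all-constant records yield an empty detection
  table (not an error); all-zero records pass every stage unchanged;
  non-finite samples are rejected with the offending frame/channel named.
* **Ties**: within a merged detection group the largest-|d_1| candidate
  wins; equal magnitudes resolve to the earliest sample.

## The synthetic generator

`simulate_breathing()` produces
`x[n] = 1/2 (0.9 sin(2π·0.25 t) + 0.2 sin(2π·1.0 t)) + λ g[n]` at
`fs = 20` Hz for 5,000 samples — a respiratory fundamental, a cardiac
component and white Gaussian noise. The noise amplitude λ defaults to
0.02: small enough that the oscillatory structure dominates (≈ 26 dB SNR),
large enough that robust thresholds are exercised; the generator's
amplitude envelope (±0.55 noiseless) and component frequencies are
asserted spectrally in the tests. Artifact injectors are purely additive
(drift: linear ramp or low-frequency sinusoid; step: Heaviside; spikes:
seeded triangular pulses of width 3), so ground truth is always available
exactly.

What the generator does **not** emulate: respiratory rate variability and
apnoea, amplitude modulation, electrode-contact impedance changes (the
physical origin of real motion artifacts, which enter multiplicatively
through the sensitivity matrix rather than additively), correlated
multichannel noise, and device-specific filtering. Passing tests therefore
demonstrate correctness of the wavelet machinery and robust behaviour under
the stated additive model — not clinical performance.

## Imaging stage

The phantom imaging stage solves the 2-D unit-conductivity forward problem
with linear finite elements on a structured disk mesh (default 784
elements, 16 point electrodes, adjacent drive), assembles the sensitivity
matrix by the adjoint formula — which makes drive/measurement reciprocity
exact — and inverts with one-step Tikhonov regularization
(`alpha = 1e-3` relative to `trace(J'J)/n`), rasterized to the 32 × 32
circular-mask display grid. A consensus-trained reconstruction matrix of
the kind used clinically is intentionally out of scope; like-with-like
comparisons (contaminated vs cleaned vs artifact-free, all reconstructed by
the same B) are what the image metrics need, and a plain regularized
inverse keeps the stage fully self-contained. Image-level magnitudes are
therefore not comparable to values obtained with other reconstruction
algorithms.

The image-level study (`phantom_artifact_study`) modulates two circular
low-conductivity "lung" regions by the breathing waveform, injects drift or
step artifacts into the boundary voltages of every channel scaled by that
channel's breathing sensitivity, cleans channel-wise, and compares the
difference images at the breathing peak where the artifact expression is
largest against the first frame. 1,024 frames (51.2 s) are simulated — the
shortest record admitting the 6-level drift decomposition with margin —
and 5 noise seeds are used; these sizes keep the whole study to a few
seconds while leaving the conclusions unchanged under other seeds.

## Known limitations

* Offline batch processing only; no streaming variant.
* Step offsets estimated from medians assume the breathing statistics are
  comparable on both sides of the change point; offsets within two windows
  of a record edge fall back to the single-window estimate.
* The drift stage's periodic-trend padding assumes a detectable dominant
  respiratory period; records without one get plain reflective boundaries
  and correspondingly larger (but bounded and edge-localized) detrending
  error.
* Artifacts are modelled and removed additively; contact-impedance physics
  is not modelled.
* `zero_global` spike mode removes the cardiac band by construction; it
  exists for comparison, not for production use.
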