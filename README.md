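# eitclean

Wavelet-based detection and removal of motion artifacts in thoracic
electrical impedance tomography (EIT) recordings.

## The problem

Thoracic EIT monitors regional lung ventilation at the bedside by injecting
small currents between adjacent pairs of 16 chest electrodes and measuring
boundary voltages (16 injection patterns × 13 measurement pairs = 208
channels per frame, typically at 20 Hz). Long-term monitoring in the ICU is
routinely disturbed by three classes of motion artifact:

* **baseline drifting** — a slow additive trend, e.g. from a pulsating air
  mattress;
* **step-like shifts** — the baseline jumps after a postural change and does
  not return;
* **spike-like transients** — brief excursions that do return to baseline.

`eitclean` implements a discrete-wavelet-transform (DWT) framework that
detects and attenuates all three classes in one decomposition, plus the
simulation machinery, a linear difference-imaging stage on a 16-electrode
disk phantom, and the signal- and image-level quality metrics needed to
evaluate it end to end — for signal-processing researchers and EIT
methodologists who need a reproducible, testable reference pipeline.

## Method

Each channel x(n) is modelled as breathing signal plus additive artifact.
A multilevel DWT (Daubechies db8, 16 taps, 8 vanishing moments) splits x
into approximation coefficients a_L and detail coefficients d_1 … d_L; at
fs = 20 Hz, detail level *i* covers ≈ (fs/2^(i+1), fs/2^i] Hz. The three
artifact classes separate in this domain:

* **drift** lives in the level-6 approximation band (≤ 0.156 Hz): zeroing
  a_6 and rebuilding acts as a drift-free high-pass that preserves the
  respiratory band (0.2–0.5 Hz). Record edges are protected by a
  periodicity-aware padding of the signal before decomposition.
* **steps** are localized by finest-detail coefficients |d_1| above a
  robust threshold τ = k·MAD/0.6745 (k = 5); each change point is
  classified step-vs-spike by whether the difference of medians across the
  change point persists, and corrected by subtracting the estimated offset
  from all later samples.
* **spikes** are suppressed by hard-thresholding coefficients in detail
  levels 1–4; only above-threshold coefficients are zeroed, so
  sub-threshold physiology (notably the ~1 Hz cardiac component in d_4)
  passes through.

Difference images are reconstructed linearly as y = B(x_c − x_ref), where B
is a one-step Tikhonov-regularized inverse of the finite-element
sensitivity (Jacobian) matrix of a 2-D unit-disk phantom with 16
point electrodes in adjacent drive.

Quality metrics: `prd()` (percent root difference,
100·Σ(x−y)²/Σx²), `r_squared()` (variance ratio Σ(y−x̄)²/Σ(x−x̄)², which can
exceed 1), `image_error()` (Σ|A−B|/Σ|R|), `image_corr()` (2-D Pearson) and
`improvement_pct()` ((before−after)/before·100).

## Worked example

```r
library(eitclean)

cfg <- breathing_sim_config(seed = 1)          # 0.25 Hz + 1 Hz, fs 20, N 5000
sim <- simulate_contaminated(cfg, list(
  artifact_spec("drift", 1.0),                 # 0.02 Hz sinusoidal drift
  artifact_spec("step", 1.0, onset = 2501)     # baseline jump mid-record
))

res <- clean_channel(sim$contaminated, fs = 20,
                     config = cleaning_config(),
                     stages = c("drift", "step"))
res$events
#>   kind location support_start support_end    offset      stat
#> 1 step     2501          2501        2505 0.2026636 0.2616496

metrics_report(sim$truth, sim$contaminated, res$signal)
#> Signal quality before -> after cleaning
#>   PRD: 818.6349 -> 0.7743  (improved 99.91%)
#>   R^2: 9.1944 -> 1.0026  (improved 89.10%)
```

The step is localized at exactly sample 2501 and the cleaned signal agrees
with the artifact-free ground truth to a PRD below 1 (on the ×100 scale)
and a variance ratio within 0.3 % of unity. The full simulation study
(three scenarios, before/after metrics, report CSV + signal CSVs) is
regenerated by `run_repro_sim("out_dir", seed = 1)`, and a command-line
wrapper with `simulate` / `inject` / `clean` / `reconstruct` / `evaluate` /
`repro-sim` subcommands is provided in `inst/cli/eitclean.R`.

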