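#' Configuration for the simulated breathing signal
#'
#' The simulated single-channel EIT waveform is a half-scaled sum of
#' sinusoids plus white Gaussian noise:
#' `x[n] = 1/2 * sum_i mu_i sin(2 pi f_i n / fs) + lambda * g[n]`,
#' with a respiratory component (0.25 Hz, amplitude 0.9) and a cardiac
#' component (1 Hz, amplitude 0.2) by default, sampled at 20 Hz for 5,000
#' samples.
#'
#' @param components Two-column matrix (or coercible) of `frequency` (Hz) and
#'   `amplitude` (dimensionless) pairs. Every frequency must lie below the
#'   Nyquist rate `fs/2`.
#' @param noise_amplitude Standard deviation `lambda` of the additive Gaussian
#'   noise (default 0.02, i.e. the oscillatory structure dominates at roughly
#'   26 dB SNR).
#' @param fs Sampling rate in Hz (default 20).
#' @param n_samples Record length in samples (default 5000).
#' @param seed Integer RNG seed recorded in the config; all noise draws are
#'   reproducible from it.
#' @return An object of class `"breathing_sim_config"`.
#' @export
breathing_sim_config <- function(components = cbind(frequency = c(0.25, 1.0),
                                                    amplitude = c(0.9, 0.2)),
                                 noise_amplitude = 0.02, fs = 20,
                                 n_samples = 5000, seed = 1L) {
  components <- as.matrix(components)
  if (ncol(components) != 2L) stop("components must have 2 columns (frequency, amplitude)")
  colnames(components) <- c("frequency", "amplitude")
  if (any(components[, "frequency"] >= fs / 2)) {
    stop("component frequency at or above the Nyquist rate fs/2 = ", fs / 2, " Hz")
  }
  if (noise_amplitude < 0) stop("noise_amplitude must be nonnegative")
  if (n_samples < 1) stop("n_samples must be >= 1")
  structure(list(components = components,
                 noise_amplitude = noise_amplitude,
                 fs = fs, n_samples = as.integer(n_samples),
                 seed = as.integer(seed)),
            class = "breathing_sim_config")
}

#' Simulate the breathing-plus-cardiac test signal
#'
#' @param config A [breathing_sim_config()].
#' @return Numeric vector of `config$n_samples` samples (time `t = n/fs`,
#'   `n` starting at 0, so the noiseless signal starts at 0).
#' @examples
#' x <- simulate_breathing(breathing_sim_config(noise_amplitude = 0))
#' var(x)  # ~ (0.45^2 + 0.10^2) / 2
#' @export
simulate_breathing <- function(config = breathing_sim_config()) {
  stopifnot(inherits(config, "breathing_sim_config"))
  n <- config$n_samples
  t <- (seq_len(n) - 1) / config$fs
  x <- numeric(n)
  for (i in seq_len(nrow(config$components))) {
    x <- x + config$components[i, "amplitude"] *
      sin(2 * pi * config$components[i, "frequency"] * t)
  }
  x <- x / 2
  if (config$noise_amplitude > 0) {
    set.seed(config$seed)
    x <- x + config$noise_amplitude * stats::rnorm(n)
  }
  x
}

#' Parametric motion-artifact description
#'
#' Describes one injectable artifact of the three classes seen in clinical
#' thoracic EIT: slow baseline drift (linear ramp or low-frequency sinusoid),
#' a step-like persistent baseline shift, or a set of spike-like transients.
#'
#' @param kind `"drift"`, `"step"` or `"spike"`.
#' @param amplitude Peak artifact amplitude in signal units.
#' @param onset 1-based sample index at which the artifact starts (drift,
#'   step) — defaults: 1 for drift, 2501 for step.
#' @param shape Drift only: `"sinusoidal"` (default) or `"linear"` (ramp from
#'   0 at onset to `amplitude` at the end of the record).
#' @param frequency Drift only: sinusoid frequency in Hz (default 0.02; must
#'   stay below the respiratory band for the drift to be a drift).
#' @param width Spike only: pulse width in samples (default 3).
#' @param count Spike only: number of pulses (default 5).
#' @param seed Spike only: RNG seed for the pulse locations (default 1).
#' @return An object of class `"artifact_spec"`.
#' @export
artifact_spec <- function(kind = c("drift", "step", "spike"), amplitude = 1.0,
                          onset = if (kind == "step") 2501L else 1L,
                          shape = c("sinusoidal", "linear"), frequency = 0.02,
                          width = 3L, count = 5L, seed = 1L) {
  kind <- match.arg(kind)
  shape <- match.arg(shape)
  if (kind == "spike" && width < 1) stop("spike width must be >= 1")
  if (onset < 1) stop("onset must be a positive sample index")
  structure(list(kind = kind, amplitude = amplitude, onset = as.integer(onset),
                 shape = shape, frequency = frequency,
                 width = as.integer(width), count = as.integer(count),
                 seed = as.integer(seed)),
            class = "artifact_spec")
}

#' Pure artifact waveform for a spec
#'
#' @param spec An [artifact_spec()].
#' @param n Record length in samples.
#' @param fs Sampling rate in Hz (needed for the drift frequency).
#' @return Numeric vector of length `n` containing just the artifact.
#' @export
artifact_waveform <- function(spec, n, fs = 20) {
  stopifnot(inherits(spec, "artifact_spec"))
  if (spec$onset > n) stop("artifact onset ", spec$onset,
                           " lies outside the record of length ", n)
  a <- numeric(n)
  idx <- spec$onset:n
  if (spec$kind == "drift") {
    if (spec$shape == "linear") {
      span <- max(1L, n - spec$onset)
      a[idx] <- spec$amplitude * (idx - spec$onset) / span
    } else {
      t <- (idx - spec$onset) / fs
      a[idx] <- spec$amplitude * sin(2 * pi * spec$frequency * t)
    }
  } else if (spec$kind == "step") {
    a[idx] <- spec$amplitude
  } else { # spike: `count` symmetric triangular pulses at seeded locations
    w <- spec$width
    half <- (w + 1) / 2
    pulse <- spec$amplitude * (1 - abs(seq_len(w) - half) / half)
    set.seed(spec$seed)
    starts <- sort(sample.int(max(1L, n - w), spec$count))
    for (s in starts) {
      span <- s:(s + w - 1L)
      a[span] <- a[span] + pulse
    }
  }
  a
}

#' Add an artifact to a signal
#'
#' Purely additive: `inject_artifact(x, spec) - x` equals
#' [artifact_waveform()] exactly.
#'
#' @inheritParams artifact_waveform
#' @param signal Numeric sample vector.
#' @return The contaminated signal, same length as `signal`.
#' @export
inject_artifact <- function(signal, spec, fs = 20) {
  signal + artifact_waveform(spec, length(signal), fs)
}

#' Bundle a ground-truth / contaminated simulation pair
#'
#' @param config A [breathing_sim_config()].
#' @param specs List of [artifact_spec()]s (possibly empty).
#' @return A list with `truth`, `contaminated` (numeric vectors) and
#'   `artifacts` (list of pure artifact vectors, one per spec);
#'   `contaminated == truth + Reduce("+", artifacts)` exactly.
#' @export
simulate_contaminated <- function(config = breathing_sim_config(),
                                  specs = list()) {
  truth <- simulate_breathing(config)
  artifacts <- lapply(specs, artifact_waveform, n = config$n_samples,
                      fs = config$fs)
  contaminated <- truth
  for (a in artifacts) contaminated <- contaminated + a
  list(truth = truth, contaminated = contaminated, artifacts = artifacts)
}

#' Extend the 1-D simulation to a 208-channel frame series
#'
#' Channel `c` carries `gain[c]` times the shared noiseless oscillatory signal
#' plus independent Gaussian channel noise of amplitude `lambda`; artifacts
#' are injected scaled by the same per-channel gain (motion couples into each
#' channel in proportion to its sensitivity).
#'
#' @param config A [breathing_sim_config()].
#' @param specs List of [artifact_spec()]s.
#' @param channel_gains Numeric vector of 208 per-channel gains.
#' @return List of two [frame_series()] objects, `truth` and `contaminated`.
#' @export
simulate_frame_series <- function(config = breathing_sim_config(),
                                  specs = list(),
                                  channel_gains = rep(1, 208)) {
  if (length(channel_gains) != 208L) {
    stop("channel_gains must have length 208, got ", length(channel_gains))
  }
  cfg0 <- config
  cfg0$noise_amplitude <- 0
  shared <- simulate_breathing(cfg0)
  n <- config$n_samples
  set.seed(config$seed)
  noise <- matrix(stats::rnorm(n * 208L), n, 208L) * config$noise_amplitude
  truth <- outer(shared, channel_gains) + noise
  art <- numeric(n)
  for (spec in specs) art <- art + artifact_waveform(spec, n, config$fs)
  contaminated <- truth + outer(art, channel_gains)
  list(truth = frame_series(truth, config$fs),
       contaminated = frame_series(contaminated, config$fs))
}
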