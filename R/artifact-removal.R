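#' Cleaning configuration
#'
#' Parameters of the three wavelet-domain artifact-removal procedures. The
#' defaults encode the level choices that isolate each artifact class at a
#' 20 Hz frame rate: the level-6 approximation band (below ~0.156 Hz) carries
#' baseline drift, the level-1 detail band (5–10 Hz) localizes abrupt
#' changes, and detail levels 1–4 (0.625–10 Hz) carry spike transients.
#'
#' @param drift_level Decomposition depth L whose approximation band is
#'   removed for detrending (default 6; acts as a high-pass at
#'   `fs / 2^(L+1)` = 0.156 Hz at 20 Hz).
#' @param step_detection_level Detail level used to localize abrupt changes
#'   (default 1, the finest).
#' @param spike_levels Inclusive range of detail levels suppressed for spike
#'   removal (default `1:4`).
#' @param threshold_k Multiplier for the robust coefficient threshold
#'   `tau = k * MAD(d) / 0.6745` (default 5; the 0.6745 constant converts the
#'   median absolute deviation to a Gaussian sigma).
#' @param step_offset_window Samples on each side of a change point used to
#'   estimate the baseline offset by difference of medians (default 40, i.e.
#'   2 s at 20 Hz).
#' @param min_event_separation Candidate detections closer than this many
#'   samples are merged, keeping the strongest (default 40).
#' @param spike_mode `"threshold_local"` (default): only coefficients above
#'   the per-level robust threshold are zeroed, preserving sub-threshold
#'   physiology such as the ~1 Hz cardiac component living in d4;
#'   `"zero_global"`: levels in `spike_levels` are zeroed entirely.
#' @param wavelet,mode Wavelet name and boundary extension passed to
#'   [dwt_decompose()].
#' @param drift_boundary Boundary handling of the drift stage:
#'   `"periodic_trend"` (default) pads the record at each end with a local
#'   linear trend plus a periodic tiling of the dominant-period residual
#'   before decomposing, which keeps the quasi-periodic breathing signal from
#'   leaking into the coarse drift band at the record edges; `"reflect"` uses
#'   the bare reflective decomposition.
#' @return An object of class `"cleaning_config"`.
#' @export
cleaning_config <- function(drift_level = 6L, step_detection_level = 1L,
                            spike_levels = 1:4, threshold_k = 5,
                            step_offset_window = 40L,
                            min_event_separation = 40L,
                            spike_mode = c("threshold_local", "zero_global"),
                            wavelet = "db8", mode = "symmetric",
                            drift_boundary = c("periodic_trend", "reflect")) {
  spike_mode <- match.arg(spike_mode)
  drift_boundary <- match.arg(drift_boundary)
  if (threshold_k <= 0) stop("threshold_k must be positive")
  if (step_offset_window < 1 || min_event_separation < 1) {
    stop("windows must be >= 1 sample")
  }
  spike_levels <- sort(unique(as.integer(spike_levels)))
  if (any(spike_levels < 1L) || any(diff(spike_levels) != 1L)) {
    stop("spike_levels must be a contiguous range of levels >= 1")
  }
  if (drift_level < 1L || step_detection_level < 1L) {
    stop("decomposition levels must be >= 1")
  }
  structure(list(drift_level = as.integer(drift_level),
                 step_detection_level = as.integer(step_detection_level),
                 spike_levels = spike_levels, threshold_k = threshold_k,
                 step_offset_window = as.integer(step_offset_window),
                 min_event_separation = as.integer(min_event_separation),
                 spike_mode = spike_mode, wavelet = wavelet, mode = mode,
                 drift_boundary = drift_boundary),
            class = "cleaning_config")
}

#' Decomposition depth for a drift cutoff frequency
#'
#' The level whose approximation band ends nearest below `f_cut`:
#' `L = floor(log2(fs / (2 * f_cut)))`.
#'
#' @param fs Sampling rate in Hz.
#' @param f_cut Desired high-pass cutoff in Hz.
#' @return Integer level.
#' @examples
#' drift_level_for(20, 0.156)  # 6
#' @export
drift_level_for <- function(fs, f_cut) {
  if (f_cut <= 0 || f_cut >= fs / 2) stop("f_cut must lie in (0, fs/2)")
  max(1L, as.integer(floor(log2(fs / (2 * f_cut)))))
}

# dominant oscillation period (in samples) from the periodogram, restricted
# to a physiological respiratory band; NA when no prominent peak exists
.estimate_period <- function(x, fs, band = c(0.1, 0.5)) {
  n <- length(x)
  sp <- Mod(stats::fft(x - mean(x)))^2
  fr <- (seq_len(n) - 1) * fs / n
  sel <- which(fr >= band[1] & fr <= band[2])
  if (length(sel) < 3L) return(NA_integer_)
  pk <- sel[which.max(sp[sel])]
  if (sp[pk] <= 10 * stats::median(sp[sel])) return(NA_integer_)
  as.integer(round(fs / fr[pk]))
}

# extend the record by Q samples at each end: local linear trend (least
# squares over the outermost 2P samples) continued, plus a periodic tiling of
# the detrended residual; value- and slope-continuous for quasi-periodic
# signals, so the coarse-band estimate stays clean up to the record edges
.pad_periodic_trend <- function(x, P, Q) {
  n <- length(x)
  w <- min(2L * P, n)
  W <- seq_len(w)
  cl <- stats::lm.fit(cbind(1, W), x[W])$coefficients
  Wr <- seq.int(n - w + 1L, n)
  cr <- stats::lm.fit(cbind(1, Wr), x[Wr])$coefficients
  res_l <- x[W] - (cl[1L] + cl[2L] * W)
  res_r <- x[Wr] - (cr[1L] + cr[2L] * Wr)
  il <- seq.int(1L - Q, 0L)
  ir <- seq.int(n + 1L, n + Q)
  left <- cl[1L] + cl[2L] * il + res_l[((il - 1L) %% P) + 1L]
  right <- cr[1L] + cr[2L] * ir + res_r[w - P + ((ir - n - 1L) %% P) + 1L]
  c(left, x, right)
}

#' Remove baseline drift
#'
#' Decomposes the signal to `drift_level` levels, zeroes the approximation
#' band and rebuilds: a wavelet high-pass at `fs / 2^(L+1)` (0.156 Hz for the
#' defaults) that removes slow drift, e.g. from a pulsating air mattress,
#' while passing the respiratory band.
#'
#' With the default `drift_boundary = "periodic_trend"` the record is first
#' extended at both ends by a local linear trend plus a periodic tiling of
#' the dominant-period residual (period estimated from the periodogram in
#' the 0.1–0.5 Hz respiratory band), decomposed, and trimmed back: this keeps
#' the breathing oscillation from leaking into the drift estimate at the
#' record edges. When no prominent respiratory peak exists the bare
#' reflective decomposition is used.
#'
#' @param signal Numeric sample vector.
#' @param fs Sampling rate in Hz (used for the period search and to document
#'   the effective cutoff; default 20).
#' @param config A [cleaning_config()].
#' @return Detrended signal, same length.
#' @export
remove_baseline_drift <- function(signal, fs = 20,
                                  config = cleaning_config()) {
  stopifnot(inherits(config, "cleaning_config"))
  n <- length(signal)
  P <- if (config$drift_boundary == "periodic_trend") {
    .estimate_period(signal, fs)
  } else NA_integer_
  if (is.na(P) || P < 2L || n < 2L * P + 10L) {
    dec <- dwt_decompose(signal, config$drift_level, config$wavelet, config$mode)
    return(dwt_rebuild(dec, coef_mask(zero_approx = TRUE)))
  }
  filt_len <- wavelet_filters(config$wavelet)$length
  Q <- as.integer(filt_len * 2^config$drift_level)  # spatial support of a_L
  padded <- .pad_periodic_trend(signal, P, Q)
  dec <- dwt_decompose(padded, config$drift_level, config$wavelet, config$mode)
  out <- dwt_rebuild(dec, coef_mask(zero_approx = TRUE))
  out[(Q + 1L):(Q + n)]
}

# robust threshold on a coefficient vector: k * MAD / 0.6745
.robust_tau <- function(d, k) k * stats::mad(d)

# Group delay of the level-1 detail band for an ideal step edge, calibrated
# from the filter bank itself: decompose a unit step at a known onset and
# record where the peak |d1| response lands. Coefficient i then maps back to
# sample 2i - delay. Cached per wavelet/mode.
.d1_delay_cache <- new.env(parent = emptyenv())

.d1_step_delay <- function(wavelet, mode) {
  key <- paste(wavelet, mode)
  if (!is.null(.d1_delay_cache[[key]])) return(.d1_delay_cache[[key]])
  onset <- 129L
  probe <- c(numeric(onset - 1L), rep(1, 128L))
  dec <- dwt_decompose(probe, 1L, wavelet, mode)
  peak <- which.max(abs(dec$details[[1L]]))
  delay <- 2L * peak - onset
  .d1_delay_cache[[key]] <- delay
  delay
}

.d1_coef_to_sample <- function(i, delay, n) {
  pmin(pmax(2L * i - delay, 1L), n)
}

#' Detect abrupt baseline changes
#'
#' Flags finest-detail coefficients whose magnitude exceeds the robust
#' threshold `tau = k * MAD(d1) / 0.6745`, maps them back to sample indices,
#' merges candidates closer than `min_event_separation` (keeping the
#' strongest), and classifies each event as a persistent `step` or a
#' transient `spike` by whether the difference of medians over
#' `step_offset_window` samples before vs after the change point persists
#' (`|offset| > tau`, also checked over twice the window when it fits, which
#' cancels the median bias of the breathing oscillation over incomplete
#' cycles).
#'
#' @param signal Numeric sample vector (length at least twice the offset
#'   window).
#' @param config A [cleaning_config()].
#' @return A data frame of class `"detected_events"` with columns `kind`
#'   (`"step"`/`"spike"`), `location` (1-based sample), `support_start`,
#'   `support_end`, `offset` (signed baseline shift; for spikes the measured,
#'   non-persistent value) and `stat` (peak |d1|). Zero rows when nothing is
#'   detected (an all-constant signal is not an error).
#' @export
detect_steps <- function(signal, config = cleaning_config()) {
  stopifnot(inherits(config, "cleaning_config"))
  n <- length(signal)
  if (n < 2L * config$step_offset_window) {
    stop("signal shorter than twice the step_offset_window")
  }
  empty <- structure(
    data.frame(kind = character(), location = integer(),
               support_start = integer(), support_end = integer(),
               offset = numeric(), stat = numeric()),
    class = c("detected_events", "data.frame")
  )
  if (stats::sd(signal) == 0) return(empty)
  dec <- dwt_decompose(signal, config$step_detection_level,
                       config$wavelet, config$mode)
  d1 <- dec$details[[config$step_detection_level]]
  tau <- .robust_tau(d1, config$threshold_k)
  hits <- which(abs(d1) > tau)
  if (tau == 0 || length(hits) == 0L) return(empty)

  delay <- .d1_step_delay(config$wavelet, config$mode)
  samples <- .d1_coef_to_sample(hits, delay, n)
  # coefficients whose support straddles a record edge respond to the
  # boundary extension, not to the data; change points there are
  # unidentifiable, so candidates within one filter support of either end
  # are discarded
  filt_len <- wavelet_filters(config$wavelet)$length
  keep <- samples > filt_len & samples <= n - filt_len
  hits <- hits[keep]
  samples <- samples[keep]
  if (length(hits) == 0L) return(empty)
  ord <- order(samples)
  samples <- samples[ord]
  strength <- abs(d1)[hits][ord]
  # chain-merge candidates within min_event_separation
  grp <- cumsum(c(1L, diff(samples) > config$min_event_separation))
  events <- lapply(split(seq_along(samples), grp), function(ix) {
    peak <- ix[which.max(strength[ix])]
    list(location = samples[peak], stat = strength[peak],
         support = range(samples[ix]))
  })

  w <- config$step_offset_window
  rows <- lapply(events, function(ev) {
    loc <- ev$location
    med_offset <- function(win) {
      if (loc <= 1L) return(0)
      before <- signal[max(1L, loc - win):(loc - 1L)]
      after <- signal[loc:min(n, loc + win - 1L)]
      stats::median(after) - stats::median(before)
    }
    off <- med_offset(w)
    persists <- abs(off) > tau
    if (loc - 2L * w >= 1L && loc + 2L * w - 1L <= n) {
      off2 <- med_offset(2L * w)
      persists <- persists && abs(off2) > tau
      if (persists) off <- off2
    }
    data.frame(kind = if (persists) "step" else "spike",
               location = loc, support_start = ev$support[1L],
               support_end = ev$support[2L], offset = off, stat = ev$stat)
  })
  out <- do.call(rbind, c(rows, list(make.row.names = FALSE)))
  out <- out[order(out$location), , drop = FALSE]
  rownames(out) <- NULL
  structure(out, class = c("detected_events", "data.frame"))
}

#' Correct step-like baseline shifts
#'
#' For each detected `step` event (in location order), subtracts its offset
#' estimate from every sample at and after the change point, restoring the
#' pre-movement baseline. Events of kind `"spike"` are ignored. An empty
#' event table returns the input unchanged.
#'
#' @param signal Numeric sample vector.
#' @param events A `"detected_events"` data frame (from [detect_steps()]).
#' @return Corrected signal, same length.
#' @export
correct_steps <- function(signal, events) {
  if (is.null(events) || nrow(events) == 0L) return(signal)
  if (any(events$location < 1L | events$location > length(signal))) {
    stop("event location outside the signal")
  }
  steps <- events[events$kind == "step", , drop = FALSE]
  steps <- steps[order(steps$location), , drop = FALSE]
  for (i in seq_len(nrow(steps))) {
    idx <- steps$location[i]:length(signal)
    signal[idx] <- signal[idx] - steps$offset[i]
  }
  signal
}

#' Remove spike-like transients
#'
#' Decomposes to `max(spike_levels)` levels and suppresses detail
#' coefficients in the configured levels. In `"threshold_local"` mode only
#' coefficients whose magnitude exceeds the per-level robust threshold
#' `tau_j = k * MAD(d_j) / 0.6745` are zeroed, leaving sub-threshold
#' physiology (including the cardiac component in d4) untouched;
#' `"zero_global"` zeroes the whole levels.
#'
#' @inheritParams remove_baseline_drift
#' @return Despiked signal, same length.
#' @export
remove_spikes <- function(signal, config = cleaning_config()) {
  stopifnot(inherits(config, "cleaning_config"))
  levels_used <- config$spike_levels
  dec <- dwt_decompose(signal, max(levels_used), config$wavelet, config$mode)
  mask <- if (config$spike_mode == "zero_global") {
    coef_mask(zero_details = levels_used)
  } else {
    taus <- vapply(levels_used, function(j) {
      .robust_tau(dec$details[[j]], config$threshold_k)
    }, numeric(1))
    names(taus) <- as.character(levels_used)
    coef_mask(thresholds = taus)
  }
  dwt_rebuild(dec, mask)
}

#' Clean one EIT channel
#'
#' Applies the requested artifact-removal stages in order (default
#' drift -> step -> spike) and returns the cleaned signal together with all
#' events detected by the step stage. Re-running on its own output is close
#' to a no-op (the stages are approximately idempotent).
#'
#' @param signal Numeric sample vector.
#' @param fs Sampling rate in Hz.
#' @param config A [cleaning_config()].
#' @param stages Ordered nonempty subset of `c("drift", "step", "spike")`.
#' @return List with `signal` (cleaned vector) and `events`
#'   (`"detected_events"` data frame; zero rows if the step stage did not run
#'   or found nothing).
#' @export
clean_channel <- function(signal, fs = 20, config = cleaning_config(),
                          stages = c("drift", "step", "spike")) {
  stopifnot(inherits(config, "cleaning_config"))
  if (length(stages) == 0L) stop("stages must be a nonempty subset of drift/step/spike")
  if (!all(stages %in% c("drift", "step", "spike"))) {
    stop("unknown stage: ", paste(setdiff(stages, c("drift", "step", "spike")),
                                  collapse = ", "))
  }
  events <- NULL
  drift_done <- FALSE
  for (stage in stages) {
    if (stage == "drift") {
      signal <- remove_baseline_drift(signal, fs, config)
      drift_done <- TRUE
    } else if (stage == "step") {
      events <- detect_steps(signal, config)
      signal <- correct_steps(signal, events)
      # after drift removal the residual step artifact is the high-pass
      # projection of an ideal step, so the correction must live in the same
      # subspace: re-apply the (linear) drift projection, which turns the
      # raw-step subtraction into a projected-step subtraction and keeps the
      # pipeline idempotent
      if (drift_done && any(events$kind == "step")) {
        signal <- remove_baseline_drift(signal, fs, config)
      }
    } else {
      signal <- remove_spikes(signal, config)
    }
  }
  if (is.null(events)) {
    events <- structure(
      data.frame(kind = character(), location = integer(),
                 support_start = integer(), support_end = integer(),
                 offset = numeric(), stat = numeric()),
      class = c("detected_events", "data.frame")
    )
  }
  list(signal = signal, events = events)
}

#' Clean every channel of a frame series
#'
#' Applies [clean_channel()] independently to each of the 208 channels.
#'
#' @param frames A [frame_series()].
#' @param config A [cleaning_config()].
#' @param stages As in [clean_channel()].
#' @return List with `frames` (cleaned [frame_series()]) and `events` (named
#'   list of per-channel event tables, channels with no events omitted).
#' @export
clean_frames <- function(frames, config = cleaning_config(),
                         stages = c("drift", "step", "spike")) {
  stopifnot(inherits(frames, "frame_series"))
  data <- frames$data
  events <- list()
  for (ch in seq_len(ncol(data))) {
    res <- clean_channel(data[, ch], frames$fs, config, stages)
    data[, ch] <- res$signal
    if (nrow(res$events) > 0L) {
      events[[colnames(frames$data)[ch]]] <- res$events
    }
  }
  list(frames = frame_series(data, frames$fs), events = events)
}
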