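cl <- cleaning_config()

test_that("drift removal passes the respiratory band and kills slow trends", {
  # a pure 0.25 Hz tone lies above the level-6 approximation band
  s <- sin(2 * pi * 0.25 * (0:4999) / 20)
  out <- remove_baseline_drift(s, 20, cl)
  expect_gt(r_squared(s, out), 0.95)
  expect_lt(r_squared(s, out), 1.05)

  # a 0 -> 2 ramp over the record is almost entirely drift
  cfg <- breathing_sim_config()
  sim <- simulate_contaminated(cfg, list(artifact_spec("drift", 2.0,
                                                       shape = "linear")))
  out <- remove_baseline_drift(sim$contaminated, 20, cl)
  expect_lt(prd(sim$truth, out), 0.2 * prd(sim$truth, sim$contaminated))

  expect_identical(remove_baseline_drift(numeric(5000), 20, cl),
                   numeric(5000))
})

test_that("drift removal acts linearly on in-band drift", {
  cfg <- breathing_sim_config(seed = 6)
  x <- simulate_breathing(cfg)
  drift <- artifact_waveform(artifact_spec("drift", 1.0), 5000, 20)
  out_clean <- remove_baseline_drift(x, 20, cl)
  out_drifted <- remove_baseline_drift(x + drift, 20, cl)
  expect_lt(prd(out_clean, out_drifted), 0.05)
})

test_that("steps are localized, signed and recovered", {
  cfg <- breathing_sim_config()
  sim <- simulate_contaminated(cfg, list(artifact_spec("step", 1.0,
                                                       onset = 2501L)))
  ev <- detect_steps(sim$contaminated, cl)
  expect_identical(nrow(ev), 1L)
  expect_identical(ev$kind, "step")
  expect_lte(abs(ev$location - 2501L), 8)

  # artifact-free signal: nothing above the robust threshold
  expect_identical(nrow(detect_steps(simulate_breathing(cfg), cl)), 0L)
  # constant signal: empty, not an error
  expect_identical(nrow(detect_steps(rep(2, 500), cl)), 0L)

  sim2 <- simulate_contaminated(cfg,
    list(artifact_spec("step", 1.0, onset = 1001L),
         artifact_spec("step", -0.8, onset = 3001L)))
  ev2 <- detect_steps(sim2$contaminated, cl)
  expect_identical(nrow(ev2), 2L)
  expect_true(all(ev2$kind == "step"))
  expect_gt(ev2$offset[1], 0)
  expect_lt(ev2$offset[2], 0)
})

test_that("step correction restores the baseline", {
  cfg <- breathing_sim_config()
  sim <- simulate_contaminated(cfg, list(artifact_spec("step", 1.0,
                                                       onset = 2501L)))
  ev <- detect_steps(sim$contaminated, cl)
  out <- correct_steps(sim$contaminated, ev)
  expect_lt(prd(sim$truth, out), 0.1 * prd(sim$truth, sim$contaminated))

  expect_identical(correct_steps(sim$contaminated, ev[0, ]),
                   sim$contaminated)
  bad <- ev
  bad$location <- 10000L
  expect_error(correct_steps(sim$contaminated, bad), "outside")
})

test_that("step offset is recovered within 0.1 across seeds", {
  errs <- vapply(1:20, function(sd) {
    sim <- simulate_contaminated(breathing_sim_config(seed = sd),
                                 list(artifact_spec("step", 1.0,
                                                    onset = 2501L)))
    ev <- detect_steps(sim$contaminated, cl)
    ev <- ev[ev$kind == "step", ]
    abs(ev$offset[1] - 1.0)
  }, numeric(1))
  expect_lte(median(errs), 0.1)
  expect_gte(sum(errs <= 0.1), 18)
})

test_that("spike suppression removes transients but passes physiology", {
  cfg <- breathing_sim_config()
  sim <- simulate_contaminated(cfg, list(artifact_spec("spike", 1.5,
                                                       width = 3L, count = 5L,
                                                       seed = 7L)))
  out <- remove_spikes(sim$contaminated, cl)
  expect_lt(prd(sim$truth, out), 0.5 * prd(sim$truth, sim$contaminated))

  x <- simulate_breathing(cfg)
  expect_lt(prd(x, remove_spikes(x, cl)), 0.05)
})

test_that("global zeroing of d1-d4 removes the cardiac band", {
  x <- simulate_breathing(breathing_sim_config())
  out <- remove_spikes(x, cleaning_config(spike_mode = "zero_global"))
  expect_gt(1 - band_power(out, 20, 0.625, 1.25) /
              band_power(x, 20, 0.625, 1.25), 0.8)
})

test_that("local spike thresholding never increases the PRD", {
  for (amp in c(0.5, 1.0, 1.5)) {
    for (sd in 1:20) {
      sim <- simulate_contaminated(
        breathing_sim_config(seed = sd),
        list(artifact_spec("spike", amp, width = 3L, count = 5L, seed = sd))
      )
      out <- remove_spikes(sim$contaminated, cl)
      expect_lte(prd(sim$truth, out),
                 prd(sim$truth, sim$contaminated) + 1e-9)
    }
  }
})

test_that("step detection stays silent on artifact-free records", {
  clean_runs <- vapply(1:100, function(sd) {
    x <- simulate_breathing(breathing_sim_config(noise_amplitude = 0.05,
                                                 seed = sd))
    nrow(detect_steps(x, cl)) == 0L
  }, logical(1))
  expect_gte(sum(clean_runs), 95)
})

test_that("channel cleaning composes its stages", {
  cfg <- breathing_sim_config()
  sim <- simulate_contaminated(cfg, list(artifact_spec("drift", 1.0)))
  res <- clean_channel(sim$contaminated, 20, cl, stages = "drift")
  expect_identical(res$signal,
                   remove_baseline_drift(sim$contaminated, 20, cl))

  specs <- list(artifact_spec("drift", 1.0),
                artifact_spec("step", 1.0, onset = 2501L),
                artifact_spec("spike", 1.5, width = 3L, count = 5L, seed = 7L))
  simc <- simulate_contaminated(cfg, specs)
  resc <- clean_channel(simc$contaminated, 20, cl)
  expect_lt(prd(simc$truth, resc$signal),
            0.3 * prd(simc$truth, simc$contaminated))
  expect_true(all(is.finite(resc$signal)))
  expect_length(resc$signal, 5000)

  # near-idempotence
  rerun <- clean_channel(resc$signal, 20, cl)
  expect_lt(prd(resc$signal, rerun$signal), 0.05)

  # artifact-free pass-through
  x <- simulate_breathing(cfg)
  expect_lt(prd(x, clean_channel(x, 20, cl)$signal), 0.05)

  expect_error(clean_channel(x, 20, cl, stages = character()), "nonempty")
  expect_error(clean_channel(x, 20, cl, stages = "detrend"), "unknown stage")
})

test_that("frame cleaning is channel-wise and validates its input", {
  n <- 1024L
  b <- simulate_breathing(breathing_sim_config(noise_amplitude = 0,
                                               n_samples = n))
  step <- artifact_waveform(artifact_spec("step", 0.5, onset = 512L), n)
  data <- matrix(rep(b, 208), n, 208)
  data[, 1:10] <- data[, 1:10] + step
  fr <- frame_series(data, 20)
  res <- clean_frames(fr, cl, stages = "step")

  # identical contaminated channels produce identical cleaned channels
  expect_true(all(res$frames$data[, 2] == res$frames$data[, 10]))
  # untouched channels pass through bit-identically (no events detected)
  expect_identical(res$frames$data[, 11:208], fr$data[, 11:208])
  expect_true(all(names(res$events) %in% sprintf("ch%03d", 1:10)))
  # frame cleaning is exactly per-channel application of clean_channel
  for (ch in c(1L, 5L, 200L)) {
    expect_identical(res$frames$data[, ch],
                     clean_channel(fr$data[, ch], 20, cl, "step")$signal)
  }

  expect_error(frame_series(data[0, , drop = FALSE]), "at least one frame")
  data[5, 3] <- NA
  expect_error(frame_series(data, 20), "frame 5, channel 3")
})

test_that("cleaning configuration is validated", {
  expect_error(cleaning_config(threshold_k = 0), "positive")
  expect_error(cleaning_config(spike_levels = c(1, 3)), "contiguous")
  expect_error(cleaning_config(step_offset_window = 0), ">= 1")
  expect_error(remove_baseline_drift(rnorm(100), 20,
                                     cleaning_config(drift_level = 6)),
               "maximum admissible level")
  expect_identical(drift_level_for(20, 0.156), 6L)
})
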