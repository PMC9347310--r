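test_that("stimulus set has the requested geometry and is seed-deterministic", {
  st <- fixture_stimuli()
  expect_length(st$waveforms, 16)
  expect_true(all(vapply(st$waveforms, length, integer(1)) == 48800))
  expect_identical(st$sound_class, c(rep("PT", 8), rep("CxS", 8)))
  expect_true(all(vapply(st$waveforms, function(w) all(is.finite(w)),
                         logical(1))))
  st2 <- make_stimulus_set(seed = 1)
  expect_identical(st$waveforms, st2$waveforms)
  expect_error(make_stimulus_set(seed = 1, sample_rate_hz = 40000),
               "Nyquist|twice")
})

test_that("every complex sound exceeds every pure tone on all three metrics", {
  m <- fixture_metrics()
  pt <- m$sound_class == "PT"
  expect_lt(max(m$occupied_bandwidth_hz[pt]),
            min(m$occupied_bandwidth_hz[!pt]))
  expect_lt(max(m$spectral_entropy_bits[pt]),
            min(m$spectral_entropy_bits[!pt]))
  expect_lt(max(m$modulation_index[pt]), min(m$modulation_index[!pt]))
})

test_that("experiments are reproducible and respect the drift-label contract", {
  st <- fixture_stimuli()
  cfg <- synth_config(n_neurons = 8, n_days = 3, seed = 11)
  e1 <- make_experiment(cfg, st)
  e2 <- make_experiment(cfg, st)
  expect_identical(e1$sessions[[2]]$traces, e2$sessions[[2]]$traces)
  expect_identical(e1$truth, e2$truth)
  expect_identical(dim(e1$truth$responsive_mask), c(8L, 16L, 3L))
  # remap labels only where the pair was responsive on >= 1 day of the step
  lab <- e1$truth$drift_labels
  for (d in 1:2) {
    remap <- which(lab[, , d] == "remap")
    resp_any <- e1$truth$responsive_mask[, , d] |
      e1$truth$responsive_mask[, , d + 1]
    expect_true(all(resp_any[remap]))
  }
})

test_that("zero noise makes repeated trials of a responsive pair identical", {
  st <- fixture_stimuli()
  # jitter-free schedule and a kernel shorter than the event spacing, so
  # each response window sees exactly one transient
  cfg <- synth_config(n_neurons = 3, n_days = 1, frac_responsive = 1,
                      noise_sd = 0, isi_jitter_s = 0, kernel_decay_s = 0.15,
                      locomotion_rate = 0, seed = 4)
  ex <- make_experiment(cfg, st)
  tt <- extract_trials(ex$sessions[[1]])
  spread <- tapply(tt$response_mag[!tt$excluded],
                   paste(tt$neuron_id, tt$stimulus_id)[!tt$excluded],
                   function(x) diff(range(x)))
  expect_true(all(spread < 1e-12))
})

test_that("field-of-view pairs honour shift, morph and determinism", {
  f0 <- make_fov_pair(seed = 3, n_neurons = 20, shift_px = c(0, 0),
                      morph_noise = 0)
  expect_identical(f0$imageA, f0$imageB)
  f1 <- make_fov_pair(seed = 3, n_neurons = 20, shift_px = c(3, 5),
                      morph_noise = 0)
  expect_identical(unname(register_translation(f1$imageA, f1$imageB)),
                   c(3L, 5L))
  f1b <- make_fov_pair(seed = 3, n_neurons = 20, shift_px = c(3, 5),
                       morph_noise = 0)
  expect_identical(f1$imageB, f1b$imageB)
  expect_error(make_fov_pair(seed = 1, n_neurons = 400), "overcrowded")
})
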