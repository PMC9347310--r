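test_that("power spectrum concentrates a tone's power at its frequency", {
  fs <- 97600
  t <- (0:48799) / fs
  sp <- compute_power_spectrum(sin(2 * pi * 8000 * t), fs)
  expect_equal(length(sp$freqs_hz), length(sp$power))
  near <- abs(sp$freqs_hz - 8000) < 100
  expect_gt(sum(sp$power[near]) / sp$total_power, 0.95)
  # two equal-amplitude tones give two equal peaks
  sp2 <- compute_power_spectrum(sin(2 * pi * 4000 * t) +
                                  sin(2 * pi * 16000 * t), fs)
  p4 <- sum(sp2$power[abs(sp2$freqs_hz - 4000) < 100])
  p16 <- sum(sp2$power[abs(sp2$freqs_hz - 16000) < 100])
  expect_equal(p4, p16, tolerance = 1e-3)
  # all-zero waveform flagged
  sp0 <- compute_power_spectrum(numeric(100), fs)
  expect_true(isTRUE(attr(sp0, "zero")))
  expect_error(spectral_entropy(sp0), "undefined")
  expect_error(spectral_centroid(sp0), "undefined")
})

test_that("occupied bandwidth follows the cumulative-power crossings", {
  expect_equal(occupied_bandwidth(manual_spectrum(5000, 1)), 0)
  flat <- manual_spectrum(seq(0, 10000, length.out = 2001), rep(1, 2001))
  expect_equal(occupied_bandwidth(flat), 0.99 * 10000, tolerance = 10)
  t <- (0:48799) / 97600
  tone <- compute_power_spectrum(sin(2 * pi * 8000 * t), 97600)
  expect_lt(occupied_bandwidth(tone), 100)
})

test_that("bandwidth and centroid match a brute-force oracle on small spectra", {
  set.seed(42)
  for (rep in 1:20) {
    nb <- sample(2:16, 1)
    freqs <- sort(runif(nb, 0, 20000))
    power <- rexp(nb)
    sp <- manual_spectrum(freqs, power)
    # oracle: explicit loop over bins accumulating power
    tot <- sum(power); acc <- 0; f_lo <- f_hi <- NA
    for (i in seq_len(nb)) {
      acc <- acc + power[i]
      if (is.na(f_lo) && acc >= 0.005 * tot) f_lo <- freqs[i]
      if (is.na(f_hi) && acc >= 0.995 * tot) f_hi <- freqs[i]
    }
    expect_identical(occupied_bandwidth(sp), f_hi - f_lo)
    cent <- 0
    for (i in seq_len(nb)) cent <- cent + freqs[i] * power[i] / tot
    expect_equal(spectral_centroid(sp), cent)
  }
})

test_that("spectral entropy hits its closed-form landmarks", {
  expect_equal(spectral_entropy(manual_spectrum(1:64, rep(2, 64))), 6)
  expect_equal(spectral_entropy(manual_spectrum(5000, 3)), 0)
  expect_equal(spectral_entropy(manual_spectrum(c(1, 2), c(5, 5))), 1)
  # bounded by log2(number of positive bins)
  set.seed(7)
  for (rep in 1:10) {
    p <- rexp(32)
    h <- spectral_entropy(manual_spectrum(1:32, p))
    expect_gte(h, 0); expect_lte(h, log2(32))
  }
})

test_that("spectral centroid is the power-weighted mean frequency", {
  t <- (0:48799) / 97600
  sp <- compute_power_spectrum(sin(2 * pi * 8000 * t), 97600)
  expect_equal(spectral_centroid(sp), 8000, tolerance = 5)
  expect_equal(spectral_centroid(
    manual_spectrum(c(4000, 16000), c(1, 1))), 10000)
  flat <- manual_spectrum(seq(0, 10000, length.out = 1001), rep(1, 1001))
  expect_equal(spectral_centroid(flat), 5000)
})

test_that("modulation index separates stationary from alternating sounds", {
  fs <- 97600
  t <- (0:48799) / fs
  tone <- sin(2 * pi * 8000 * t)
  expect_lt(spectrotemporal_modulation_index(tone, fs), 0.05)
  # sweep through 20 disjoint noise bands, one per 25 ms time bin: every
  # bin pair has disjoint frequency support, so all pairwise correlations
  # are negative and the index exceeds 1 (its ceiling for 20 bins is
  # 1 + 1/19, when all pairs are maximally anticorrelated)
  set.seed(1)
  sweep_w <- numeric(length(t))
  for (k in 1:20) {
    idx <- (k - 1) * 2440 + 1:2440
    x <- rnorm(2440)
    X <- fft(x)
    fr <- (seq_along(x) - 1) / length(x) * fs
    fr <- pmin(fr, fs - fr)
    X[fr < (k - 1) * 2440 | fr >= k * 2440] <- 0
    sweep_w[idx] <- Re(fft(X, inverse = TRUE)) / length(x)
  }
  mi <- spectrotemporal_modulation_index(sweep_w, fs)
  expect_gt(mi, 1)
  expect_lte(mi, 1 + 1 / 19)
})

test_that("all four metrics are invariant to amplitude scaling", {
  w <- fixture_stimuli()$waveforms[[10]]
  fs <- fixture_stimuli()$sample_rate_hz
  a <- complexity_metrics(w, fs)
  b <- complexity_metrics(3.7 * w, fs)
  expect_equal(unlist(a), unlist(b), tolerance = 1e-9)
})

test_that("adding power at the spectrum edges never shrinks bandwidth", {
  set.seed(11)
  for (rep in 1:10) {
    freqs <- seq(0, 20000, length.out = 101)
    power <- rexp(101)
    bw0 <- occupied_bandwidth(manual_spectrum(freqs, power))
    power_edge <- power
    power_edge[c(1, 101)] <- power_edge[c(1, 101)] + 50 * max(power)
    bw1 <- occupied_bandwidth(manual_spectrum(freqs, power_edge))
    expect_gte(bw1, bw0)
  }
})

test_that("overlapping tones are ranked by integrated local power", {
  tones <- c(2000, 4000, 8000, 16000)
  freqs <- seq(0, 20000, by = 10)
  # flat band 3-6 kHz: only the 4 kHz tone window overlaps; second place
  # is a three-way zero tie broken by lower frequency
  band <- manual_spectrum(freqs, as.numeric(freqs >= 3000 & freqs <= 6000))
  expect_identical(overlapping_tone_set(band, tones, 2), c(2L, 1L))
  # k = all tones returns the identity set
  expect_setequal(overlapping_tone_set(band, tones, 4), 1:4)
  # power entirely above every tone window (the 16 kHz window tops out at
  # 16 * 2^(1/3) ~ 20.2 kHz): all-zero overlap, lower-frequency tie-break
  freqs_hi <- seq(0, 30000, by = 10)
  high <- manual_spectrum(freqs_hi, as.numeric(freqs_hi >= 25000))
  expect_identical(overlapping_tone_set(high, tones, 3), c(1L, 2L, 3L))
})
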