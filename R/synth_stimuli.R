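#' Synthesize a pure-tone + complex-sound stimulus set
#'
#' Builds the two stimulus protocols used throughout the package: `n_pt`
#' pure tones log-spaced from 2 to 32 kHz with 5 ms cosine on/off ramps, and
#' `n_cxs` spectrotemporally complex sounds. Each complex sound is a sum of
#' 3-5 band-limited noise components with independent amplitude envelopes
#' re-drawn every 50-100 ms, which guarantees that every complex sound has a
#' higher occupied bandwidth, spectral entropy and modulation index than any
#' pure tone (the generator's separation contract, verified in tests).
#'
#' @param seed integer seed; the set is bit-identical for a given seed.
#' @param n_pt,n_cxs number of pure tones / complex sounds (default 8 each).
#' @param sample_rate_hz sampling rate (default 97600 Hz); must exceed twice
#'   the highest tone frequency (32 kHz).
#' @param duration_s stimulus duration in seconds (default 0.5).
#' @return object of class `stimulus_set`: list with `waveforms` (list of
#'   numeric vectors, peak-normalized to 0.9), `sample_rate_hz`, `labels`,
#'   `sound_class` (character, "PT" or "CxS"), `duration_s`.
#' @export
make_stimulus_set <- function(seed = 1L, n_pt = 8L, n_cxs = 8L,
                              sample_rate_hz = 97600, duration_s = 0.5) {
  stopifnot(n_pt >= 1, n_cxs >= 1, duration_s > 0)
  f_max <- 32000
  if (sample_rate_hz <= 2 * f_max)
    stop("sample_rate_hz (", sample_rate_hz, ") must exceed twice the ",
         "highest tone frequency (", f_max, " Hz)")
  n <- round(duration_s * sample_rate_hz)
  t <- (seq_len(n) - 1) / sample_rate_hz
  ramp <- cosine_ramp(n, sample_rate_hz, ramp_s = 0.005)
  tone_freqs <- if (n_pt == 1) 2000 else
    2000 * (f_max / 2000)^(seq(0, 1, length.out = n_pt))
  with_rng_seed(seed, {
    pt <- lapply(tone_freqs, function(f) {
      w <- sin(2 * pi * f * t) * ramp
      w / max(abs(w)) * 0.9
    })
    cxs <- lapply(seq_len(n_cxs), function(i) {
      w <- complex_sound_waveform(n, sample_rate_hz)
      w * ramp / max(abs(w)) * 0.9
    })
  })
  structure(list(
    waveforms = c(pt, cxs),
    sample_rate_hz = sample_rate_hz,
    labels = c(sprintf("PT_%.1fkHz", tone_freqs / 1000),
               sprintf("CxS_%02d", seq_len(n_cxs))),
    sound_class = c(rep("PT", n_pt), rep("CxS", n_cxs)),
    duration_s = duration_s,
    tone_freqs_hz = tone_freqs
  ), class = "stimulus_set")
}

cosine_ramp <- function(n, sample_rate_hz, ramp_s = 0.005) {
  nr <- max(1L, round(ramp_s * sample_rate_hz))
  r <- 0.5 - 0.5 * cos(pi * seq_len(nr) / nr)
  env <- rep(1, n)
  env[seq_len(nr)] <- r
  env[n - nr + seq_len(nr)] <- rev(r)
  env
}

# One broadband modulated sound: 3-5 band-limited noise components, each with
# a piecewise amplitude envelope re-drawn every 50-100 ms (segments linearly
# interpolated to avoid clicks; ~30% of segments near-silent so frequency
# content visibly turns on and off over time).
complex_sound_waveform <- function(n, sample_rate_hz) {
  n_comp <- sample(3:5, 1)
  # force coverage of low and high bands so the set is wideband overall
  centers <- exp(runif(n_comp, log(2500), log(24000)))
  centers[1] <- exp(runif(1, log(2500), log(5000)))
  centers[n_comp] <- exp(runif(1, log(12000), log(24000)))
  out <- numeric(n)
  for (ci in seq_len(n_comp)) {
    half_oct <- runif(1, 0.5, 1.25)          # half-bandwidth in octaves
    lo <- centers[ci] / 2^half_oct
    hi <- min(centers[ci] * 2^half_oct, 0.45 * sample_rate_hz)
    noise <- bandlimited_noise(n, sample_rate_hz, lo, hi)
    out <- out + segment_envelope(n, sample_rate_hz) * noise
  }
  out
}

# White noise restricted to [lo_hz, hi_hz] by zeroing FFT bins outside band.
bandlimited_noise <- function(n, sample_rate_hz, lo_hz, hi_hz) {
  x <- rnorm(n)
  sp <- fft(x)
  freqs <- (seq_len(n) - 1) / n * sample_rate_hz
  freqs <- pmin(freqs, sample_rate_hz - freqs)  # mirror for negative freqs
  sp[freqs < lo_hz | freqs > hi_hz] <- 0
  y <- Re(fft(sp, inverse = TRUE)) / n
  y / (sd(y) + 1e-12)
}

# Piecewise amplitude envelope: segment lengths uniform in 50-100 ms,
# amplitudes half-normal with ~30% near-silent segments, linear interpolation
# between segment midpoints.
segment_envelope <- function(n, sample_rate_hz) {
  seg_len <- round(runif(12, 0.05, 0.1) * sample_rate_hz)
  bounds <- pmin(cumsum(seg_len), n)
  bounds <- unique(c(0L, bounds[bounds > 0], n))
  n_seg <- length(bounds) - 1
  amp <- abs(rnorm(n_seg, 0, 1))
  amp[runif(n_seg) < 0.3] <- 0.02
  mids <- (bounds[-1] + bounds[-length(bounds)]) / 2
  approx(x = c(0, mids, n), y = c(amp[1], amp, amp[n_seg]),
         xout = seq_len(n))$y
}

#' Write every stimulus of a set as 16-bit PCM WAV files
#'
#' @param stimuli a `stimulus_set`.
#' @param dir output directory (created if missing).
#' @return character vector of file paths, invisibly.
#' @export
write_stimulus_set <- function(stimuli, dir) {
  stopifnot(inherits(stimuli, "stimulus_set"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- file.path(dir, paste0(stimuli$labels, ".wav"))
  for (i in seq_along(paths))
    write_wav(stimuli$waveforms[[i]], stimuli$sample_rate_hz, paths[i])
  invisible(paths)
}
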