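#' Single-sided power spectrum of a waveform
#'
#' Full-signal periodogram at a fixed FFT length (next power of two at or
#' above the waveform length). A full-length periodogram, rather than an
#' averaged (Welch) estimate, preserves the narrow spectral lines of pure
#' tones and is deterministic.
#'
#' @param waveform numeric vector of samples.
#' @param sample_rate_hz sampling rate in Hz.
#' @return object of class `caldrift_spectrum`: list with `freqs_hz`
#'   (ascending grid from 0 to Nyquist), `power` (non-negative per-bin
#'   power), and `total_power`. An all-zero waveform yields a zero spectrum
#'   with attribute `zero = TRUE`; entropy and centroid are undefined on it.
#' @export
compute_power_spectrum <- function(waveform, sample_rate_hz) {
  stopifnot(length(waveform) > 0, all(is.finite(waveform)),
            is.numeric(sample_rate_hz), sample_rate_hz > 0)
  n <- length(waveform)
  nfft <- 2^ceiling(log2(n))
  xw <- c(waveform, numeric(nfft - n))
  sp <- abs(fft(xw))^2 / (sample_rate_hz * n)
  half <- nfft / 2 + 1
  power <- sp[seq_len(half)]
  # fold negative frequencies into the single-sided view (DC and Nyquist once)
  power[2:(half - 1)] <- 2 * power[2:(half - 1)]
  freqs <- seq(0, sample_rate_hz / 2, length.out = half)
  out <- structure(list(freqs_hz = freqs, power = power,
                        total_power = sum(power)),
                   class = "caldrift_spectrum")
  if (out$total_power == 0) attr(out, "zero") <- TRUE
  out
}

#' Occupied bandwidth of a spectrum
#'
#' Frequency span between the points where the integrated (cumulative)
#' spectral power crosses `lo_frac` and `hi_frac` of the total power
#' (defaults 0.5% and 99.5%).
#'
#' @param spectrum a `caldrift_spectrum`.
#' @param lo_frac,hi_frac lower/upper cumulative-power fractions.
#' @return bandwidth in Hz (0 for a single-bin spectrum).
#' @export
occupied_bandwidth <- function(spectrum, lo_frac = 0.005, hi_frac = 0.995) {
  stopifnot(inherits(spectrum, "caldrift_spectrum"),
            spectrum$total_power > 0, lo_frac < hi_frac)
  cum <- cumsum(spectrum$power)
  f_at <- function(q) {
    spectrum$freqs_hz[which(cum >= q * spectrum$total_power)[1]]
  }
  f_at(hi_frac) - f_at(lo_frac)
}

#' Shannon spectral entropy in bits
#'
#' Entropy of the normalized power distribution: high for broadband sounds,
#' 0 for a single spectral line.
#'
#' @param spectrum a `caldrift_spectrum`.
#' @return entropy in bits, in \[0, log2(n_bins)\].
#' @export
spectral_entropy <- function(spectrum) {
  stopifnot(inherits(spectrum, "caldrift_spectrum"))
  if (spectrum$total_power <= 0) stop("entropy undefined for zero spectrum")
  p <- spectrum$power / spectrum$total_power
  p <- p[p > 0]
  -sum(p * log2(p))
}

#' Spectral centroid
#'
#' Power-weighted mean frequency.
#'
#' @param spectrum a `caldrift_spectrum`.
#' @return centroid in Hz.
#' @export
spectral_centroid <- function(spectrum) {
  stopifnot(inherits(spectrum, "caldrift_spectrum"))
  if (spectrum$total_power <= 0) stop("centroid undefined for zero spectrum")
  sum(spectrum$freqs_hz * spectrum$power) / spectrum$total_power
}

# Short-time power spectrogram: Hann window, 50% overlap. Returns a
# freq-bins x frames matrix of linear power.
stft_power <- function(waveform, window = 1024L, hop = window %/% 2L) {
  n <- length(waveform)
  if (n < window) stop("waveform shorter than one spectrogram window")
  w <- 0.5 - 0.5 * cos(2 * pi * seq_len(window) / window)
  starts <- seq(1L, n - window + 1L, by = hop)
  half <- window %/% 2L + 1L
  out <- vapply(starts, function(s) {
    seg <- waveform[s:(s + window - 1L)] * w
    abs(fft(seg))[seq_len(half)]^2
  }, numeric(half))
  out
}

#' Spectrotemporal modulation index
#'
#' One minus the spectrogram autocorrelation: the spectrogram (Hann window of
#' `window_samples`, 50% overlap) is truncated of trailing silence, its
#' columns are averaged into `n_time_bins` equal time bins, and the Pearson
#' correlations between all unordered distinct pairs of the binned
#' frequency-power vectors are averaged. Index near 0 means a stationary
#' sound; values above 1 indicate anticorrelated frequency content across
#' time (the index lives in \[0, 2\]).
#'
#' @param waveform numeric samples.
#' @param sample_rate_hz sampling rate in Hz.
#' @param n_time_bins number of equal time bins (default 20).
#' @param window_samples spectrogram window length (default 1024).
#' @param silence_frac trailing frames with broadband power below this
#'   fraction of the peak frame power are treated as silence and dropped.
#' @return scalar modulation index.
#' @export
spectrotemporal_modulation_index <- function(waveform, sample_rate_hz,
                                             n_time_bins = 20L,
                                             window_samples = 1024L,
                                             silence_frac = 0.01) {
  sg <- stft_power(waveform, window = as.integer(window_samples))
  frame_pow <- colSums(sg)
  keep_until <- max(which(frame_pow >= silence_frac * max(frame_pow)))
  sg <- sg[, seq_len(keep_until), drop = FALSE]
  n_frames <- ncol(sg)
  if (n_frames < n_time_bins)
    stop("too few spectrogram frames (", n_frames, ") for ", n_time_bins,
         " time bins")
  bin_of <- ceiling(seq_len(n_frames) / n_frames * n_time_bins)
  binned <- vapply(seq_len(n_time_bins),
                   function(b) rowMeans(sg[, bin_of == b, drop = FALSE]),
                   numeric(nrow(sg)))
  sds <- apply(binned, 2, sd)
  if (any(sds == 0)) {
    warning(sum(sds == 0), " constant time-bin vector(s); pairs involving ",
            "them dropped from the correlation average")
  }
  cm <- suppressWarnings(cor(binned))
  vals <- cm[upper.tri(cm)]
  vals <- vals[is.finite(vals)]
  if (length(vals) == 0) stop("no valid time-bin pairs for correlation")
  1 - mean(vals)
}

#' All four complexity metrics for one waveform
#'
#' Convenience wrapper returning occupied bandwidth, spectral entropy,
#' spectrotemporal modulation index and spectral centroid.
#'
#' @inheritParams spectrotemporal_modulation_index
#' @return one-row data.frame with columns `occupied_bandwidth_hz`,
#'   `spectral_entropy_bits`, `modulation_index`, `spectral_centroid_hz`.
#' @export
complexity_metrics <- function(waveform, sample_rate_hz) {
  sp <- compute_power_spectrum(waveform, sample_rate_hz)
  data.frame(
    occupied_bandwidth_hz = occupied_bandwidth(sp),
    spectral_entropy_bits = spectral_entropy(sp),
    modulation_index = spectrotemporal_modulation_index(waveform, sample_rate_hz),
    spectral_centroid_hz = spectral_centroid(sp)
  )
}

#' Complexity metrics for every stimulus in a set
#'
#' @param stimuli a `stimulus_set` (see [make_stimulus_set()]).
#' @return data.frame with one row per stimulus: `label`, `sound_class`,
#'   and the four metric columns.
#' @export
stimulus_set_metrics <- function(stimuli) {
  stopifnot(inherits(stimuli, "stimulus_set"))
  rows <- lapply(seq_along(stimuli$waveforms), function(i) {
    cbind(data.frame(label = stimuli$labels[i],
                     sound_class = stimuli$sound_class[i]),
          complexity_metrics(stimuli$waveforms[[i]], stimuli$sample_rate_hz))
  })
  do.call(rbind, rows)
}

#' Pure tones maximally overlapping a complex-sound spectrum
#'
#' Ranks candidate tone frequencies by the integrated power of the
#' complex-sound spectrum within one third of an octave on either side of
#' each tone, and returns the indices of the `k` tones with the greatest
#' local power. Ties are broken in favour of the lower frequency.
#'
#' @param cxs_spectrum a `caldrift_spectrum` of the complex sound.
#' @param tone_freqs_hz candidate tone frequencies (Hz).
#' @param k number of tones to return.
#' @return integer indices into `tone_freqs_hz`, ordered by decreasing
#'   overlap (ties by lower frequency).
#' @export
overlapping_tone_set <- function(cxs_spectrum, tone_freqs_hz, k) {
  stopifnot(inherits(cxs_spectrum, "caldrift_spectrum"),
            k >= 1, k <= length(tone_freqs_hz))
  local_power <- vapply(tone_freqs_hz, function(f) {
    lo <- f / 2^(1 / 3); hi <- f * 2^(1 / 3)
    sel <- cxs_spectrum$freqs_hz >= lo & cxs_spectrum$freqs_hz <= hi
    sum(cxs_spectrum$power[sel])
  }, numeric(1))
  ord <- order(-local_power, tone_freqs_hz)
  ord[seq_len(k)]
}
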