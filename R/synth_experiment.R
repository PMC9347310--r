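#' Configuration for a synthetic multi-day imaging experiment
#'
#' Defaults emulate the recording protocol the pipeline targets: 3 frames/s
#' galvo imaging, 10 trials per stimulus per session with an interstimulus
#' interval of 1.5 +/- 0.3 s, and 5 daily sessions per focal plane.
#'
#' @param n_neurons number of ROIs per focal plane.
#' @param n_days number of daily sessions (default 5).
#' @param n_trials trials per stimulus per session (default 10).
#' @param frame_rate_hz imaging frame rate (default 3).
#' @param isi_mean_s,isi_jitter_s interstimulus interval mean and SD in
#'   seconds (defaults 1.5 and 0.3).
#' @param frac_responsive probability that a (neuron, stimulus) pair is
#'   responsive on day 1.
#' @param kernel_decay_s calcium transient exponential decay constant in
#'   seconds (default 0.7, GCaMP6f-like at this frame rate).
#' @param noise_sd master variability scale: additive pink trace noise SD in
#'   dF/F units, and trial-to-trial multiplicative amplitude jitter with
#'   sdlog = noise_sd / 2. Zero makes repeated trials bit-identical.
#' @param gain_drift_sd sdlog of the per-neuron day-to-day multiplicative
#'   gain random walk (0 disables gain drift).
#' @param tuning_drift_prob probability per day step that a responsive
#'   (neuron, stimulus) pair remaps (its amplitude is re-drawn). Either a
#'   scalar or a named vector by sound class, e.g. `c(PT = 0.2, CxS = 0.1)`.
#' @param locomotion_rate expected number of locomotion epochs (1-3 s each)
#'   per session.
#' @param baseline_f baseline raw fluorescence in arbitrary units.
#' @param amp_mean_dff median response amplitude in dF/F units.
#' @param amp_sdlog sdlog of the across-pair amplitude distribution.
#' @param seed integer seed; the experiment is bit-identical per seed.
#' @return validated list of class `synth_config`.
#' @export
synth_config <- function(n_neurons = 50L, n_days = 5L, n_trials = 10L,
                         frame_rate_hz = 3, isi_mean_s = 1.5,
                         isi_jitter_s = 0.3, frac_responsive = 0.3,
                         kernel_decay_s = 0.7, noise_sd = 0.1,
                         gain_drift_sd = 0.1, tuning_drift_prob = 0.1,
                         locomotion_rate = 2, baseline_f = 100,
                         amp_mean_dff = 0.4, amp_sdlog = 0.4, seed = 1L) {
  cfg <- list(n_neurons = as.integer(n_neurons), n_days = as.integer(n_days),
              n_trials = as.integer(n_trials), frame_rate_hz = frame_rate_hz,
              isi_mean_s = isi_mean_s, isi_jitter_s = isi_jitter_s,
              frac_responsive = frac_responsive,
              kernel_decay_s = kernel_decay_s, noise_sd = noise_sd,
              gain_drift_sd = gain_drift_sd,
              tuning_drift_prob = tuning_drift_prob,
              locomotion_rate = locomotion_rate, baseline_f = baseline_f,
              amp_mean_dff = amp_mean_dff, amp_sdlog = amp_sdlog,
              seed = as.integer(seed))
  with(cfg, {
    stopifnot(n_neurons >= 1, n_days >= 1, n_trials >= 1, frame_rate_hz > 0,
              isi_mean_s > 0, isi_jitter_s >= 0,
              frac_responsive >= 0, frac_responsive <= 1,
              kernel_decay_s > 0, noise_sd >= 0, gain_drift_sd >= 0,
              all(tuning_drift_prob >= 0), all(tuning_drift_prob <= 1),
              locomotion_rate >= 0, baseline_f > 0)
  })
  structure(cfg, class = "synth_config")
}

#' Generate a multi-day synthetic experiment with ground truth
#'
#' Produces one session per day for a single focal plane. Each session holds
#' a neurons x frames raw-fluorescence matrix (baseline `baseline_f` a.u.
#' with pink noise), an event table of pseudorandom stimulus presentations
#' with jittered ISI, a locomotion mask of Poisson-count 1-3 s epochs, and
#' per-ROI quality stats. Responsive (neuron, stimulus) pairs emit calcium
#' transients (one-frame rise, exponential decay) whose day-to-day amplitude
#' evolution follows the returned drift labels: `stable` (constant mean),
#' `gain` (neuron-level multiplicative lognormal gain walk), or `remap`
#' (tuning amplitude re-drawn).
#'
#' @param config a [synth_config()].
#' @param stimuli a `stimulus_set`; only its length and `sound_class` are
#'   used (waveforms are presented, not simulated at the sample level).
#' @return list with `sessions` (list of `session_recording`, one per day)
#'   and `truth`: list with `responsive_mask` (neurons x stimuli x days),
#'   `drift_labels` (neurons x stimuli x (days-1), in
#'   \{"stable","gain","remap"\}), `true_gains` (neurons x days), and
#'   `amps` (neurons x stimuli x days base dF/F amplitudes, gain excluded).
#' @export
make_experiment <- function(config, stimuli) {
  stopifnot(inherits(config, "synth_config"), inherits(stimuli, "stimulus_set"))
  n_stim <- length(stimuli$waveforms)
  classes <- stimuli$sound_class
  drift_p <- config$tuning_drift_prob
  p_stim <- if (!is.null(names(drift_p))) {
    missing_cls <- setdiff(unique(classes), names(drift_p))
    if (length(missing_cls))
      stop("tuning_drift_prob missing class(es): ",
           paste(missing_cls, collapse = ", "))
    unname(drift_p[classes])
  } else rep(drift_p, n_stim)

  with_rng_seed(config$seed, {
    nn <- config$n_neurons; nd <- config$n_days
    resp <- array(FALSE, c(nn, n_stim, nd))
    amps <- array(0, c(nn, n_stim, nd))
    labels <- array("stable", c(nn, n_stim, max(nd - 1, 1)))
    gains <- matrix(1, nn, nd)
    resp[, , 1] <- matrix(runif(nn * n_stim) < config$frac_responsive,
                          nn, n_stim)
    amps[, , 1][resp[, , 1]] <- rlnorm(sum(resp[, , 1]),
                                       log(config$amp_mean_dff),
                                       config$amp_sdlog)
    if (nd > 1) for (d in 2:nd) {
      gains[, d] <- gains[, d - 1] *
        exp(rnorm(nn, 0, config$gain_drift_sd))
      resp[, , d] <- resp[, , d - 1]
      amps[, , d] <- amps[, , d - 1]
      for (s in seq_len(n_stim)) {
        on <- which(resp[, s, d - 1])
        if (!length(on)) next
        remap <- on[runif(length(on)) < p_stim[s]]
        labels[on, s, d - 1] <- if (config$gain_drift_sd > 0) "gain" else "stable"
        if (length(remap)) {
          labels[remap, s, d - 1] <- "remap"
          amps[remap, s, d] <- rlnorm(length(remap),
                                      log(config$amp_mean_dff),
                                      config$amp_sdlog)
        }
      }
    }
    sessions <- lapply(seq_len(nd), function(d)
      simulate_session(config, n_stim,
                       matrix(amps[, , d], nn, n_stim) * gains[, d], d))
    list(sessions = sessions,
         truth = list(responsive_mask = resp,
                      drift_labels = if (nd > 1) labels else NULL,
                      true_gains = gains, amps = amps))
  })
}

# One session: event schedule, per-neuron transient signal, pink noise,
# locomotion mask, nominal ROI stats (the generator emulates ROIs that have
# already passed curation).
simulate_session <- function(config, n_stim, amp_day, day_index) {
  fr <- config$frame_rate_hz
  nn <- config$n_neurons
  stim_order <- sample(rep(seq_len(n_stim), config$n_trials))
  n_ev <- length(stim_order)
  isi <- pmax(0.5, rnorm(n_ev, config$isi_mean_s, config$isi_jitter_s))
  onset_t <- 2 + cumsum(c(0, 0.5 + isi[-n_ev]))
  onset_f <- as.integer(round(onset_t * fr)) + 1L
  n_frames <- max(onset_f) + ceiling((1.5 + 5 * config$kernel_decay_s) * fr) + 5L
  kl <- ceiling(5 * config$kernel_decay_s * fr)
  kernel <- exp(-(seq_len(kl) - 1) / (config$kernel_decay_s * fr))
  traces <- matrix(0, nn, n_frames)
  for (i in seq_len(nn)) {
    sig <- numeric(n_frames)
    for (e in seq_len(n_ev)) {
      a <- amp_day[i, stim_order[e]]
      if (a <= 0) next
      a <- a * exp(rnorm(1, 0, config$noise_sd / 2))
      j <- onset_f[e]:min(onset_f[e] + kl - 1L, n_frames)
      sig[j] <- sig[j] + a * kernel[seq_along(j)]
    }
    noise <- if (config$noise_sd > 0)
      pink_noise(n_frames, config$noise_sd) else numeric(n_frames)
    traces[i, ] <- config$baseline_f * (1 + sig + noise)
  }
  loco <- rep(FALSE, n_frames)
  n_epochs <- rpois(1, config$locomotion_rate)
  if (n_epochs > 0) for (k in seq_len(n_epochs)) {
    start <- sample.int(n_frames, 1)
    len <- ceiling(runif(1, 1, 3) * fr)
    loco[start:min(start + len - 1L, n_frames)] <- TRUE
  }
  structure(list(
    traces = traces, frame_rate_hz = fr,
    events = data.frame(onset_frame = onset_f, stimulus_id = stim_order),
    locomotion_mask = loco, day_index = day_index, plane_id = "plane01",
    roi_stats = data.frame(neuron_id = seq_len(nn),
                           compactness = runif(nn, 0.82, 0.95),
                           skewness = runif(nn, 1.3, 3.0))
  ), class = "session_recording")
}

# 1/f-shaped Gaussian noise normalized to the requested SD.
pink_noise <- function(n, sd_target) {
  x <- rnorm(n)
  sp <- fft(x)
  f <- c(1, seq_len(n - 1))
  f <- pmin(f, n - f + 1)
  sp <- sp / sqrt(f)
  y <- Re(fft(sp, inverse = TRUE)) / n
  y / sd(y) * sd_target
}
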