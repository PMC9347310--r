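# Shared fixtures, built once per test run.

# The default 8 PT + 8 CxS stimulus set and its complexity metrics are used
# by several files; cache them (metric computation does 16 full-length FFTs).
.fixture_env <- new.env(parent = emptyenv())

fixture_stimuli <- function() {
  if (is.null(.fixture_env$stimuli))
    .fixture_env$stimuli <- make_stimulus_set(seed = 1)
  .fixture_env$stimuli
}

fixture_metrics <- function() {
  if (is.null(.fixture_env$metrics))
    .fixture_env$metrics <- stimulus_set_metrics(fixture_stimuli())
  .fixture_env$metrics
}

# Hand-built spectrum object on an arbitrary grid (for unit tests that need
# exact control over bins).
manual_spectrum <- function(freqs_hz, power) {
  structure(list(freqs_hz = freqs_hz, power = power,
                 total_power = sum(power)),
            class = "caldrift_spectrum")
}

# Minimal hand-built session: one trace per neuron given as a matrix,
# events at given onsets.
manual_session <- function(traces, onsets, stimulus_ids,
                           frame_rate_hz = 3, locomotion = NULL,
                           day_index = 1, roi_stats = NULL) {
  traces <- rbind(traces)
  structure(list(
    traces = traces, frame_rate_hz = frame_rate_hz,
    events = data.frame(onset_frame = onsets, stimulus_id = stimulus_ids),
    locomotion_mask = if (is.null(locomotion)) rep(FALSE, ncol(traces))
      else locomotion,
    day_index = day_index, plane_id = "p1",
    roi_stats = if (is.null(roi_stats))
      data.frame(neuron_id = seq_len(nrow(traces)),
                 compactness = 0.9, skewness = 2)
      else roi_stats
  ), class = "session_recording")
}

# Independent enumeration oracle for the two-sided exact rank-sum p-value:
# enumerates every C(n1+n2, n1) assignment of pooled values to group x.
rank_sum_enum_p <- function(x, y) {
  pooled <- c(x, y)
  n1 <- length(x)
  r <- rank(pooled)
  obs <- sum(r[seq_len(n1)])
  subsets <- utils::combn(length(pooled), n1)
  sums <- colSums(matrix(r[subsets], nrow = n1))
  p_lo <- mean(sums <= obs)
  p_hi <- mean(sums >= obs)
  min(1, 2 * min(p_lo, p_hi))
}
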