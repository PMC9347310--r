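#' Relative fluorescence change (dF/F)
#'
#' `(F(t) - F0) / F0` with `F0` the median of the raw fluorescence signal
#' across the session. By construction the median of the returned series
#' is 0 for every valid neuron.
#'
#' @param trace numeric raw fluorescence series (a.u.).
#' @return dF/F series of the same length.
#' @export
dff <- function(trace) {
  stopifnot(all(is.finite(trace)))
  f0 <- median(trace)
  if (f0 <= 0)
    stop("invalid baseline: session median fluorescence is ", f0,
         " (must be positive)", call. = FALSE)
  (trace - f0) / f0
}

#' ROI quality-control mask
#'
#' Keeps a neuron iff its ROI compactness exceeds 0.8 and its full-session
#' dF/F trace skewness exceeds 1.1 (both strict inequalities). Compactness
#' here is circularity, `4*pi*area / perimeter^2` (disk = 1), computed
#' upstream by the segmentation tool. Missing stats drop the neuron.
#'
#' @param roi_stats data.frame with columns `compactness` and `skewness`
#'   (one row per neuron).
#' @param compactness_min,skewness_min thresholds (defaults 0.8 and 1.1).
#' @return logical vector, TRUE = keep.
#' @export
qc_mask <- function(roi_stats, compactness_min = 0.8, skewness_min = 1.1) {
  stopifnot(is.data.frame(roi_stats),
            all(c("compactness", "skewness") %in% names(roi_stats)))
  keep <- roi_stats$compactness > compactness_min &
    roi_stats$skewness > skewness_min
  keep[is.na(keep)] <- FALSE
  keep
}

#' Extract trial-resolved response and prestimulus magnitudes
#'
#' Converts each neuron's trace to dF/F and computes, per presented trial,
#' the mean dF/F over the response window (default 0 to 1.5 s from sound
#' onset) and the prestimulus window (default -1.5 to 0 s). A frame belongs
#' to a window if its start time relative to onset lies in `[a, b)`
#' (half-open, so no frame is counted twice). Trials whose response window
#' overlaps any locomotion-masked frame are excluded (reason "locomotion");
#' trials whose windows run past the session edges are excluded (reason
#' "edge"); neurons with non-positive median fluorescence have all their
#' rows excluded (reason "invalid_f0").
#'
#' @param session a `session_recording`.
#' @param response_window_s half-open window `c(a, b)` in seconds relative
#'   to onset (default `c(0, 1.5)`).
#' @param prestim_window_s analogous prestimulus window (default
#'   `c(-1.5, 0)`).
#' @return data.frame (the trial table): `neuron_id`, `day`, `stimulus_id`,
#'   `trial` (per-stimulus repetition index), `response_mag`, `prestim_mag`,
#'   `excluded` (logical), `reason`.
#' @export
extract_trials <- function(session, response_window_s = c(0, 1.5),
                           prestim_window_s = c(-1.5, 0)) {
  stopifnot(inherits(session, "session_recording"))
  fr <- session$frame_rate_hz
  n_frames <- ncol(session$traces)
  ev <- session$events
  stopifnot(all(ev$onset_frame >= 1), all(ev$onset_frame <= n_frames))
  rel_frames <- function(w) {
    r <- ceiling(w[1] * fr):(ceiling(w[2] * fr) - 1L)
    r[r / fr >= w[1] & r / fr < w[2]]
  }
  resp_rel <- rel_frames(response_window_s)
  pre_rel <- rel_frames(prestim_window_s)
  trial_idx <- stats::ave(seq_len(nrow(ev)), ev$stimulus_id,
                          FUN = seq_along)
  loco <- session$locomotion_mask
  out <- vector("list", nrow(session$traces))
  for (i in seq_len(nrow(session$traces))) {
    d <- tryCatch(dff(session$traces[i, ]), error = function(e) NULL)
    resp <- pre <- rep(NA_real_, nrow(ev))
    excluded <- rep(FALSE, nrow(ev))
    reason <- rep("", nrow(ev))
    if (is.null(d)) {
      excluded[] <- TRUE; reason[] <- "invalid_f0"
    } else {
      for (e in seq_len(nrow(ev))) {
        rf <- ev$onset_frame[e] + resp_rel
        pf <- ev$onset_frame[e] + pre_rel
        if (min(pf) < 1 || max(rf) > n_frames) {
          excluded[e] <- TRUE; reason[e] <- "edge"; next
        }
        resp[e] <- mean(d[rf]); pre[e] <- mean(d[pf])
        if (any(loco[rf])) { excluded[e] <- TRUE; reason[e] <- "locomotion" }
      }
    }
    out[[i]] <- data.frame(neuron_id = i, day = session$day_index,
                           stimulus_id = ev$stimulus_id, trial = trial_idx,
                           response_mag = resp, prestim_mag = pre,
                           excluded = excluded, reason = reason)
  }
  do.call(rbind, out)
}

#' z-score a neuron's trial responses across a day pair
#'
#' To pool response changes across neurons with different response scales,
#' each neuron's trial response magnitudes across the two compared days and
#' all stimuli of the protocol are z-scored together (population-SD
#' denominator, so the transform is deterministic in n). Excluded trials do
#' not contribute to the mean/SD and keep `NA` z-values.
#'
#' @param table trial table rows for one neuron, one protocol, two days.
#' @return the table with an added `response_z` column, or `NULL` (with a
#'   warning) if fewer than 2 usable trials or zero pooled SD.
#' @export
zscore_day_pair <- function(table) {
  use <- !table$excluded & is.finite(table$response_mag)
  x <- table$response_mag[use]
  if (length(x) < 2) {
    warning("fewer than 2 non-excluded trials; neuron-pair skipped")
    return(NULL)
  }
  mu <- mean(x)
  sigma <- sqrt(mean((x - mu)^2))
  if (sigma == 0) {
    warning("zero pooled SD; neuron-pair skipped")
    return(NULL)
  }
  table$response_z <- ifelse(use, (table$response_mag - mu) / sigma, NA_real_)
  table
}
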