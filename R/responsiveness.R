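#' Bootstrap responsiveness test for one (neuron, stimulus, day)
#'
#' The observed statistic is the mean sound-response magnitude across trials
#' minus the mean prestimulus magnitude (pooled over all stimuli of the
#' protocol). The null is built by pooling both sets and randomly
#' relabeling while preserving group sizes, recomputing the mean difference
#' `n_shuffles` times. The response is declared responsive iff the observed
#' difference strictly exceeds the `quantile` (default 97.5%) empirical
#' shuffle quantile AND the magnitude gate passes: the sound magnitude must
#' be at least `1 + margin` times the prestim magnitude when the prestim
#' mean is positive, and simply positive otherwise (median-based dF/F makes
#' prestim means hover around zero, where a literal percentage referent is
#' undefined).
#'
#' @param sound_trials response magnitudes for one stimulus (>= 3 values).
#' @param prestim_pool prestimulus magnitudes of all stimuli of the protocol.
#' @param n_shuffles number of shuffles (default 1000).
#' @param quantile empirical null quantile the observed difference must
#'   strictly exceed (default 0.975, a one-sided 2.5% level).
#' @param margin relative magnitude gate (default 0.10).
#' @param seed optional seed for the shuffles.
#' @return list: `observed_diff`, `shuffle_quantile` (proportion of shuffled
#'   differences strictly below the observed), `margin_pass`, `responsive`.
#' @export
stimulus_responsiveness_test <- function(sound_trials, prestim_pool,
                                         n_shuffles = 1000L,
                                         quantile = 0.975, margin = 0.10,
                                         seed = NULL) {
  if (length(sound_trials) < 3) stop("need at least 3 sound trials")
  if (length(prestim_pool) < 1) stop("prestim pool is empty")
  stopifnot(all(is.finite(sound_trials)), all(is.finite(prestim_pool)))
  m_s <- mean(sound_trials); m_p <- mean(prestim_pool)
  observed <- m_s - m_p
  margin_pass <- if (m_p > 0) m_s >= (1 + margin) * m_p else m_s > 0
  pool <- c(sound_trials, prestim_pool)
  if (length(unique(pool)) == 1L) {
    return(list(observed_diff = observed, shuffle_quantile = 0,
                margin_pass = margin_pass, responsive = FALSE))
  }
  null <- with_rng_seed(seed,
    perm_mean_diff_null(sound_trials, prestim_pool, n_shuffles))
  thresh <- sort(null)[ceiling(quantile * n_shuffles)]
  list(observed_diff = observed,
       shuffle_quantile = mean(null < observed),
       margin_pass = margin_pass,
       responsive = observed > thresh && margin_pass)
}

#' Per-day sound-responsiveness of a neuron
#'
#' A neuron is sound responsive on a day if it is responsive to at least one
#' stimulus under a Bonferroni-tightened criterion: the per-stimulus shuffle
#' quantile threshold becomes `1 - (1 - quantile) / n_stimuli` (for 8
#' stimuli at the default level, 0.996875), evaluated on the empirical null
#' CDF position of the observed difference, together with the magnitude
#' gate.
#'
#' @param results list of per-stimulus results from
#'   [stimulus_responsiveness_test()] (one per stimulus).
#' @param n_stimuli number of stimuli tested (Bonferroni denominator).
#' @param quantile the uncorrected per-stimulus level (default 0.975).
#' @return logical.
#' @export
sound_responsive <- function(results, n_stimuli, quantile = 0.975) {
  stopifnot(length(results) >= 1, n_stimuli >= 1)
  thr <- 1 - (1 - quantile) / n_stimuli
  any(vapply(results, function(r)
    r$margin_pass && r$shuffle_quantile > thr, logical(1)))
}
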