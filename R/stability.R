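#' Cross-day change shuffle test for one (neuron, stimulus, day pair)
#'
#' The observed change is the absolute difference of mean z-scored response
#' magnitudes between the two days. The null pools the trials of both days,
#' relabels them preserving per-day counts, and recomputes the absolute
#' mean difference `n_shuffles` times. The change is significant iff the
#' observed value strictly exceeds the `quantile` (default 95%) empirical
#' shuffle quantile AND the relative magnitude of change,
#' `|m2 - m1| / max(|m1|, |m2|)`, is at least `margin` (the symmetric
#' referent keeps the gate invariant to day order).
#'
#' @param day1_trials,day2_trials z-scored response magnitudes (>= 3 each).
#' @param n_shuffles number of shuffles (default 1000).
#' @param quantile empirical null quantile (default 0.95).
#' @param margin relative magnitude-of-change gate (default 0.10).
#' @param seed optional seed.
#' @return list: `significant`, `observed_change`, `shuffle_quantile`
#'   (proportion of shuffled absolute differences strictly below the
#'   observed), `margin_pass`.
#' @export
cross_day_change_test <- function(day1_trials, day2_trials,
                                  n_shuffles = 1000L, quantile = 0.95,
                                  margin = 0.10, seed = NULL) {
  if (length(day1_trials) < 3 || length(day2_trials) < 3)
    stop("need at least 3 trials per day")
  stopifnot(all(is.finite(day1_trials)), all(is.finite(day2_trials)))
  m1 <- mean(day1_trials); m2 <- mean(day2_trials)
  observed <- abs(m2 - m1)
  denom <- max(abs(m1), abs(m2))
  margin_pass <- denom > 0 && observed / denom >= margin
  pool <- c(day1_trials, day2_trials)
  if (length(unique(pool)) == 1L) {
    return(list(significant = FALSE, observed_change = observed,
                shuffle_quantile = 0, margin_pass = margin_pass))
  }
  null <- with_rng_seed(seed,
    perm_mean_diff_null(day1_trials, day2_trials, n_shuffles,
                        absolute = TRUE))
  thresh <- sort(null)[ceiling(quantile * n_shuffles)]
  list(significant = observed > thresh && margin_pass,
       observed_change = observed,
       shuffle_quantile = mean(null < observed),
       margin_pass = margin_pass)
}

#' Percentage of significant response changes
#'
#' `100 * (number of included sound responses with a significant change) /
#' (number of included sound responses)`, where a response is included if
#' the neuron was sound responsive on at least one of the two compared days.
#'
#' @param records data.frame of change records with logical columns
#'   `included` and `significant`.
#' @return percentage in \[0, 100\].
#' @export
percent_changed <- function(records) {
  stopifnot(is.data.frame(records),
            all(c("included", "significant") %in% names(records)))
  n_inc <- sum(records$included)
  if (n_inc == 0) stop("no included records: percent changed undefined")
  100 * sum(records$significant & records$included) / n_inc
}

#' Did a neuron change significantly across a day pair?
#'
#' TRUE iff the neuron shows a significant change to at least one stimulus
#' under a Bonferroni-tightened quantile `1 - (1 - quantile) / n_stimuli`,
#' evaluated on each record's empirical null CDF position, with the
#' magnitude gate.
#'
#' @param records one neuron's change records for one day pair: data.frame
#'   with `shuffle_quantile` and `margin_pass` columns.
#' @param n_stimuli Bonferroni denominator.
#' @param quantile uncorrected level (default 0.95).
#' @return logical.
#' @export
neuron_changed <- function(records, n_stimuli, quantile = 0.95) {
  stopifnot(is.data.frame(records), n_stimuli >= 1)
  thr <- 1 - (1 - quantile) / n_stimuli
  any(records$margin_pass & records$shuffle_quantile > thr)
}

#' Euclidean distance between two response profiles
#'
#' `sqrt(sum_i (x_i - y_i)^2)` over the per-stimulus mean (z-scored)
#' response magnitudes of a neuron on two days, in a fixed stimulus order.
#'
#' @param p1,p2 numeric vectors of equal length.
#' @return non-negative scalar.
#' @export
profile_euclidean_distance <- function(p1, p2) {
  if (length(p1) != length(p2))
    stop("profiles have different lengths (", length(p1), " vs ",
         length(p2), ")")
  stopifnot(all(is.finite(p1)), all(is.finite(p2)))
  sqrt(sum((p1 - p2)^2))
}

#' Enumerate day pairs by interval
#'
#' For `n_days` sessions, interval `k` contains all pairs `(d, d + k)`;
#' with 5 days that is four 1-day, three 2-day, two 3-day and one 4-day
#' pair.
#'
#' @param n_days number of days (default 5).
#' @return named list; element `"k"` is a matrix with columns `d1`, `d2`.
#' @export
interval_pairs <- function(n_days = 5L) {
  stopifnot(n_days >= 2)
  out <- lapply(seq_len(n_days - 1), function(k) {
    d1 <- seq_len(n_days - k)
    cbind(d1 = d1, d2 = d1 + k)
  })
  names(out) <- as.character(seq_len(n_days - 1))
  out
}
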