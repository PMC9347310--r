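#' Run the full cross-day stability analysis on a set of sessions
#'
#' Sequences preprocessing, responsiveness, cross-day change testing,
#' response-profile drift, and day-by-stimulus ANOVA for every protocol
#' (sound class) and every day-pair interval, then computes the group-level
#' comparisons between protocols.
#'
#' Stages, per protocol: (1) trial extraction with locomotion/edge
#' exclusion and ROI quality gates; (2) per (neuron, day, stimulus)
#' bootstrap responsiveness on raw dF/F magnitudes and per (neuron, day)
#' Bonferroni sound-responsiveness; (3) for every day pair, per-neuron
#' z-scoring across the pair, per-stimulus change shuffle tests (a response
#' enters if it was responsive on at least one of the two days), Bonferroni
#' neuron-level change, Euclidean profile distances, and interaction ANOVA
#' with omega squared (neurons sound-responsive on at least one day); (4)
#' per (protocol, interval) aggregation pooling all pairs of the interval
#' with repetitions.
#'
#' @param sessions list of `session_recording`, one per day.
#' @param sound_class character vector giving the sound class ("PT"/"CxS")
#'   of each stimulus id.
#' @param n_shuffles shuffles for both shuffle tests (default 1000).
#' @param resp_quantile responsiveness null quantile (default 0.975).
#' @param change_quantile change-test null quantile (default 0.95).
#' @param margin relative magnitude gate for both tests (default 0.10).
#' @param seed integer seed driving all shuffles.
#' @param apply_qc apply the compactness/skewness ROI gates (default TRUE).
#' @return list of class `caldrift_analysis`: `trial_table`,
#'   `responsiveness`, `sound_responsive`, `records` (change records),
#'   `neuron_change`, `distances`, `anova`, `summary` (per protocol x
#'   interval), `group` (between-protocol statistics), `params`.
#' @export
analyze_experiment <- function(sessions, sound_class, n_shuffles = 1000L,
                               resp_quantile = 0.975,
                               change_quantile = 0.95, margin = 0.10,
                               seed = 1L, apply_qc = TRUE) {
  stopifnot(length(sessions) >= 1,
            all(vapply(sessions, inherits, logical(1), "session_recording")))
  n_days <- length(sessions)
  tt <- do.call(rbind, lapply(sessions, extract_trials))
  qc <- do.call(rbind, lapply(sessions, function(s)
    data.frame(neuron_id = s$roi_stats$neuron_id, day = s$day_index,
               keep = if (apply_qc) qc_mask(s$roi_stats) else
                 rep(TRUE, nrow(s$roi_stats)))))
  with_rng_seed(seed, {
    resp <- responsiveness_stage(tt, qc, sound_class, n_shuffles,
                                 resp_quantile, margin)
    sr <- sound_responsive_stage(resp, sound_class, resp_quantile)
    pair_res <- day_pair_stage(tt, resp, sr, qc, sound_class, n_days,
                               n_shuffles, change_quantile, margin)
    summary_df <- summarize_analysis(pair_res, sound_class)
    group <- group_statistics(pair_res, summary_df)
  })
  structure(list(trial_table = tt, responsiveness = resp,
                 sound_responsive = sr, records = pair_res$records,
                 neuron_change = pair_res$neuron_change,
                 distances = pair_res$distances, anova = pair_res$anova,
                 summary = summary_df, group = group,
                 params = list(n_shuffles = n_shuffles,
                               resp_quantile = resp_quantile,
                               change_quantile = change_quantile,
                               margin = margin, seed = seed)),
            class = "caldrift_analysis")
}

# Stage 2: per (neuron, day, stimulus) responsiveness on raw magnitudes.
responsiveness_stage <- function(tt, qc, sound_class, n_shuffles,
                                 quantile, margin) {
  ok <- tt[!tt$excluded & is.finite(tt$response_mag), ]
  acc <- list(); ai <- 0L
  for (chunk in split(ok, list(ok$day, ok$neuron_id), drop = TRUE)) {
    d <- chunk$day[1]; n <- chunk$neuron_id[1]
    if (!any(qc$keep[qc$neuron_id == n & qc$day == d])) next
    for (proto in unique(sound_class)) {
      stims <- which(sound_class == proto)
      sub <- chunk[chunk$stimulus_id %in% stims, ]
      if (!nrow(sub)) next
      pre <- sub$prestim_mag[is.finite(sub$prestim_mag)]
      if (!length(pre)) next
      for (s in stims) {
        st <- sub$response_mag[sub$stimulus_id == s]
        if (length(st) < 3) next
        r <- stimulus_responsiveness_test(st, pre, n_shuffles, quantile,
                                          margin)
        ai <- ai + 1L
        acc[[ai]] <- c(n, d, s, r$observed_diff, r$shuffle_quantile,
                       r$margin_pass, r$responsive)
      }
    }
  }
  if (!length(acc)) return(empty_resp_df())
  m <- do.call(rbind, acc)
  data.frame(neuron_id = m[, 1], day = m[, 2], stimulus_id = m[, 3],
             protocol = sound_class[m[, 3]], observed_diff = m[, 4],
             shuffle_quantile = m[, 5], margin_pass = as.logical(m[, 6]),
             responsive = as.logical(m[, 7]))
}

empty_resp_df <- function() {
  data.frame(neuron_id = integer(), day = integer(), stimulus_id = integer(),
             protocol = character(), observed_diff = numeric(),
             shuffle_quantile = numeric(), margin_pass = logical(),
             responsive = logical())
}

# Stage 2b: Bonferroni sound-responsiveness per (neuron, day, protocol).
sound_responsive_stage <- function(resp, sound_class, quantile) {
  if (!nrow(resp)) {
    return(data.frame(neuron_id = integer(), day = integer(),
                      protocol = character(), responsive = logical()))
  }
  groups <- split(resp, list(resp$neuron_id, resp$day, resp$protocol),
                  drop = TRUE)
  rows <- lapply(groups, function(g) {
    n_stim <- sum(sound_class == g$protocol[1])
    results <- lapply(seq_len(nrow(g)), function(i)
      list(margin_pass = g$margin_pass[i],
           shuffle_quantile = g$shuffle_quantile[i]))
    data.frame(neuron_id = g$neuron_id[1], day = g$day[1],
               protocol = g$protocol[1],
               responsive = sound_responsive(results, n_stim, quantile))
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

# Stage 3: every day pair of every interval, per protocol.
day_pair_stage <- function(tt, resp, sr, qc, sound_class, n_days,
                           n_shuffles, quantile, margin) {
  records <- list(); neuron_change <- list(); dists <- list(); anova <- list()
  ri <- ni <- di <- vi <- 0L
  resp_key <- paste(resp$neuron_id, resp$day, resp$stimulus_id)
  resp_flag <- stats::setNames(resp$responsive, resp_key)
  sr_key <- paste(sr$neuron_id, sr$day, sr$protocol)
  sr_flag <- stats::setNames(sr$responsive, sr_key)
  qc_key <- paste(qc$neuron_id, qc$day)
  qc_flag <- stats::setNames(qc$keep, qc_key)
  tt_by_neuron <- split(tt, tt$neuron_id)
  if (n_days < 2) {
    return(list(records = NULL, neuron_change = NULL, distances = NULL,
                anova = NULL))
  }
  ivs <- interval_pairs(n_days)
  for (k in names(ivs)) {
    pm <- ivs[[k]]
    for (r in seq_len(nrow(pm))) {
      d1 <- pm[r, 1]; d2 <- pm[r, 2]
      for (proto in unique(sound_class)) {
        stims <- which(sound_class == proto)
        for (nid in names(tt_by_neuron)) {
          n <- as.integer(nid)
          if (!isTRUE(qc_flag[paste(n, d1)]) ||
              !isTRUE(qc_flag[paste(n, d2)])) next
          sr1 <- isTRUE(sr_flag[paste(n, d1, proto)])
          sr2 <- isTRUE(sr_flag[paste(n, d2, proto)])
          if (!sr1 && !sr2) next
          sub <- tt_by_neuron[[nid]]
          sub <- sub[sub$day %in% c(d1, d2) & sub$stimulus_id %in% stims, ]
          z <- suppressWarnings(zscore_day_pair(sub))
          if (is.null(z)) next
          zok <- z[!z$excluded & is.finite(z$response_z), ]
          prof1 <- prof2 <- rep(NA_real_, length(stims))
          rec_rows <- list(); rr <- 0L
          for (si in seq_along(stims)) {
            s <- stims[si]
            x1 <- zok$response_z[zok$day == d1 & zok$stimulus_id == s]
            x2 <- zok$response_z[zok$day == d2 & zok$stimulus_id == s]
            if (length(x1)) prof1[si] <- mean(x1)
            if (length(x2)) prof2[si] <- mean(x2)
            if (length(x1) < 3 || length(x2) < 3) next
            ct <- cross_day_change_test(x1, x2, n_shuffles, quantile, margin)
            included <- isTRUE(resp_flag[paste(n, d1, s)]) ||
              isTRUE(resp_flag[paste(n, d2, s)])
            rr <- rr + 1L
            rec_rows[[rr]] <- data.frame(
              neuron_id = n, stimulus_id = s, protocol = proto,
              d1 = d1, d2 = d2, interval_days = d2 - d1,
              observed_change = ct$observed_change,
              shuffle_quantile = ct$shuffle_quantile,
              margin_pass = ct$margin_pass, included = included,
              significant = ct$significant && included)
          }
          if (rr) {
            rec <- do.call(rbind, rec_rows)
            ri <- ri + 1L; records[[ri]] <- rec
            inc <- rec[rec$included, , drop = FALSE]
            ni <- ni + 1L
            neuron_change[[ni]] <- data.frame(
              neuron_id = n, protocol = proto, d1 = d1, d2 = d2,
              interval_days = d2 - d1,
              changed = nrow(inc) > 0 &&
                neuron_changed(inc, length(stims), quantile))
          }
          use <- is.finite(prof1) & is.finite(prof2)
          if (sum(use) >= 2) {
            di <- di + 1L
            dists[[di]] <- data.frame(
              neuron_id = n, protocol = proto, d1 = d1, d2 = d2,
              interval_days = d2 - d1,
              distance = profile_euclidean_distance(prof1[use], prof2[use]))
          }
          an <- try_day_stimulus_anova(zok, d1, d2, stims)
          if (!is.null(an)) {
            vi <- vi + 1L
            anova[[vi]] <- data.frame(
              neuron_id = n, protocol = proto, d1 = d1, d2 = d2,
              interval_days = d2 - d1, F_interaction = an$F_interaction,
              p_interaction = an$p_interaction,
              omega_squared = an$omega_squared,
              significant = an$significant)
          }
        }
      }
    }
  }
  bindl <- function(x) if (length(x)) do.call(rbind, x) else NULL
  list(records = bindl(records), neuron_change = bindl(neuron_change),
       distances = bindl(dists), anova = bindl(anova))
}

# ANOVA wrapper: keep stimuli with >= 2 trials in both day cells; skip the
# neuron when fewer than 2 stimuli survive.
try_day_stimulus_anova <- function(zok, d1, d2, stims) {
  counts <- table(factor(zok$day, levels = c(d1, d2)),
                  factor(zok$stimulus_id, levels = stims))
  good <- stims[counts[1, ] >= 2 & counts[2, ] >= 2]
  if (length(good) < 2) return(NULL)
  sub <- zok[zok$stimulus_id %in% good, ]
  tryCatch(day_stimulus_anova(sub$response_z, sub$day, sub$stimulus_id),
           error = function(e) NULL)
}

# Stage 4: per (protocol, interval) aggregation, pooling pairs with
# repetitions.
summarize_analysis <- function(pair_res, sound_class) {
  if (is.null(pair_res$records)) return(NULL)
  rec <- pair_res$records
  rows <- list(); i <- 0L
  for (proto in unique(sound_class)) {
    for (k in sort(unique(rec$interval_days))) {
      rk <- rec[rec$protocol == proto & rec$interval_days == k, ]
      nc <- pair_res$neuron_change
      nc <- nc[nc$protocol == proto & nc$interval_days == k, ]
      dd <- pair_res$distances
      dd <- dd[dd$protocol == proto & dd$interval_days == k, ]
      av <- pair_res$anova
      av <- av[av$protocol == proto & av$interval_days == k, ]
      i <- i + 1L
      rows[[i]] <- data.frame(
        protocol = proto, interval_days = k,
        included = sum(rk$included), changed = sum(rk$significant),
        percent_changed = if (sum(rk$included)) percent_changed(rk) else NA,
        n_neurons = nrow(nc), n_neurons_changed = sum(nc$changed),
        neurons_changed_fraction = if (nrow(nc)) mean(nc$changed) else NA,
        mean_distance = if (nrow(dd)) mean(dd$distance) else NA,
        anova_n = nrow(av),
        anova_prop_significant = if (nrow(av)) mean(av$significant) else NA,
        mean_omega_squared = if (nrow(av)) mean(av$omega_squared) else NA)
    }
  }
  do.call(rbind, rows)
}

# Between-protocol statistics, mirroring the group-level comparisons:
# chi-squared + Fisher on pooled 1-day change counts, two-proportion z on
# 1-day neuron fractions, rank-sum on omega^2, and the multi-interval
# bootstrap proportion test (reference = first protocol alphabetically,
# i.e. CxS when classes are CxS/PT).
group_statistics <- function(pair_res, summary_df) {
  if (is.null(summary_df)) return(NULL)
  protos <- sort(unique(summary_df$protocol))
  if (length(protos) != 2) return(NULL)
  s1 <- summary_df[summary_df$protocol == protos[1], ]
  s2 <- summary_df[summary_df$protocol == protos[2], ]
  out <- list(protocol_order = protos)
  d1 <- s1[s1$interval_days == 1, ]; d2 <- s2[s2$interval_days == 1, ]
  if (nrow(d1) && nrow(d2) && d1$included > 0 && d2$included > 0) {
    tab <- matrix(c(d1$changed, d1$included - d1$changed,
                    d2$changed, d2$included - d2$changed), 2, 2,
                  byrow = TRUE)
    if (all(rowSums(tab) > 0) && all(colSums(tab) > 0)) {
      out$change_chi2 <- chi2_2x2(tab)
      out$change_fisher <- fisher_exact_2x2(tab)
    }
    if (d1$n_neurons > 0 && d2$n_neurons > 0) {
      out$neuron_fraction_z <- tryCatch(
        two_proportion_z(d1$n_neurons_changed, d1$n_neurons,
                         d2$n_neurons_changed, d2$n_neurons),
        error = function(e) NULL)
    }
  }
  av <- pair_res$anova
  if (!is.null(av)) {
    o1 <- av$omega_squared[av$protocol == protos[1] & av$interval_days == 1]
    o2 <- av$omega_squared[av$protocol == protos[2] & av$interval_days == 1]
    if (length(o1) && length(o2))
      out$omega_squared_rank_sum <- rank_sum_test(o1, o2)
  }
  ks <- intersect(s1$interval_days, s2$interval_days)
  cats <- merge(s1[s1$interval_days %in% ks,
                   c("interval_days", "included", "changed")],
                s2[s2$interval_days %in% ks,
                   c("interval_days", "included", "changed")],
                by = "interval_days", suffixes = c("_ref", "_test"))
  if (nrow(cats) && all(cats$included_ref > 0)) {
    out$multi_interval_bootstrap_p <- bootstrap_proportion_test(
      data.frame(n_ref = cats$included_ref, k_ref = cats$changed_ref,
                 n_test = cats$included_test, k_test = cats$changed_test),
      n_sims = 10000L)
  }
  out
}
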