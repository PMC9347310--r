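#' Day-by-stimulus two-way ANOVA with interaction effect size
#'
#' Fixed-effects two-way ANOVA of trial response magnitudes on day (2
#' levels) and stimulus identity, with interaction. A significant
#' interaction means the stimuli were differentially modulated across the
#' two days, i.e. the change is stimulus-specific rather than a global gain
#' shift. The effect size of the interaction is Hays' omega squared,
#' `(SS_int - df_int * MS_err) / (SS_total + MS_err)`, which is slightly
#' negative in expectation-free null samples and is invariant to adding a
#' constant to all observations. Balanced designs use the sequential (Type
#' I) decomposition, which is exact there; designs left unbalanced by trial
#' exclusions use Type II sums of squares.
#'
#' @param values numeric trial response magnitudes (typically z-scored).
#' @param day factor-like with exactly 2 levels.
#' @param stimulus factor-like with >= 2 levels.
#' @param alpha significance level for the interaction (default 0.05).
#' @return list: `F_interaction`, `p_interaction`, `omega_squared`,
#'   `significant`, `balanced`.
#' @export
day_stimulus_anova <- function(values, day, stimulus, alpha = 0.05) {
  keep <- is.finite(values)
  values <- values[keep]
  day <- factor(day[keep]); stimulus <- factor(stimulus[keep])
  if (nlevels(day) != 2) stop("need exactly 2 day levels")
  if (nlevels(stimulus) < 2) stop("need at least 2 stimuli")
  counts <- table(day, stimulus)
  if (any(counts < 2))
    stop("empty or singleton (day, stimulus) cell; neuron skipped")
  balanced <- length(unique(counts)) == 1L
  df <- data.frame(y = values, day = day, stimulus = stimulus)
  fit <- stats::aov(y ~ day * stimulus, data = df)
  if (balanced) {
    tab <- summary(fit)[[1]]
    rn <- trimws(rownames(tab))
    ss_int <- tab[rn == "day:stimulus", "Sum Sq"]
    df_int <- tab[rn == "day:stimulus", "Df"]
    f_int <- tab[rn == "day:stimulus", "F value"]
    p_int <- tab[rn == "day:stimulus", "Pr(>F)"]
    ms_err <- tab[rn == "Residuals", "Sum Sq"] / tab[rn == "Residuals", "Df"]
  } else {
    tab <- car::Anova(fit, type = 2)
    rn <- trimws(rownames(tab))
    ss_int <- tab[rn == "day:stimulus", "Sum Sq"]
    df_int <- tab[rn == "day:stimulus", "Df"]
    f_int <- tab[rn == "day:stimulus", "F value"]
    p_int <- tab[rn == "day:stimulus", "Pr(>F)"]
    ms_err <- tab[rn == "Residuals", "Sum Sq"] / tab[rn == "Residuals", "Df"]
  }
  ss_total <- sum((values - mean(values))^2)
  omega2 <- (ss_int - df_int * ms_err) / (ss_total + ms_err)
  list(F_interaction = f_int, p_interaction = p_int,
       omega_squared = omega2, significant = p_int < alpha,
       balanced = balanced)
}
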