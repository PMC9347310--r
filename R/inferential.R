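#' Pearson chi-squared test on a 2x2 table (no continuity correction)
#'
#' @param table 2x2 matrix of counts (rows = group, cols = outcome), or the
#'   four counts `a, b, c, d` row-wise via `as_table_2x2()`.
#' @return list: `statistic` (df = 1), `p`.
#' @export
chi2_2x2 <- function(table) {
  table <- as_table_2x2(table)
  if (any(rowSums(table) == 0) || any(colSums(table) == 0))
    stop("zero margin: chi-squared undefined, use fisher_exact_2x2()")
  ht <- suppressWarnings(stats::chisq.test(table, correct = FALSE))
  list(statistic = unname(ht$statistic), p = unname(ht$p.value))
}

#' Fisher's exact test with sample odds ratio
#'
#' Reports the sample odds ratio `(a*d) / (b*c)` (0 or Inf when a zero cell
#' makes it degenerate) along with the two-sided exact p-value and the
#' conditional exact confidence interval from [stats::fisher.test()] (whose
#' odds-ratio estimate, the conditional MLE, is also returned).
#'
#' @inheritParams chi2_2x2
#' @return list: `odds_ratio` (sample), `p`, `ci`, `conditional_mle`.
#' @export
fisher_exact_2x2 <- function(table) {
  table <- as_table_2x2(table)
  ht <- stats::fisher.test(table)
  a <- table[1, 1]; b <- table[1, 2]; c <- table[2, 1]; d <- table[2, 2]
  or <- if (b * c == 0) {
    if (a * d == 0) NaN else Inf
  } else (a * d) / (b * c)
  list(odds_ratio = or, p = unname(ht$p.value),
       ci = unname(ht$conf.int), conditional_mle = unname(ht$estimate))
}

as_table_2x2 <- function(x) {
  if (is.data.frame(x)) x <- as.matrix(x)
  if (is.matrix(x)) {
    stopifnot(identical(dim(x), c(2L, 2L)))
  } else {
    stopifnot(length(x) == 4)
    x <- matrix(x, 2, 2, byrow = TRUE)
  }
  stopifnot(all(x >= 0), all(x == round(x)))
  x
}

#' Two-proportion z test (pooled variance)
#'
#' `z = (p1 - p2) / sqrt(p(1-p)(1/n1 + 1/n2))` with `p` the pooled
#' proportion. The one-sided p-value is taken in the direction of the
#' observed difference; the two-sided value is also returned.
#'
#' @param k1,n1 successes and trials in group 1.
#' @param k2,n2 successes and trials in group 2.
#' @return list: `z`, `p_one_sided`, `p_two_sided`.
#' @export
two_proportion_z <- function(k1, n1, k2, n2) {
  stopifnot(n1 > 0, n2 > 0, k1 >= 0, k1 <= n1, k2 >= 0, k2 <= n2)
  p_pool <- (k1 + k2) / (n1 + n2)
  if (p_pool %in% c(0, 1))
    stop("pooled proportion is ", p_pool, ": z undefined")
  z <- (k1 / n1 - k2 / n2) /
    sqrt(p_pool * (1 - p_pool) * (1 / n1 + 1 / n2))
  list(z = z, p_one_sided = stats::pnorm(-abs(z)),
       p_two_sided = 2 * stats::pnorm(-abs(z)))
}

#' Wilcoxon rank-sum test reporting the rank-sum statistic
#'
#' Returns the rank sum of sample `x` in the pooled (midrank) ranking. The
#' two-sided p-value is exact (full null enumeration via the Wilcoxon
#' distribution) when both samples have at most `exact_max` values and
#' there are no ties; otherwise a normal approximation with tie correction
#' is used.
#'
#' @param x,y numeric samples.
#' @param exact_max largest per-group size for the exact null (default 12).
#' @return list: `rank_sum_x`, `U` (Mann-Whitney statistic of `x`), `p`,
#'   `exact` (logical).
#' @export
rank_sum_test <- function(x, y, exact_max = 12L) {
  if (!length(x) || !length(y)) stop("empty sample")
  n1 <- length(x); n2 <- length(y)
  r <- rank(c(x, y))
  w <- sum(r[seq_len(n1)])
  u <- w - n1 * (n1 + 1) / 2
  ties <- anyDuplicated(c(x, y)) > 0
  if (!ties && max(n1, n2) <= exact_max) {
    p_lo <- stats::pwilcox(u, n1, n2)
    p_hi <- stats::pwilcox(u - 1, n1, n2, lower.tail = FALSE)
    p <- min(1, 2 * min(p_lo, p_hi))
    exact <- TRUE
  } else {
    mu <- n1 * n2 / 2
    tie_tab <- table(r)
    n <- n1 + n2
    sigma2 <- n1 * n2 / 12 * (n + 1 - sum(tie_tab^3 - tie_tab) / (n * (n - 1)))
    z <- (u - mu) / sqrt(sigma2)
    p <- 2 * stats::pnorm(-abs(z))
    exact <- FALSE
  }
  list(rank_sum_x = w, U = u, p = p, exact = exact)
}

#' Multi-category bootstrap proportion test
#'
#' For each category, draws `k* ~ Binomial(n_test, k_ref / n_ref)` per
#' simulation round; under the joint rule (`rule = "all"`) a round is
#' extreme iff the simulated proportion is at least the observed test-group
#' proportion in every category, and the p-value is the fraction of extreme
#' rounds. `rule = "mean"` instead compares the across-category mean
#' simulated proportion to the mean observed proportion.
#'
#' @param categories data.frame with columns `n_ref`, `k_ref`, `n_test`,
#'   `k_test` (one row per category).
#' @param n_sims simulation rounds (default 10000).
#' @param seed optional seed.
#' @param rule `"all"` (joint, default) or `"mean"`.
#' @return p-value in \[0, 1\].
#' @export
bootstrap_proportion_test <- function(categories, n_sims = 10000L,
                                      seed = NULL, rule = c("all", "mean")) {
  rule <- match.arg(rule)
  stopifnot(is.data.frame(categories),
            all(c("n_ref", "k_ref", "n_test", "k_test") %in%
                  names(categories)))
  if (any(categories$n_ref == 0)) stop("n_ref must be positive")
  stopifnot(all(categories$k_ref >= 0 & categories$k_ref <= categories$n_ref),
            all(categories$k_test >= 0 &
                  categories$k_test <= categories$n_test))
  p_ref <- categories$k_ref / categories$n_ref
  p_obs <- categories$k_test / categories$n_test
  nc <- nrow(categories)
  with_rng_seed(seed, {
    sims <- matrix(stats::rbinom(n_sims * nc, categories$n_test, p_ref),
                   nrow = nc) / categories$n_test
    extreme <- if (rule == "all") {
      colSums(sims >= p_obs) == nc
    } else {
      colMeans(sims) >= mean(p_obs)
    }
    mean(extreme)
  })
}

#' Fisher r-to-z comparison of two correlation coefficients
#'
#' `z = (atanh(r1) - atanh(r2)) / sqrt(1/(n1-3) + 1/(n2-3))`, two-sided
#' normal p-value.
#'
#' @param r1,n1 first correlation and its sample size.
#' @param r2,n2 second correlation and its sample size.
#' @return list: `z`, `p`.
#' @export
fisher_r_compare <- function(r1, n1, r2, n2) {
  stopifnot(abs(r1) < 1, abs(r2) < 1, n1 > 3, n2 > 3)
  z <- (atanh(r1) - atanh(r2)) / sqrt(1 / (n1 - 3) + 1 / (n2 - 3))
  list(z = z, p = 2 * stats::pnorm(-abs(z)))
}
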