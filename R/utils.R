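#' @keywords internal
"_PACKAGE"

# Evaluate `expr` under a temporary RNG state seeded with `seed`; the caller's
# RNG stream is untouched. seed = NULL runs expr on the current stream.
with_rng_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  expr
}

# Deterministic sub-seed derivation; stays inside 32-bit integer range.
derive_seed <- function(seed, offset) {
  as.integer((as.numeric(seed) * 48271 + as.numeric(offset)) %% 2147483647)
}

# Permutation null for the difference of group means. Pools x and y, relabels
# preserving group sizes (without replacement within each shuffle) and returns
# n_shuffles mean differences (group-1 mean minus group-2 mean), optionally in
# absolute value. Vectorised over shuffles: one sample.int per shuffle, means
# computed by column sums.
perm_mean_diff_null <- function(x, y, n_shuffles, absolute = FALSE) {
  pool <- c(x, y)
  n1 <- length(x)
  n <- length(pool)
  tot <- sum(pool)
  idx <- vapply(seq_len(n_shuffles), function(i) sample.int(n, n1),
                integer(n1))
  s1 <- .colSums(pool[idx], n1, n_shuffles)
  m1 <- s1 / n1
  m2 <- (tot - s1) / (n - n1)
  d <- m1 - m2
  if (absolute) abs(d) else d
}

# Adjusted Fisher-Pearson sample skewness (the b1 estimator with the
# n-based bias adjustment used by most stats packages).
sample_skewness <- function(x) {
  x <- x[is.finite(x)]
  n <- length(x)
  if (n < 3) return(NA_real_)
  m <- mean(x)
  s <- sqrt(sum((x - m)^2) / (n - 1))
  if (s == 0) return(NA_real_)
  g1 <- sum((x - m)^3) / n / (sum((x - m)^2) / n)^1.5
  g1 * sqrt(n * (n - 1)) / (n - 2)
}
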