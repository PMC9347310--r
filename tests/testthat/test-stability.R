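test_that("cross-day change test detects shifts and not identity", {
  set.seed(2)
  d1 <- rnorm(10)
  r_same <- cross_day_change_test(d1, d1, n_shuffles = 500, seed = 5)
  expect_false(r_same$significant)
  r_shift <- cross_day_change_test(d1, d1 + 10 * sd(d1), n_shuffles = 1000,
                                   seed = 5)
  expect_true(r_shift$significant)
  expect_equal(r_shift$shuffle_quantile, 1)
  # degenerate (all-equal) pools are never significant
  r_deg <- cross_day_change_test(rep(1, 5), rep(1, 5), n_shuffles = 100,
                                 seed = 1)
  expect_false(r_deg$significant)
  # determinism
  expect_identical(cross_day_change_test(d1, d1 + 1, n_shuffles = 300,
                                         seed = 7),
                   cross_day_change_test(d1, d1 + 1, n_shuffles = 300,
                                         seed = 7))
})

test_that("percent changed reproduces the published arithmetic", {
  rec <- function(n_sig, n_inc) data.frame(
    included = rep(TRUE, n_inc),
    significant = rep(c(TRUE, FALSE), c(n_sig, n_inc - n_sig)))
  expect_equal(percent_changed(rec(66, 543)), 12.15, tolerance = 0.005)
  expect_equal(percent_changed(rec(114, 518)), 22.01, tolerance = 0.005)
  expect_equal(percent_changed(rec(0, 100)), 0)
  expect_error(percent_changed(data.frame(included = FALSE,
                                          significant = FALSE)),
               "undefined")
})

test_that("neuron-level change uses the Bonferroni-tightened quantile", {
  rec <- function(q, m = TRUE) data.frame(shuffle_quantile = q,
                                          margin_pass = m)
  expect_false(neuron_changed(rec(c(0.96, 0.9)), 8))   # needs > 0.99375
  expect_true(neuron_changed(rec(c(0.996, 0.2)), 8))
  expect_false(neuron_changed(rec(0.999, m = FALSE), 8))
})

test_that("profile distance is the Euclidean metric", {
  expect_equal(profile_euclidean_distance(c(1, 2, 3), c(1, 2, 3)), 0)
  expect_equal(profile_euclidean_distance(c(0, 0), c(3, 4)), 5)
  set.seed(10)
  p <- rnorm(8); q <- rnorm(8)
  perm <- sample(8)
  expect_equal(profile_euclidean_distance(p, q),
               profile_euclidean_distance(p[perm], q[perm]))
  expect_error(profile_euclidean_distance(1:3, 1:4), "lengths")
  # metric axioms on random triples
  for (i in 1:25) {
    a <- rnorm(8); b <- rnorm(8); c <- rnorm(8)
    dab <- profile_euclidean_distance(a, b)
    dba <- profile_euclidean_distance(b, a)
    expect_equal(dab, dba)
    expect_gte(dab, 0)
    expect_lte(profile_euclidean_distance(a, c),
               dab + profile_euclidean_distance(b, c) + 1e-12)
  }
})

test_that("interval enumeration covers all day pairs", {
  iv <- interval_pairs(5)
  expect_equal(unname(vapply(iv, nrow, integer(1))), c(4, 3, 2, 1))
  expect_equal(iv[["1"]][, "d1"], 1:4)
  expect_equal(iv[["1"]][, "d2"], 2:5)
  expect_equal(unname(iv[["4"]]), matrix(c(1L, 5L), 1))
  expect_equal(nrow(interval_pairs(2)[["1"]]), 1)
})

test_that("null cross-day change rate respects its nominal level", {
  set.seed(77)
  fp <- vapply(1:300, function(i) {
    x <- rnorm(10); y <- rnorm(10)
    z <- (c(x, y) - mean(c(x, y))) / sd(c(x, y))
    cross_day_change_test(z[1:10], z[11:20], n_shuffles = 300)$significant
  }, logical(1))
  se <- sqrt(0.05 * 0.95 / 300)
  expect_lte(mean(fp), 0.05 + 3 * se)
})
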