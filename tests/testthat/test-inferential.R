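test_that("chi-squared on the published count tables matches the printed values", {
  r1 <- chi2_2x2(matrix(c(66, 477, 114, 404), 2, byrow = TRUE))
  expect_equal(r1$statistic, 18.27, tolerance = 0.005)
  r2 <- chi2_2x2(matrix(c(34, 207, 59, 197), 2, byrow = TRUE))
  expect_equal(r2$statistic, 6.52, tolerance = 0.005)
  expect_equal(chi2_2x2(matrix(c(10, 90, 10, 90), 2))$statistic, 0)
  expect_error(chi2_2x2(matrix(c(0, 0, 5, 5), 2, byrow = TRUE)), "margin")
})

test_that("chi-squared equals the squared two-proportion z statistic", {
  set.seed(14)
  for (i in 1:20) {
    n1 <- sample(20:200, 1); n2 <- sample(20:200, 1)
    k1 <- sample(1:(n1 - 1), 1); k2 <- sample(1:(n2 - 1), 1)
    tab <- matrix(c(k1, n1 - k1, k2, n2 - k2), 2, byrow = TRUE)
    expect_equal(chi2_2x2(tab)$statistic,
                 two_proportion_z(k1, n1, k2, n2)$z^2, tolerance = 1e-10)
  }
})

test_that("Fisher's exact reports the sample odds ratio", {
  r1 <- fisher_exact_2x2(matrix(c(66, 477, 114, 404), 2, byrow = TRUE))
  expect_equal(r1$odds_ratio, 0.4903, tolerance = 5e-4)
  r2 <- fisher_exact_2x2(matrix(c(34, 207, 59, 197), 2, byrow = TRUE))
  expect_equal(r2$odds_ratio, 0.55, tolerance = 0.005)
  rs <- fisher_exact_2x2(matrix(c(5, 5, 5, 5), 2))
  expect_equal(rs$odds_ratio, 1)
  expect_equal(rs$p, 1)
  expect_equal(fisher_exact_2x2(matrix(c(0, 5, 5, 5), 2,
                                       byrow = TRUE))$odds_ratio, 0)
})

test_that("two-proportion z matches the published statistic and hand cases", {
  r <- two_proportion_z(36, 241, 54, 256)
  expect_equal(r$z, -1.7811, tolerance = 5e-4)
  expect_equal(two_proportion_z(20, 100, 20, 100)$z, 0)
  # hand computation: pooled p = 0.5, z = -1 / sqrt(0.5*0.5*(1/10+1/10))
  expect_equal(two_proportion_z(0, 10, 10, 10)$z, -1 / sqrt(0.05))
  expect_error(two_proportion_z(0, 10, 0, 10), "undefined")
})

test_that("rank-sum statistic and exact p match the enumeration oracle", {
  # complete separation, n = 8 each
  r_lo <- rank_sum_test(1:8, 11:18)
  expect_equal(r_lo$rank_sum_x, 36)
  expect_equal(r_lo$p, 2 / 12870)
  r_hi <- rank_sum_test(11:18, 1:8)
  expect_equal(r_hi$rank_sum_x, 100)
  # oracle equivalence across sample sizes up to 8
  set.seed(19)
  for (n1 in c(2, 4, 6, 8)) for (n2 in c(3, 5, 8)) {
    x <- rnorm(n1); y <- rnorm(n2, 0.5)
    r <- rank_sum_test(x, y)
    expect_true(r$exact)
    expect_equal(r$p, rank_sum_enum_p(x, y), tolerance = 1e-12)
  }
  # ties fall back to the midrank normal approximation
  rt <- rank_sum_test(c(1, 2, 2, 3), c(2, 4, 5, 6))
  expect_false(rt$exact)
  expect_true(rt$p > 0 && rt$p <= 1)
})

test_that("bootstrap proportion test honours its boundary and symmetry cases", {
  one <- function(k_ref, n_ref, k_test, n_test)
    data.frame(n_ref = n_ref, k_ref = k_ref, n_test = n_test,
               k_test = k_test)
  # matched proportions at 0.5: p concentrates near the binomial
  # point-mass-inclusive tail, ~0.5
  p_mid <- bootstrap_proportion_test(one(500, 1000, 250, 500),
                                     n_sims = 10000, seed = 3)
  expect_equal(p_mid, 0.5, tolerance = 0.05)
  expect_equal(bootstrap_proportion_test(one(0, 100, 5, 100), seed = 1), 0)
  expect_equal(bootstrap_proportion_test(one(100, 100, 50, 100), seed = 1), 1)
  # determinism and monotonicity in the observed count
  p_prev <- 1.01
  for (k in c(40, 50, 60)) {
    p_k <- bootstrap_proportion_test(one(50, 100, k, 100), n_sims = 5000,
                                     seed = 11)
    expect_lt(p_k, p_prev)
    p_prev <- p_k
  }
  expect_identical(bootstrap_proportion_test(one(30, 90, 40, 80), seed = 7),
                   bootstrap_proportion_test(one(30, 90, 40, 80), seed = 7))
})

test_that("multi-category bootstrap requires joint extremity", {
  cats <- data.frame(n_ref = c(100, 100), k_ref = c(50, 50),
                     n_test = c(100, 100), k_test = c(95, 5))
  # one category far above, one far below the reference: jointly extreme
  # rounds are rare even though one margin alone is common
  p <- bootstrap_proportion_test(cats, n_sims = 5000, seed = 2)
  expect_lt(p, 0.01)
  p_mean <- bootstrap_proportion_test(cats, n_sims = 5000, seed = 2,
                                      rule = "mean")
  expect_gt(p_mean, 0.2)  # the mean rule sees an average near reference
})

test_that("Fisher r-to-z comparison follows the closed form", {
  r0 <- fisher_r_compare(0.4, 50, 0.4, 80)
  expect_equal(r0$z, 0)
  expect_equal(r0$p, 1)
  ra <- fisher_r_compare(0.5, 100, 0.1, 60)
  rb <- fisher_r_compare(0.1, 60, 0.5, 100)
  expect_equal(ra$z, -rb$z)
  expect_equal(ra$p, rb$p)
  expect_equal(fisher_r_compare(0.5, 100, 0, 100)$z,
               atanh(0.5) / sqrt(2 / 97))
  expect_error(fisher_r_compare(1, 10, 0, 10), "abs")
})
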