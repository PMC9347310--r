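test_that("dF/F uses the session median and is scale invariant", {
  expect_equal(dff(c(90, 100, 110)), c(-0.1, 0, 0.1))
  expect_equal(dff(rep(100, 10)), rep(0, 10))
  tr <- rlnorm(50, log(100), 0.1)
  expect_equal(dff(tr), dff(2 * tr))
  expect_equal(median(dff(tr)), 0)
  expect_error(dff(c(-5, -1, 0)), "median")
})

test_that("QC gates are strict inequalities on compactness and skewness", {
  stats <- data.frame(compactness = c(0.9, 0.8, 0.9, 0.7, NA),
                      skewness = c(2.0, 2.0, 1.1, 2.0, 2.0))
  expect_identical(qc_mask(stats), c(TRUE, FALSE, FALSE, FALSE, FALSE))
})

test_that("trial extraction windows, exclusions and conservation hold", {
  # 3 fps; constant baseline 100 except a plateau of 120 covering the
  # response window of the second event
  n_frames <- 120
  tr <- rep(100, n_frames)
  onsets <- c(31, 61, 118)  # third event runs past the session edge
  tr[61:65] <- 120
  loco <- rep(FALSE, n_frames); loco[33] <- TRUE  # one frame of trial 1
  s <- manual_session(matrix(tr, 1), onsets, c(1, 1, 2), locomotion = loco)
  tt <- extract_trials(s)
  expect_equal(nrow(tt), 3)  # one row per presented trial per neuron
  expect_true(tt$excluded[1])
  expect_equal(tt$reason[1], "locomotion")
  # frames 61..65 are exactly the [0, 1.5) s window of onset 61
  expect_false(tt$excluded[2])
  expect_equal(tt$response_mag[2], 0.2)
  expect_equal(tt$prestim_mag[2], 0)
  expect_true(tt$excluded[3])
  expect_equal(tt$reason[3], "edge")
})

test_that("trial table is conserved for a generated session", {
  st <- fixture_stimuli()
  cfg <- synth_config(n_neurons = 4, n_days = 1, seed = 2)
  ex <- make_experiment(cfg, st)
  tt <- extract_trials(ex$sessions[[1]])
  expect_equal(nrow(tt), 4 * nrow(ex$sessions[[1]]$events))
  expect_true(all(tt$excluded | (is.finite(tt$response_mag) &
                                   is.finite(tt$prestim_mag))))
})

test_that("day-pair z-scoring pools both days with a population SD", {
  tab <- data.frame(response_mag = c(1, 1, 3, 3), excluded = FALSE)
  z <- zscore_day_pair(tab)
  expect_equal(z$response_z, c(-1, -1, 1, 1))
  set.seed(3)
  tab2 <- data.frame(response_mag = rnorm(40), excluded = FALSE)
  z2 <- zscore_day_pair(tab2)$response_z
  expect_equal(mean(z2), 0)
  expect_equal(sqrt(mean(z2^2)), 1)
  expect_warning(out <- zscore_day_pair(
    data.frame(response_mag = rep(2, 6), excluded = FALSE)), "zero")
  expect_null(out)
})

test_that("shuffle-test decisions are invariant to affine response rescaling", {
  set.seed(9)
  d1 <- rnorm(10); d2 <- rnorm(10, 1)
  pool_z <- function(a, b) {
    x <- c(a, b); mu <- mean(x); s <- sqrt(mean((x - mu)^2))
    list((a - mu) / s, (b - mu) / s)
  }
  z_raw <- pool_z(d1, d2)
  z_aff <- pool_z(5 + 3 * d1, 5 + 3 * d2)
  r1 <- cross_day_change_test(z_raw[[1]], z_raw[[2]], n_shuffles = 200,
                              seed = 42)
  r2 <- cross_day_change_test(z_aff[[1]], z_aff[[2]], n_shuffles = 200,
                              seed = 42)
  expect_identical(r1$significant, r2$significant)
  expect_equal(r1$observed_change, r2$observed_change)
})
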