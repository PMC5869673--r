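test_that("population draws have the requested mean and are reproducible", {
  ages <- sample_population(5, 1e6, seed = 1)
  expect_true(all(ages >= 0))
  expect_lt(abs(mean(ages) - 5), 0.02)
  expect_identical(ages, sample_population(5, 1e6, seed = 1))
  expect_length(sample_population(3, 1, seed = 2), 1L)
})

test_that("mean-age estimation is the sample mean with sane intervals", {
  const <- estimate_mean_age(rep(5, 40), method = "nonparametric", seed = 1)
  expect_equal(const$estimate, 5)
  expect_equal(const$upper - const$lower, 0)

  withr::local_seed(2)
  obs <- rexp(1e4, 1 / 7) + rnorm(1e4, 0, 2)
  est <- estimate_mean_age(obs, seed = 3)
  se <- sqrt((7^2 + 2^2) / 1e4)
  expect_lt(abs(est$estimate - 7), 3 * se)
  expect_true(est$lower <= est$estimate && est$estimate <= est$upper)

  w <- vapply(c(50, 400), function(n) {
    e <- estimate_mean_age(sample_population(5, n, seed = n), seed = 4)
    e$upper - e$lower
  }, numeric(1))
  expect_lt(w[2], w[1])
  expect_error(estimate_mean_age(numeric(0)), "size error")
})

test_that("a noise-free surrogate contributes exactly zero uncertainty share", {
  d <- decompose_uncertainty(5, 50, surrogate(0, 1, 0, 0),
                             replicates = 2000, seed = 5)
  expect_equal(d$nirs_share, 0)
  expect_equal(d$total_width, d$sampling_width)
})

test_that("decomposition share decreases with training size and mean age", {
  pl <- power_law(0.44, 34.81)
  shares <- vapply(c(100, 2000), function(ntr) {
    decompose_uncertainty(5, 100, surrogate_from_training_size(pl, ntr),
                          replicates = 8000, seed = 6)$nirs_share
  }, numeric(1))
  expect_gt(shares[1], shares[2])

  by_age <- vapply(c(3, 7), function(mu) {
    decompose_uncertainty(mu, 100, surrogate_from_training_size(pl, 500),
                          replicates = 8000, seed = 7)$nirs_share
  }, numeric(1))
  expect_gt(by_age[1], by_age[2])
})

test_that("sample-size search is monotone in the mean-age gap", {
  sur <- surrogate_from_training_size(power_law(0.44, 34.81), 430)
  n_far <- min_sample_size_to_distinguish(3, 7, sur, replicates = 2000,
                                          seed = 8)
  n_near <- min_sample_size_to_distinguish(5, 7, sur, replicates = 2000,
                                           seed = 8)
  expect_lt(n_far, n_near)
  expect_message(
    same <- min_sample_size_to_distinguish(5, 5, sur),
    "identical means"
  )
  expect_true(is.na(same))
  n_z <- min_sample_size_to_distinguish(3, 7, sur, replicates = 1000,
                                        criterion = "z_test", seed = 9)
  expect_true(is.finite(n_z))
})

test_that("proportion-old matches the exponential closed form but is noise-biased", {
  expect_equal(proportion_old(c(3, 3, 3)), 0)
  ages <- sample_population(5, 1e6, seed = 10)
  expect_lt(abs(proportion_old(ages) - exp(-7 / 5)), 0.002)

  # measurement noise biases the proportion while the mean stays unbiased
  noised <- simulate_predictions(surrogate(0, 1, 3, 0), ages, seed = 11,
                                 floor = FALSE)
  expect_lt(abs(mean(noised) - 5), 0.02)
  expect_gt(abs(proportion_old(noised) - exp(-7 / 5)), 0.01)
})
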