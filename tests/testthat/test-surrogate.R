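test_that("an exact predictor yields the identity surrogate", {
  withr::local_seed(1)
  age <- runif(200, 0, 20)
  m <- fit_surrogate(age, age, draws = 0)
  expect_lt(abs(m$alpha), 0.1)
  expect_equal(m$beta, 1, tolerance = 0.02)
  expect_lt(m$sigma0, 0.1)
})

test_that("generating parameters are recovered from a large sample", {
  withr::local_seed(2)
  age <- runif(2000, 0, 20)
  pred <- 0.5 + 0.9 * age + rnorm(2000, 0, 0.5 + 0.1 * age)
  m <- fit_surrogate(age, pred, seed = 3)
  td <- tidy(m)
  truth <- c(alpha = 0.5, beta = 0.9, sigma0 = 0.5, sigma1 = 0.1)
  expect_true(all(td$conf_low <= truth & truth <= td$conf_high))
  expect_true(glance(m)$heteroscedastic)
})

test_that("simulation honours the degenerate and stochastic regimes", {
  m0 <- surrogate(alpha = 1, beta = 0.8, sigma0 = 0, sigma1 = 0)
  ages <- c(0, 5, 10)
  expect_equal(simulate_predictions(m0, ages, seed = 1), 1 + 0.8 * ages)

  m <- surrogate(alpha = 0.5, beta = 0.9, sigma0 = 0.5, sigma1 = 0.1)
  draws <- simulate_predictions(m, rep(5, 1e5), seed = 2, floor = FALSE)
  mu <- 0.5 + 0.9 * 5
  s <- 0.5 + 0.1 * 5
  expect_lt(abs(mean(draws) - mu), 3 * s / sqrt(1e5))
  expect_lt(abs(stats::sd(draws) / s - 1), 0.02)

  spread_young <- stats::sd(simulate_predictions(m, rep(2, 2e4), seed = 3))
  spread_old <- stats::sd(simulate_predictions(m, rep(15, 2e4), seed = 3))
  expect_gt(spread_old, spread_young)

  expect_error(simulate_predictions(list(), 1:3), "state error")
  expect_error(
    simulate_predictions(m, 1:3, mode = "posterior"),
    "no posterior draws"
  )
})

test_that("posterior predictive bands achieve near-nominal coverage", {
  withr::local_seed(4)
  age <- runif(1500, 0, 20)
  pred <- 0.3 + 0.95 * age + rnorm(1500, 0, 0.6 + 0.08 * age)
  m <- fit_surrogate(age, pred, draws = 0)
  hold_age <- runif(2000, 0, 20)
  hold_pred <- 0.3 + 0.95 * hold_age + rnorm(2000, 0, 0.6 + 0.08 * hold_age)
  mu <- m$alpha + m$beta * hold_age
  s <- m$sigma0 + m$sigma1 * hold_age
  covered <- mean(abs(hold_pred - mu) <= 1.96 * s)
  expect_gt(covered, 0.92)
  expect_lt(covered, 0.98)
})

test_that("training-set size maps to measurement SD through the power law", {
  fit <- power_law(0.44, 34.81)
  m <- surrogate_from_training_size(fit, 300)
  expect_equal(m$sigma0, 0.44 + 34.81 / sqrt(300), tolerance = 1e-12)
  expect_equal(m$sigma0, 2.45, tolerance = 0.01)
  expect_equal(m$alpha, 0)
  expect_equal(m$beta, 1)
  m_inf <- surrogate_from_training_size(fit, 1e12)
  expect_equal(m_inf$sigma0, 0.44, tolerance = 1e-4)
})
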