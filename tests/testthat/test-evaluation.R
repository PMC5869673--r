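test_that("rmse matches its definition", {
  expect_equal(rmse(c(1, 2, 3), c(1, 2, 3)), 0)
  expect_equal(rmse(c(3, 4), c(0, 0)), sqrt(12.5))
  expect_error(rmse(1:3, 1:4), "shape error")
  withr::local_seed(1)
  a <- rnorm(50)
  b <- rnorm(50)
  brute <- sqrt(sum((a - b)^2) / 50)
  expect_equal(rmse(a, b), brute)
})

test_that("the power law is recovered exactly from noiseless data", {
  x <- c(25, 50, 100, 200, 400, 800)
  y <- 1 + 10 / sqrt(x)
  fit <- fit_power_law(x, y)
  expect_equal(fit$a, 1, tolerance = 1e-4)
  expect_equal(fit$b, 10, tolerance = 1e-4)

  flat <- fit_power_law(c(50, 100, 200), rep(2.5, 3))
  expect_equal(flat$b, 0)
  expect_equal(flat$a, 2.5)
  expect_error(fit_power_law(c(50, 50, 100), c(1, 1, 1)), "fit error")
})

test_that("power-law fits scale linearly with the error scale", {
  withr::local_seed(2)
  x <- c(50, 100, 200, 400)
  y <- 0.5 + 20 / sqrt(x) + rnorm(4, 0, 0.05)
  f1 <- fit_power_law(x, y)
  f3 <- fit_power_law(x, 3 * y)
  expect_equal(f3$a, 3 * f1$a, tolerance = 1e-8)
  expect_equal(f3$b, 3 * f1$b, tolerance = 1e-8)
})

test_that("predicted RMSE shows square-root diminishing returns", {
  fit <- power_law(0.44, 34.81)
  expect_equal(predicted_rmse(fit, 500), 0.44 + 34.81 / sqrt(500),
               tolerance = 1e-12)
  expect_equal(predicted_rmse(fit, 500), 1.9967, tolerance = 1e-3)
  expect_equal(predicted_rmse(power_law(2, 0), c(10, 1000)), c(2, 2))
  gain_small <- predicted_rmse(fit, 200) - predicted_rmse(fit, 400)
  gain_large <- predicted_rmse(fit, 800) - predicted_rmse(fit, 1600)
  expect_lt(gain_large, gain_small)
})

test_that("learning curves are reproducible and improve with size", {
  ds <- signal_ds(n = 280, seed = 17, step = 25)
  lc1 <- learning_curve(ds, sizes = 60, replicates = 1,
                        cv = cv_config(n_bootstrap = 4), seed = 5)
  lc2 <- learning_curve(ds, sizes = 60, replicates = 1,
                        cv = cv_config(n_bootstrap = 4), seed = 5)
  expect_identical(lc1$results$rmse, lc2$results$rmse)

  lc <- learning_curve(ds, sizes = c(45, 180), replicates = 6,
                       cv = cv_config(n_bootstrap = 4), seed = 6)
  s <- lc$summary
  expect_lt(s$median_rmse[s$size == 180], s$median_rmse[s$size == 45])
  expect_true(all(s$q25 <= s$median_rmse & s$median_rmse <= s$q75))
  expect_error(
    learning_curve(ds, sizes = 5000, replicates = 1, seed = 1),
    "size error"
  )
})
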