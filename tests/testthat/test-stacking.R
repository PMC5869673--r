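test_that("the stacker recovers an already-perfect base predictor", {
  withr::local_seed(1)
  age <- runif(120, 1, 20)
  base <- cbind(age, age + rnorm(120, 0, 4))
  st <- fit_stacker(base, age)
  expect_lt(max(abs(predict(st, base) - age)), 0.05)
})

test_that("a pure-noise base predictor barely hurts the stack", {
  withr::local_seed(2)
  age <- runif(150, 1, 20)
  good <- age + rnorm(150, 0, 0.5)
  junk <- rnorm(150, 10, 5)
  st <- fit_stacker(cbind(good, junk), age)
  stacked_rmse <- rmse(predict(st, cbind(good, junk)), age)
  expect_lt(stacked_rmse, rmse(good, age) * 1.1)
})

test_that("too few rows for the requested smooths is an error", {
  age <- 1:10
  base <- cbind(age, age, age, age)
  expect_error(fit_stacker(base, age), "configuration error")
})

test_that("bias correction is near-identity on unbiased input", {
  withr::local_seed(3)
  age <- runif(200, 1, 20)
  bc <- fit_bias_correction(age, age)
  expect_lt(max(abs(predict(bc, age) - age)), 0.2)
})

test_that("bias correction inverts an affine distortion on noiseless data", {
  withr::local_seed(4)
  age <- runif(200, 1, 20)
  raw <- 0.5 * age + 2.5
  bc <- fit_bias_correction(raw, age)
  expect_lt(rmse(predict(bc, raw), age), 0.3)
})

test_that("bias correction recovers truth under monotone distortions", {
  withr::local_seed(5)
  age <- runif(300, 1, 20)
  for (g in list(function(a) 0.6 * a + 3,
                 function(a) 2 * sqrt(a) + 0.2 * a,
                 function(a) 12 * a / (6 + a))) {
    raw <- g(age)
    bc <- fit_bias_correction(raw, age)
    expect_lt(rmse(predict(bc, raw), age), 0.5)
  }
})

test_that("the corrector is monotone and extends linearly with decile balance", {
  withr::local_seed(6)
  age <- runif(400, 1, 20)
  raw <- 0.7 * age + 2 + rnorm(400, 0, 1)
  bc <- fit_bias_correction(raw, age)
  grid_vals <- predict(bc, seq(min(raw), max(raw), length.out = 100))
  expect_true(all(diff(grid_vals) >= -1e-9))
  # calibration: mean residual within each decile of the raw predictions
  corrected <- predict(bc, raw)
  dec <- cut(raw, stats::quantile(raw, seq(0, 1, 0.1)), include.lowest = TRUE)
  dec_bias <- tapply(corrected - age, dec, mean)
  expect_lt(max(abs(dec_bias)), 0.5)
  # linear extension beyond the fitted range
  hi <- max(raw)
  expect_gt(predict(bc, hi + 5), predict(bc, hi))
})

test_that("constant raw predictions yield an identity corrector with warning", {
  expect_warning(
    bc <- fit_bias_correction(rep(4, 50), runif(50, 1, 20)),
    "constant"
  )
  expect_equal(predict(bc, c(1, 9)), c(1, 9))
})

test_that("pipeline fits are deterministic and leak-free", {
  ds <- signal_ds(n = 260, seed = 8, step = 20)
  cv <- cv_config(n_bootstrap = 6, seed = 31)
  sp <- split_spec(seed = 12)
  p1 <- fit_pipeline(ds, "anopheles", split = sp, cv = cv)
  p2 <- fit_pipeline(ds, "anopheles", split = sp, cv = cv)
  expect_identical(predict_age(p1, p1$test), predict_age(p2, p2$test))

  # scrambling the test rows' spectra cannot change the fitted pipeline
  probe <- signal_ds(n = 40, seed = 99, step = 20)
  ds_scrambled <- ds
  test_rows <- p1$split$test
  wl_cols <- as.character(spectra_wavelengths(ds))
  ds_scrambled[test_rows, wl_cols] <-
    ds_scrambled[rev(test_rows), wl_cols]
  p3 <- fit_pipeline(ds_scrambled, "anopheles", split = sp, cv = cv)
  expect_identical(predict_age(p1, probe), predict_age(p3, probe))
})

test_that("the stacker uses one smooth per base model, and predictions behave", {
  ds <- signal_ds(n = 260, seed = 13, step = 20)
  p <- fit_pipeline(ds, "anopheles", split = split_spec(seed = 3),
                    cv = cv_config(n_bootstrap = 6, seed = 7))
  expect_length(p$stacker$cols, 4L) # 3 interval models + wide model
  pred <- predict_age(p, p$test)
  expect_true(all(is.finite(pred)) && all(pred >= 0))
  # batch and row-by-row prediction agree
  one_by_one <- vapply(seq_len(5), function(i) {
    predict_age(p, p$test[i, , drop = FALSE])
  }, numeric(1))
  expect_equal(one_by_one, pred[1:5], tolerance = 1e-10)
  # grid mismatch is a shape error
  expect_error(
    predict_age(p, dplyr::select(p$test, !"1850")),
    "shape error"
  )
})

test_that("bias correction flattens the error-versus-age slope", {
  ds <- signal_ds(n = 320, seed = 21, step = 20)
  p <- fit_pipeline(ds, "anopheles", split = split_spec(seed = 5),
                    cv = cv_config(n_bootstrap = 6, seed = 9))
  truth <- p$test$age_days
  slope <- function(pred) {
    unname(stats::coef(stats::lm((pred - truth) ~ truth))[2])
  }
  s_raw <- slope(predict_age(p, p$test, correct = FALSE))
  s_cor <- slope(predict_age(p, p$test, correct = TRUE))
  expect_lt(s_raw, 0) # shrinkage: old under-predicted, young over-predicted
  expect_lt(abs(s_cor), abs(s_raw))
})
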