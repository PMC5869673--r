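test_that("generation is deterministic and respects degenerate settings", {
  spec <- synth_spec(n = 20, grid = coarse_grid(50), seed = 7)
  expect_identical(generate_study(spec), generate_study(spec))

  flat <- synth_spec(
    n = 8, grid = coarse_grid(50), ages = rep(5, 8),
    bands = list(signal_band(500, 1100, peak = 0)),
    study_offset_sd = 0, study_gain_sd = 0,
    mosquito_offset_sd = 0, mosquito_gain_sd = 0,
    noise_sd = 0, edge_noise_sd = 0, seed = 3
  )
  ab <- spectra_matrix(generate_study(flat))
  expect_equal(max(apply(ab, 2, stats::sd)), 0)
})

test_that("a noiseless single-band signal is exactly recoverable by PLS", {
  spec <- synth_spec(
    n = 60, grid = coarse_grid(10), ages = 8,
    bands = list(signal_band(700, 1100, peak = 0.002)),
    study_offset_sd = 0, study_gain_sd = 0,
    mosquito_offset_sd = 0, mosquito_gain_sd = 0,
    noise_sd = 0, edge_noise_sd = 0, seed = 11
  )
  ds <- generate_study(spec)
  idx <- bin_intervals(spectra_wavelengths(ds),
                       tibble::tibble(low_nm = 700, high_nm = 1100))[[1]]
  X <- spectra_matrix(ds)[, idx]
  fit <- simpls <- fit_pls(X, ds$age_days, cv_config(n_bootstrap = 5, seed = 1))
  expect_lt(rmse(predict(fit, X, ncomp = 1), ds$age_days), 1e-6)
})

test_that("raising per-mosquito noise raises prediction error", {
  errs <- vapply(c(0.005, 0.08), function(nsd) {
    med <- vapply(1:8, function(s) {
      ds <- signal_ds(n = 120, seed = s, step = 20, noise_sd = nsd,
                      confound_sd = 0)
      parts <- split_train_val_test(ds, split_spec(seed = s))
      fit <- fit_pls(
        spectra_matrix(parts$train), parts$train$age_days,
        cv_config(n_bootstrap = 6, seed = s)
      )
      rmse(predict(fit, spectra_matrix(parts$test)), parts$test$age_days)
    }, numeric(1))
    stats::median(med)
  }, numeric(1))
  expect_gt(errs[2], errs[1])
})

test_that("multi-study concatenation preserves rows and requires one grid", {
  specs <- lapply(1:3, function(i) {
    synth_spec(n = 10 + i, grid = coarse_grid(50), seed = i, study = LETTERS[i])
  })
  ds <- generate_multistudy(specs)
  expect_equal(nrow(ds), sum(11:13))
  expect_setequal(unique(ds$study), c("A", "B", "C"))

  specs[[2]]$grid <- coarse_grid(25)
  expect_error(generate_multistudy(specs), "grid error")
})

test_that("models trained on one study transfer poorly to an offset study", {
  mk <- function(study, seed) {
    s <- synth_spec_study_a(n = 250, grid = coarse_grid(10), seed = seed,
                            study = study)
    s$study_offset_sd <- 0.15
    s
  }
  ds_a <- generate_study(mk("A", 1))
  ds_b <- generate_study(mk("B", 2))
  parts <- split_train_val_test(ds_a, split_spec(seed = 3))
  fit <- fit_pls(
    spectra_matrix(parts$train), parts$train$age_days,
    cv_config(n_bootstrap = 8, seed = 3)
  )
  within_rmse <- rmse(predict(fit, spectra_matrix(parts$test)),
                      parts$test$age_days)
  across_rmse <- rmse(predict(fit, spectra_matrix(ds_b)), ds_b$age_days)
  expect_gt(across_rmse, within_rmse)
})
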