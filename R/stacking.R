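#' Combine base-model predictions with an additive spline stacker
#'
#' One penalised cubic regression spline per base predictor, fitted with
#' `mgcv::gam` (smoothness by GCV). Must be fitted on held-out rows
#' (the validation set), never on the rows the base models were trained on.
#' The basis dimension adapts downward when the validation set is small.
#'
#' @param base_predictions Matrix or data frame, one column per base model.
#' @param true_ages True ages (days), one per row.
#' @param k Basis dimension per smooth term (default 8).
#' @return An object of class `age_stacker`.
#' @export
fit_stacker <- function(base_predictions, true_ages, k = 8) {
  B <- as.matrix(base_predictions)
  m <- ncol(B)
  n <- nrow(B)
  if (n != length(true_ages)) stop("shape error: row/length mismatch")
  if (n < 3 * m + 2) {
    stop(
      "configuration error: ", n, " rows cannot support ", m,
      " smooth terms"
    )
  }
  cols <- paste0("p", seq_len(m))
  df <- stats::setNames(as.data.frame(B), cols)
  df$.age <- true_ages
  terms <- purrr::map_chr(cols, function(cl) {
    uq <- length(unique(df[[cl]]))
    k_use <- max(3, min(k, uq - 1, floor(n / (m + 1)) - 1))
    if (uq < 4) cl else sprintf("s(%s, k = %d)", cl, k_use)
  })
  form <- stats::as.formula(paste(".age ~", paste(terms, collapse = " + ")))
  fit <- mgcv::gam(form, data = df, method = "GCV.Cp")
  structure(
    list(fit = fit, cols = cols, n = n),
    class = "age_stacker"
  )
}

#' @export
predict.age_stacker <- function(object, newdata, ...) {
  B <- as.matrix(newdata)
  if (ncol(B) != length(object$cols)) {
    stop("shape error: expected ", length(object$cols), " base predictions")
  }
  df <- stats::setNames(as.data.frame(B), object$cols)
  as.numeric(mgcv::predict.gam(object$fit, newdata = df))
}

#' Fit a monotone bias-correction map from raw to corrected age
#'
#' Raw stacked predictions systematically over-predict young and
#' under-predict old mosquitoes. The corrector fits a spline of true age on
#' raw prediction (`mgcv::gam`) on the validation set, evaluates it on a
#' fine grid, makes it monotone non-decreasing by isotonic regression, and
#' interpolates linearly; beyond the fitted range it extends linearly with
#' the end slopes (splines extrapolate wildly otherwise).
#'
#' @param raw_predictions Raw (uncorrected) predicted ages (days).
#' @param true_ages Matching true ages (days).
#' @param k Spline basis dimension (default 8).
#' @return An object of class `bias_corrector`. If the raw predictions are
#'   (near-)constant an identity corrector is returned with a warning.
#' @export
fit_bias_correction <- function(raw_predictions, true_ages, k = 8) {
  if (length(raw_predictions) != length(true_ages)) {
    stop("shape error: length mismatch")
  }
  if (length(unique(true_ages)) < 3) {
    stop("size error: need >= 3 distinct true ages")
  }
  if (stats::sd(raw_predictions) < 1e-8) {
    warning("raw predictions are constant; returning identity corrector")
    return(structure(
      list(identity = TRUE, grid = NULL, values = NULL),
      class = "bias_corrector"
    ))
  }
  n <- length(true_ages)
  k_use <- max(3, min(k, length(unique(raw_predictions)) - 1))
  df <- data.frame(raw = raw_predictions, age = true_ages)
  fit <- mgcv::gam(age ~ s(raw, k = k_use), data = df, method = "GCV.Cp")
  grid <- seq(min(raw_predictions), max(raw_predictions), length.out = 201)
  f <- as.numeric(mgcv::predict.gam(fit, newdata = data.frame(raw = grid)))
  mono <- stats::isoreg(grid, f)$yf
  structure(
    list(identity = FALSE, grid = grid, values = mono, n = n),
    class = "bias_corrector"
  )
}

#' @export
predict.bias_corrector <- function(object, newdata, ...) {
  x <- as.numeric(newdata)
  if (isTRUE(object$identity)) return(x)
  g <- object$grid
  v <- object$values
  out <- stats::approx(g, v, xout = x, rule = 2)$y
  # linear extension beyond the fitted range using the end slopes
  ng <- length(g)
  slope_lo <- (v[2] - v[1]) / (g[2] - g[1])
  slope_hi <- (v[ng] - v[ng - 1]) / (g[ng] - g[ng - 1])
  lo <- x < g[1]
  hi <- x > g[ng]
  out[lo] <- v[1] + slope_lo * (x[lo] - g[1])
  out[hi] <- v[ng] + slope_hi * (x[hi] - g[ng])
  out
}

# Fit interval models + wide model on `train`, stacker and corrector on
# `validation`. The workhorse behind fit_pipeline() and learning_curve().
train_pipeline <- function(train, validation, intervals,
                           wide = wide_interval(), cv = cv_config(),
                           wide_cap = 40, stacker_k = 8, genus = NA_character_) {
  wl <- spectra_wavelengths(train)
  Xtr <- spectra_matrix(train)
  Xval <- spectra_matrix(validation)
  ytr <- train$age_days
  yval <- validation$age_days
  iv_idx <- bin_intervals(wl, intervals)
  wide_idx <- bin_intervals(wl, wide)[[1]]
  interval_models <- lapply(iv_idx, function(cols) {
    fit_pls(Xtr[, cols, drop = FALSE], ytr, cv = cv)
  })
  cv_wide <- cv
  cv_wide$component_cap <- as.integer(wide_cap)
  wide_model <- fit_pls(Xtr[, wide_idx, drop = FALSE], ytr, cv = cv_wide)
  base_val <- vapply(seq_along(interval_models), function(i) {
    predict(interval_models[[i]], Xval[, iv_idx[[i]], drop = FALSE])
  }, numeric(nrow(Xval)))
  base_val <- cbind(base_val, predict(wide_model, Xval[, wide_idx, drop = FALSE]))
  stacker <- fit_stacker(base_val, yval, k = stacker_k)
  raw_val <- predict(stacker, base_val)
  corrector <- fit_bias_correction(raw_val, yval)
  structure(
    list(
      interval_models = interval_models,
      wide_model = wide_model,
      intervals = tibble::as_tibble(intervals),
      wide = tibble::as_tibble(wide),
      interval_idx = iv_idx,
      wide_idx = wide_idx,
      wavelengths = wl,
      stacker = stacker,
      corrector = corrector,
      genus = genus,
      n_train = nrow(train),
      n_validation = nrow(validation),
      val_rmse_raw = sqrt(mean((raw_val - yval)^2)),
      val_rmse_corrected = sqrt(mean((predict(corrector, raw_val) - yval)^2))
    ),
    class = "age_pipeline"
  )
}

#' Fit the full interval-PLS age pipeline
#'
#' End-to-end fit: the data are split into inner-train / validation / test
#' partitions ([split_train_val_test()]); PLS models for each wavelength
#' interval (cap 20 components) and for the wide 350--1850 nm spectrum
#' (cap 40) are fitted on the inner-train rows; their validation-set
#' predictions feed the additive spline stacker and the monotone bias
#' corrector, both fitted on validation rows only. Test rows are never
#' touched — the fit is a pure function of the train and validation rows.
#'
#' @param ds A spectral table.
#' @param genus `"anopheles"` or `"aedes"`; selects the interval preset
#'   when `intervals` is `NULL`.
#' @param split A [split_spec()]; the realised split is recorded for audit.
#' @param cv A [cv_config()] for the interval models; the wide model uses
#'   the same bootstrap settings with `wide_cap` components.
#' @param intervals Optional tibble of intervals overriding the preset.
#' @param wide_cap Component cap for the wide-spectrum model.
#' @param stacker_k Spline basis dimension per stacker term.
#' @return An `age_pipeline`; `$split` holds the partition indices and
#'   `$test` the untouched test rows for evaluation.
#' @export
fit_pipeline <- function(ds, genus = c("anopheles", "aedes"),
                         split = split_spec(), cv = cv_config(),
                         intervals = NULL, wide_cap = 40, stacker_k = 8) {
  genus <- match.arg(genus)
  if (is.null(intervals)) intervals <- ipls_intervals(genus)
  parts <- split_train_val_test(ds, split)
  p <- train_pipeline(
    parts$train, parts$validation, intervals,
    cv = cv, wide_cap = wide_cap, stacker_k = stacker_k, genus = genus
  )
  p$split <- parts$indices
  p$split_spec <- split
  p$test <- parts$test
  p
}

#' Predict corrected mosquito ages from spectra
#'
#' Forward pass of a fitted pipeline: per-interval and wide-spectrum PLS
#' predictions, spline stacking, then (optionally) the monotone bias
#' correction. Corrected ages are floored at 0 days.
#'
#' @param pipeline An `age_pipeline` from [fit_pipeline()].
#' @param spectra A spectral table on a grid containing all wavelengths the
#'   pipeline was trained on.
#' @param correct Apply the bias correction (default `TRUE`); `FALSE`
#'   gives the accuracy-only (uncorrected) prediction.
#' @return Numeric vector of predicted ages (days), finite and >= 0.
#' @export
predict_age <- function(pipeline, spectra, correct = TRUE) {
  wl_new <- spectra_wavelengths(spectra)
  pos <- match(pipeline$wavelengths, wl_new)
  if (anyNA(pos)) {
    stop("shape error: spectra lack wavelengths the pipeline needs")
  }
  X <- spectra_matrix(spectra)[, pos, drop = FALSE]
  base <- vapply(seq_along(pipeline$interval_models), function(i) {
    predict(
      pipeline$interval_models[[i]],
      X[, pipeline$interval_idx[[i]], drop = FALSE]
    )
  }, numeric(nrow(X)))
  if (nrow(X) == 1) base <- matrix(base, nrow = 1)
  base <- cbind(
    base,
    predict(pipeline$wide_model, X[, pipeline$wide_idx, drop = FALSE])
  )
  raw <- predict(pipeline$stacker, base)
  out <- if (correct) predict(pipeline$corrector, raw) else raw
  pmax(out, 0)
}

#' @export
predict.age_pipeline <- function(object, newdata, correct = TRUE, ...) {
  predict_age(object, newdata, correct = correct)
}

#' @export
print.age_pipeline <- function(x, ...) {
  cat(sprintf(
    "<age_pipeline> genus %s: %d interval models + wide model, trained on %d rows (validation %d)\n",
    x$genus, length(x$interval_models), x$n_train, x$n_validation
  ))
  cat(sprintf(
    "  validation RMSE: raw %.2f, bias-corrected %.2f days\n",
    x$val_rmse_raw, x$val_rmse_corrected
  ))
  invisible(x)
}

#' @method tidy age_pipeline
#' @export
tidy.age_pipeline <- function(x, ...) {
  iv <- x$intervals
  dplyr::bind_rows(
    tibble::tibble(
      model = paste0("interval_", seq_len(nrow(iv))),
      low_nm = iv$low_nm, high_nm = iv$high_nm,
      ncomp = purrr::map_int(x$interval_models, ~ as.integer(.x$ncomp))
    ),
    tibble::tibble(
      model = "wide", low_nm = x$wide$low_nm, high_nm = x$wide$high_nm,
      ncomp = as.integer(x$wide_model$ncomp)
    )
  )
}

#' @method glance age_pipeline
#' @export
glance.age_pipeline <- function(x, ...) {
  tibble::tibble(
    genus = x$genus,
    n_train = x$n_train,
    n_validation = x$n_validation,
    n_models = length(x$interval_models) + 1L,
    val_rmse_raw = x$val_rmse_raw,
    val_rmse_corrected = x$val_rmse_corrected
  )
}

#' Fit the standard full-spectrum PLS baseline
#'
#' The comparison method: a single PLS model on the whole spectrum with
#' bootstrap-CV component selection and no interval selection, stacking or
#' bias correction. It is fitted on the train and validation rows combined
#' (it has no second-stage model to hold data out for).
#'
#' @param ds A spectral table.
#' @param split A [split_spec()] (only the test partition matters here;
#'   train and validation rows are pooled for fitting).
#' @param cv A [cv_config()]; the default cap is 40 components.
#' @return An object of class `standard_model` with `$test` rows attached.
#' @export
fit_standard <- function(ds, split = split_spec(),
                         cv = cv_config(component_cap = 40)) {
  parts <- split_train_val_test(ds, split)
  train <- dplyr::bind_rows(parts$train, parts$validation)
  X <- spectra_matrix(train)
  fit <- fit_pls(X, train$age_days, cv = cv)
  structure(
    list(
      model = fit,
      wavelengths = spectra_wavelengths(train),
      split = parts$indices,
      test = parts$test,
      n_train = nrow(train)
    ),
    class = "standard_model"
  )
}

#' @export
predict.standard_model <- function(object, newdata, ...) {
  wl_new <- spectra_wavelengths(newdata)
  pos <- match(object$wavelengths, wl_new)
  if (anyNA(pos)) stop("shape error: spectra lack required wavelengths")
  X <- spectra_matrix(newdata)[, pos, drop = FALSE]
  pmax(predict(object$model, X), 0)
}

#' @export
print.standard_model <- function(x, ...) {
  cat(sprintf(
    "<standard_model> full-spectrum PLS, %d components, %d training rows\n",
    x$model$ncomp, x$n_train
  ))
  invisible(x)
}

#' Mean prediction error as a function of true age
#'
#' Summarises systematic bias: mean (predicted - true) within equal-count
#' age bins, over the observed age range only.
#'
#' @param true_ages,predicted_ages Paired ages (days).
#' @param n_bins Number of equal-count age bins (default 10).
#' @return Tibble with `age_mid`, `mean_error`, `n` per bin.
#' @export
bias_curve <- function(true_ages, predicted_ages, n_bins = 10) {
  if (length(true_ages) != length(predicted_ages)) {
    stop("shape error: length mismatch")
  }
  qs <- unique(stats::quantile(true_ages, probs = seq(0, 1, length.out = n_bins + 1)))
  bin <- cut(true_ages, breaks = qs, include.lowest = TRUE)
  tibble::tibble(
    true = true_ages, err = predicted_ages - true_ages, bin = bin
  ) |>
    dplyr::group_by(.data$bin) |>
    dplyr::summarise(
      age_mid = mean(.data$true),
      mean_error = mean(.data$err),
      n = dplyr::n(),
      .groups = "drop"
    ) |>
    dplyr::select(!"bin")
}
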