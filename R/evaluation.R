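#' Root-mean-square error between predicted and true ages
#'
#' @param predicted,true Numeric vectors of equal length (days).
#' @return RMSE in days; 0 iff the vectors are identical.
#' @export
rmse <- function(predicted, true) {
  if (length(predicted) != length(true)) stop("shape error: length mismatch")
  if (length(predicted) < 1) stop("shape error: empty input")
  sqrt(mean((predicted - true)^2))
}

#' Learning curve: pipeline error versus training-set size
#'
#' A fixed test set (`test_frac` of the data) is held out once. For each
#' training size and replicate, that many rows are drawn without
#' replacement from the remaining pool, split 70/30 into inner-train and
#' validation, a full pipeline (interval models + wide model + stacker +
#' bias correction) is fitted, and its RMSE on the fixed test set recorded.
#' Medians and 25%/75% quantiles per size summarise the replicates.
#'
#' @param ds A spectral table.
#' @param sizes Integer training-set sizes; each must fit in the pool.
#' @param replicates Subsample-fit-evaluate cycles per size (default 100).
#' @param genus Interval preset for the pipelines.
#' @param cv A [cv_config()] used inside each pipeline fit; fewer bootstrap
#'   repetitions than the default 25 keep large experiments tractable.
#' @param test_frac Fraction held out as the fixed test set.
#' @param stacker_k Spline basis dimension for the stackers (small
#'   validation sets force it down automatically).
#' @param correct Evaluate bias-corrected (`TRUE`) or raw predictions.
#' @param seed Integer seed; fixes the test set and all subsamples.
#' @return An object of class `learning_curve` with `$results`
#'   (size, replicate, rmse) and `$summary` (median and quartiles per size).
#' @export
learning_curve <- function(ds, sizes, replicates = 100,
                           genus = c("anopheles", "aedes"),
                           cv = cv_config(n_bootstrap = 10),
                           test_frac = 0.3, stacker_k = 6,
                           correct = TRUE, seed = NULL) {
  genus <- match.arg(genus)
  if (replicates < 1) stop("replicates must be >= 1")
  intervals <- ipls_intervals(genus)
  run <- function() {
    n <- nrow(ds)
    test_idx <- sample.int(n, round(n * test_frac))
    test <- ds[test_idx, , drop = FALSE]
    pool <- ds[-test_idx, , drop = FALSE]
    if (any(sizes > nrow(pool))) {
      stop(
        "size error: requested training size exceeds the ",
        nrow(pool), "-row training pool"
      )
    }
    res <- tidyr::expand_grid(size = sizes, replicate = seq_len(replicates))
    res$rmse <- purrr::map2_dbl(res$size, res$replicate, function(sz, rep) {
      sub <- pool[sample.int(nrow(pool), sz), , drop = FALSE]
      n_tr <- floor(0.7 * sz)
      ord <- sample.int(sz)
      p <- train_pipeline(
        sub[ord[seq_len(n_tr)], , drop = FALSE],
        sub[ord[-seq_len(n_tr)], , drop = FALSE],
        intervals,
        cv = cv, stacker_k = stacker_k
      )
      rmse(predict_age(p, test, correct = correct), test$age_days)
    })
    res
  }
  results <- if (is.null(seed)) run() else withr::with_seed(seed, run())
  summary <- results |>
    dplyr::group_by(.data$size) |>
    dplyr::summarise(
      median_rmse = stats::median(.data$rmse),
      q25 = stats::quantile(.data$rmse, 0.25),
      q75 = stats::quantile(.data$rmse, 0.75),
      replicates = dplyr::n(),
      .groups = "drop"
    )
  structure(
    list(results = results, summary = summary),
    class = "learning_curve"
  )
}

#' @export
print.learning_curve <- function(x, ...) {
  cat("<learning_curve>\n")
  print(x$summary)
  invisible(x)
}

#' Construct a fitted RMSE-versus-training-size power law directly
#'
#' `predicted RMSE = a + b / sqrt(n)`: `a` is the error asymptote (days)
#' and `b` the scale coefficient (days * sqrt(mosquitoes)). Use this to
#' build the relation from published coefficients; [fit_power_law()]
#' estimates them from a learning curve.
#'
#' @param a Asymptote (days), >= 0.
#' @param b Scale coefficient, >= 0.
#' @param sigma Residual SD of the fit, if known.
#' @return An object of class `power_law_fit`.
#' @export
power_law <- function(a, b, sigma = NA_real_) {
  if (a < 0 || b < 0) stop("a and b must be non-negative")
  structure(
    list(a = a, b = b, sigma = sigma, data = NULL),
    class = "power_law_fit"
  )
}

#' Fit the RMSE-versus-training-size power law
#'
#' Maximum-likelihood fit (Gaussian additive noise, equivalent to least
#' squares on the transformed predictor `1/sqrt(size)`) of
#' `median RMSE = a + b / sqrt(size)`. The square-root decay follows from
#' the central limit theorem: prediction error is dominated by sampling
#' variation in the training data. Coefficients are constrained
#' non-negative so predicted RMSE always decreases with training size.
#'
#' @param sizes Training sizes (>= 3 distinct values), or a
#'   `learning_curve` object (its per-size median RMSEs are used).
#' @param median_rmse Median RMSE per size (days); ignored when `sizes` is
#'   a `learning_curve`.
#' @return A `power_law_fit` with elements `a`, `b`, `sigma` and the
#'   fitted `data`.
#' @export
fit_power_law <- function(sizes, median_rmse = NULL) {
  if (inherits(sizes, "learning_curve")) {
    s <- sizes$summary
    return(fit_power_law(s$size, s$median_rmse))
  }
  x <- as.numeric(sizes)
  y <- as.numeric(median_rmse)
  if (length(unique(x)) < 3) stop("fit error: need >= 3 distinct sizes")
  if (length(x) != length(y)) stop("shape error: length mismatch")
  u <- 1 / sqrt(x)
  cf <- stats::coef(stats::lm(y ~ u))
  a <- unname(cf[1])
  b <- unname(cf[2])
  if (b < 0) {
    b <- 0
    a <- mean(y)
  } else if (a < 0) {
    a <- 0
    b <- sum(u * y) / sum(u^2)
    if (b < 0) b <- 0
  }
  resid <- y - (a + b * u)
  out <- power_law(a, b, sigma = sqrt(mean(resid^2)))
  out$data <- tibble::tibble(size = x, median_rmse = y)
  out
}

#' Predicted RMSE at a given training-set size
#'
#' @param fit A `power_law_fit`.
#' @param n_train Training-set size(s), >= 1.
#' @return Predicted RMSE (days).
#' @export
predicted_rmse <- function(fit, n_train) {
  if (any(n_train < 1)) stop("n_train must be >= 1")
  fit$a + fit$b / sqrt(n_train)
}

#' @export
print.power_law_fit <- function(x, ...) {
  cat(sprintf(
    "<power_law_fit> RMSE = %.3f + %.2f / sqrt(n)  (sigma %.3f)\n",
    x$a, x$b, x$sigma
  ))
  invisible(x)
}

#' @method tidy power_law_fit
#' @export
tidy.power_law_fit <- function(x, ...) {
  tibble::tibble(term = c("a", "b"), estimate = c(x$a, x$b))
}

#' @method glance power_law_fit
#' @export
glance.power_law_fit <- function(x, ...) {
  tibble::tibble(
    a = x$a, b = x$b, sigma = x$sigma,
    n_sizes = if (is.null(x$data)) NA_integer_ else nrow(x$data)
  )
}
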