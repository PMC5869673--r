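#' Draw true ages from an exponentially age-structured population
#'
#' Under constant adult recruitment and age-independent mortality the
#' stationary age distribution is exponential, with mean equal to the
#' average life expectancy; its maximum-likelihood estimator from a random
#' sample is the sample mean.
#'
#' @param mean_age Mean age / life expectancy (days), > 0.
#' @param n Number of mosquitoes sampled, >= 1.
#' @param seed Optional seed (same seed, same draw).
#' @return Numeric vector of `n` non-negative ages (days).
#' @export
sample_population <- function(mean_age, n, seed = NULL) {
  if (mean_age <= 0) stop("mean_age must be > 0")
  if (n < 1) stop("n must be >= 1")
  run <- function() stats::rexp(n, rate = 1 / mean_age)
  if (is.null(seed)) run() else withr::with_seed(seed, run())
}

#' Estimate the mean age of a mosquito population
#'
#' Point estimate is the sample mean (the MLE under the exponential age
#' structure). The default 95% interval is a percentile interval of the
#' estimator's Monte-Carlo sampling distribution: a parametric bootstrap
#' redraws populations from the fitted exponential, adds surrogate
#' measurement noise when a surrogate is supplied, and takes quantiles of
#' the replicate means. `method = "nonparametric"` resamples the observed
#' ages instead (degenerate data give a zero-width interval).
#'
#' @param observed_ages Observed (NIRS-estimated) ages (days), n >= 1.
#' @param surrogate Optional `surrogate_model` describing the measurement
#'   process; its noise is replayed in the parametric bootstrap.
#' @param level Interval coverage (default 0.95).
#' @param replicates Bootstrap replicates (default 2000).
#' @param method `"parametric"` (default) or `"nonparametric"`.
#' @param seed Optional seed.
#' @return One-row tibble: `n`, `estimate`, `lower`, `upper`, `method`,
#'   `replicates`. Lower bound floored at 0 days.
#' @export
estimate_mean_age <- function(observed_ages, surrogate = NULL, level = 0.95,
                              replicates = 2000,
                              method = c("parametric", "nonparametric"),
                              seed = NULL) {
  method <- match.arg(method)
  ages <- as.numeric(observed_ages)
  n <- length(ages)
  if (n < 1) stop("size error: empty input")
  est <- mean(ages)
  probs <- c((1 - level) / 2, 1 - (1 - level) / 2)
  run <- function() {
    if (method == "nonparametric") {
      reps <- matrix(sample(ages, n * replicates, replace = TRUE),
                     replicates, n)
    } else {
      if (est <= 0) {
        return(c(0, 0))
      }
      reps <- matrix(stats::rexp(n * replicates, rate = 1 / est),
                     replicates, n)
      if (!is.null(surrogate)) {
        s <- surrogate$sigma0 + surrogate$sigma1 * reps
        reps <- surrogate$alpha + surrogate$beta * reps +
          stats::rnorm(length(reps), 0, s)
        reps <- pmax(reps, 0)
      }
    }
    stats::quantile(rowMeans(reps), probs)
  }
  ci <- if (is.null(seed)) run() else withr::with_seed(seed, run())
  tibble::tibble(
    n = n, estimate = est,
    lower = max(0, unname(ci[1])), upper = unname(ci[2]),
    method = method, replicates = as.integer(replicates)
  )
}

#' Decompose mean-age uncertainty into sampling and measurement components
#'
#' Monte-Carlo decomposition: the 95% interval width of the mean-age
#' estimator is computed twice over replicate exponential populations —
#' once on the true ages (sampling variability only) and once after
#' passing every age through the surrogate measurement model. The NIRS
#' share is `(total - sampling) / total` by default (`measure = "width"`),
#' with the variance ratio `1 - var_sampling/var_total` as an alternative.
#'
#' @param mean_age True mean population age (days).
#' @param n_sampled Mosquitoes scanned per population sample.
#' @param surrogate A `surrogate_model` for the measurement process.
#' @param replicates Monte-Carlo replicates (>= 1000 recommended).
#' @param measure `"width"` (interval-width ratio, default) or
#'   `"variance"`.
#' @param level Interval coverage (default 0.95).
#' @param floor Floor noised ages at 0 before averaging (default `FALSE`:
#'   the decomposition follows the additive-noise construction of the
#'   measurement process; flooring truncates the noise distribution at
#'   young ages and distorts both the share and the mean).
#' @param seed Optional seed.
#' @return One-row tibble: `total_width`, `sampling_width`, `nirs_share`
#'   (in [0, 1]), `measure`, plus the flooring-induced bias of the mean
#'   (`floor_bias`, days) when it exceeds 0.05 days (otherwise 0).
#' @export
decompose_uncertainty <- function(mean_age, n_sampled, surrogate,
                                  replicates = 10000,
                                  measure = c("width", "variance"),
                                  level = 0.95, floor = FALSE, seed = NULL) {
  measure <- match.arg(measure)
  run <- function() {
    probs <- c((1 - level) / 2, 1 - (1 - level) / 2)
    ages <- matrix(stats::rexp(n_sampled * replicates, rate = 1 / mean_age),
                   replicates, n_sampled)
    sampling_means <- rowMeans(ages)
    s <- surrogate$sigma0 + surrogate$sigma1 * ages
    noised <- surrogate$alpha + surrogate$beta * ages
    if (any(s > 0)) noised <- noised + stats::rnorm(length(ages), 0, s)
    if (floor) noised <- pmax(noised, 0)
    total_means <- rowMeans(noised)
    sw <- unname(diff(stats::quantile(sampling_means, probs)))
    tw <- unname(diff(stats::quantile(total_means, probs)))
    share <- if (measure == "width") {
      if (tw <= 0) 0 else max(0, (tw - sw) / tw)
    } else {
      vt <- stats::var(total_means)
      if (vt <= 0) 0 else max(0, 1 - stats::var(sampling_means) / vt)
    }
    fb <- mean(total_means) -
      (surrogate$alpha + surrogate$beta * mean(sampling_means))
    tibble::tibble(
      mean_age = mean_age, n_sampled = as.integer(n_sampled),
      total_width = tw, sampling_width = sw,
      nirs_share = min(share, 1), measure = measure,
      floor_bias = if (abs(fb) > 0.05) fb else 0
    )
  }
  if (is.null(seed)) run() else withr::with_seed(seed, run())
}

#' Minimum per-group sample size to distinguish two mean ages
#'
#' Grid search over per-group sample sizes. With the default
#' `criterion = "interval_overlap"` the two populations are
#' "distinguishable" at size n when their Monte-Carlo 95% intervals for the
#' estimated mean age (the bands one would plot against n) no longer
#' overlap. `criterion = "z_test"` instead requires a two-sample z-test of
#' the group means to reject at `alpha` in at least `power` of the
#' replicates.
#'
#' @param mean1,mean2 The two true mean ages (days); must differ.
#' @param surrogate A `surrogate_model` for the measurement process.
#' @param grid Candidate per-group sizes (ascending; default 10-500 by 10).
#' @param replicates Monte-Carlo replicates per size (default 4000).
#' @param criterion `"interval_overlap"` (default) or `"z_test"`.
#' @param level Interval coverage for the overlap criterion.
#' @param alpha,power Test size and required power for the z criterion.
#' @param seed Optional seed.
#' @return Smallest grid size meeting the criterion, as an integer;
#'   `NA_integer_` when the means are equal (not achievable) or no grid
#'   size suffices.
#' @export
min_sample_size_to_distinguish <- function(mean1, mean2, surrogate,
                                           grid = seq(10, 500, by = 10),
                                           replicates = 4000,
                                           criterion = c("interval_overlap",
                                                         "z_test"),
                                           level = 0.95, alpha = 0.05,
                                           power = 0.95, seed = NULL) {
  criterion <- match.arg(criterion)
  if (mean1 == mean2) {
    message("identical means can never be distinguished")
    return(NA_integer_)
  }
  lo <- min(mean1, mean2)
  hi <- max(mean1, mean2)
  probs <- c((1 - level) / 2, 1 - (1 - level) / 2)
  draw_groups <- function(mu, n) {
    ages <- matrix(stats::rexp(n * replicates, rate = 1 / mu), replicates, n)
    s <- surrogate$sigma0 + surrogate$sigma1 * ages
    noised <- surrogate$alpha + surrogate$beta * ages
    if (any(s > 0)) noised <- noised + stats::rnorm(length(ages), 0, s)
    noised <- pmax(noised, 0)
    list(
      mean = rowMeans(noised),
      var = apply(noised, 1, stats::var)
    )
  }
  run <- function() {
    for (n in sort(grid)) {
      g_lo <- draw_groups(lo, n)
      g_hi <- draw_groups(hi, n)
      ok <- if (criterion == "interval_overlap") {
        stats::quantile(g_lo$mean, probs[2]) < stats::quantile(g_hi$mean, probs[1])
      } else {
        # per-replicate two-sample z on paired group samples
        z <- abs(g_hi$mean - g_lo$mean) /
          sqrt(g_lo$var / n + g_hi$var / n)
        mean(z > stats::qnorm(1 - alpha / 2)) >= power
      }
      if (isTRUE(ok)) return(as.integer(n))
    }
    NA_integer_
  }
  if (is.null(seed)) run() else withr::with_seed(seed, run())
}

#' Proportion of old mosquitoes in a sample
#'
#' The fraction of ages at or above `threshold_days` (default 7 days, the
#' conventional young/old cut in NIRS studies). Reported alongside mean
#' age for comparison only: unlike the mean, its bias under measurement
#' noise grows with the error of the aging method.
#'
#' @param ages Ages (days), n >= 1.
#' @param threshold_days Young/old threshold (default 7).
#' @return Fraction in [0, 1].
#' @export
proportion_old <- function(ages, threshold_days = 7) {
  if (length(ages) < 1) stop("size error: empty input")
  mean(ages >= threshold_days)
}
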