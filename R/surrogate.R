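#' Weakly informative priors for the surrogate error model
#'
#' @param alpha_sd SD of the Normal(0, .) prior on the intercept (days).
#' @param beta_sd SD of the Normal(1, .) prior on the slope.
#' @param sigma_scale Scale of the half-Normal priors on both noise-scale
#'   parameters.
#' @return A list of class `surrogate_priors`.
#' @export
surrogate_priors <- function(alpha_sd = 5, beta_sd = 1, sigma_scale = 2.5) {
  structure(
    list(alpha_sd = alpha_sd, beta_sd = beta_sd, sigma_scale = sigma_scale),
    class = "surrogate_priors"
  )
}

#' Construct a surrogate measurement model directly
#'
#' The surrogate stands in for "spectrometer + age pipeline": given a true
#' age it returns a predicted age
#' `alpha + beta * age + Normal(0, (sigma0 + sigma1 * age)^2)`.
#' An unbiased pipeline has `alpha = 0`, `beta = 1`; `sigma1 > 0` encodes
#' the increase of measurement spread with age seen in validation scatter.
#'
#' @param alpha Intercept (days).
#' @param beta Slope (unitless).
#' @param sigma0 Noise scale at age 0 (days), > 0 unless `sigma1 = 0` and a
#'   degenerate noise-free surrogate is wanted.
#' @param sigma1 Noise-scale slope (days per day of age), >= 0.
#' @return An object of class `surrogate_model` (no posterior draws).
#' @export
surrogate <- function(alpha = 0, beta = 1, sigma0 = 1, sigma1 = 0) {
  if (sigma0 < 0 || sigma1 < 0) stop("noise scales must be non-negative")
  structure(
    list(
      alpha = alpha, beta = beta, sigma0 = sigma0, sigma1 = sigma1,
      draws = NULL, vcov = NULL, n = NA_integer_, age_range = NULL,
      convergence = NA_integer_
    ),
    class = "surrogate_model"
  )
}

# Negative log posterior in theta = (alpha, beta, log sigma0, log sigma1).
surrogate_nlp <- function(theta, x, y, priors) {
  alpha <- theta[1]
  beta <- theta[2]
  s0 <- exp(theta[3])
  s1 <- exp(theta[4])
  s <- s0 + s1 * x
  nll <- -sum(stats::dnorm(y, alpha + beta * x, s, log = TRUE))
  nlp <- -stats::dnorm(alpha, 0, priors$alpha_sd, log = TRUE) -
    stats::dnorm(beta, 1, priors$beta_sd, log = TRUE) -
    (stats::dnorm(s0, 0, priors$sigma_scale, log = TRUE) + theta[3]) -
    (stats::dnorm(s1, 0, priors$sigma_scale, log = TRUE) + theta[4])
  nll + nlp
}

#' Fit the heteroscedastic surrogate error model
#'
#' Bayesian linear regression of predicted on true age with a noise scale
#' linear in age: `pred ~ Normal(alpha + beta * age, (sigma0 + sigma1 *
#' age)^2)`. The posterior mode is found by penalised maximum likelihood
#' under the [surrogate_priors()], and posterior draws come from a Gaussian
#' (Laplace) approximation around the mode — deterministic diagnostics, and
#' effectively exact at the sample sizes used to validate pipelines.
#'
#' @param true_ages True ages (days), >= 50 values spanning >= 3 distinct
#'   ages.
#' @param predicted_ages Matching pipeline predictions (days).
#' @param priors A [surrogate_priors()].
#' @param draws Number of posterior draws to store (0 for point-only).
#' @param seed Optional seed for the posterior draws.
#' @return A `surrogate_model` with point estimates, the Laplace
#'   variance-covariance matrix, and a tibble of posterior `$draws`.
#' @export
fit_surrogate <- function(true_ages, predicted_ages,
                          priors = surrogate_priors(), draws = 2000,
                          seed = NULL) {
  x <- as.numeric(true_ages)
  y <- as.numeric(predicted_ages)
  if (length(x) != length(y)) stop("shape error: length mismatch")
  if (length(x) < 50) stop("size error: need >= 50 age/prediction pairs")
  if (length(unique(x)) < 3) stop("size error: need >= 3 distinct ages")
  ls_fit <- stats::lm(y ~ x)
  r_sd <- max(stats::sd(stats::resid(ls_fit)), 1e-3)
  init <- unname(c(stats::coef(ls_fit)[1], stats::coef(ls_fit)[2],
                   log(r_sd), log(max(r_sd / (2 * max(x)), 1e-4))))
  opt <- stats::optim(
    init, surrogate_nlp, x = x, y = y, priors = priors,
    method = "L-BFGS-B",
    lower = c(-Inf, -Inf, log(1e-4), log(1e-6)),
    control = list(maxit = 500), hessian = TRUE
  )
  theta <- opt$par
  H <- opt$hessian
  vc <- tryCatch(solve(H), error = function(e) {
    # near-degenerate fits (noise scale at its lower bound) need the
    # pseudo-inverse; the affected directions have essentially zero spread
    MASS::ginv(H + diag(1e-8, 4))
  })
  m <- surrogate(
    alpha = theta[1], beta = theta[2],
    sigma0 = exp(theta[3]), sigma1 = exp(theta[4])
  )
  m$vcov <- vc
  m$n <- length(x)
  m$age_range <- range(x)
  m$convergence <- opt$convergence
  if (m$sigma0 + m$sigma1 * max(x) <= 0) {
    stop("fit error: non-positive noise scale on the fitted age range")
  }
  if (draws > 0) {
    dr <- withr::with_seed(
      if (is.null(seed)) sample.int(.Machine$integer.max, 1) else seed,
      MASS::mvrnorm(draws, mu = theta, Sigma = vc)
    )
    m$draws <- tibble::tibble(
      alpha = dr[, 1], beta = dr[, 2],
      sigma0 = exp(dr[, 3]), sigma1 = exp(dr[, 4])
    )
  }
  m
}

#' @export
print.surrogate_model <- function(x, ...) {
  cat(sprintf(
    "<surrogate_model> pred ~ N(%.3f + %.3f age, (%.3f + %.3f age)^2)%s\n",
    x$alpha, x$beta, x$sigma0, x$sigma1,
    if (is.null(x$draws)) "" else sprintf(" [%d posterior draws]", nrow(x$draws))
  ))
  invisible(x)
}

#' @method tidy surrogate_model
#' @export
tidy.surrogate_model <- function(x, conf_level = 0.95, ...) {
  est <- tibble::tibble(
    term = c("alpha", "beta", "sigma0", "sigma1"),
    estimate = c(x$alpha, x$beta, x$sigma0, x$sigma1)
  )
  if (!is.null(x$draws)) {
    lo <- (1 - conf_level) / 2
    q <- purrr::map(est$term, function(tm) {
      stats::quantile(x$draws[[tm]], c(lo, 1 - lo))
    })
    est$conf_low <- purrr::map_dbl(q, 1)
    est$conf_high <- purrr::map_dbl(q, 2)
  }
  est
}

#' @method glance surrogate_model
#' @export
glance.surrogate_model <- function(x, ...) {
  tibble::tibble(
    n = x$n,
    convergence = x$convergence,
    heteroscedastic = x$sigma1 > 1e-8
  )
}

#' Simulate pipeline predictions for known true ages
#'
#' Draws `alpha + beta * age + Normal(0, (sigma0 + sigma1 * age)^2)`.
#' In `"posterior"` mode one posterior parameter draw is used per call, so
#' repeated calls integrate over parameter uncertainty. Simulated ages are
#' floored at 0 by default; flooring preserves the mean only approximately,
#' so set `floor = FALSE` where strict unbiasedness matters.
#'
#' @param m A `surrogate_model`.
#' @param true_ages Non-negative true ages (days).
#' @param seed Optional seed.
#' @param mode `"point"` (use the stored point estimates) or `"posterior"`.
#' @param floor Floor simulated ages at 0 days (default `TRUE`).
#' @return Numeric vector of simulated predicted ages.
#' @export
simulate_predictions <- function(m, true_ages, seed = NULL,
                                 mode = c("point", "posterior"),
                                 floor = TRUE) {
  mode <- match.arg(mode)
  if (!inherits(m, "surrogate_model")) stop("state error: not a surrogate model")
  if (any(true_ages < 0)) stop("true ages must be >= 0")
  run <- function() {
    par <- if (mode == "posterior") {
      if (is.null(m$draws)) stop("state error: surrogate has no posterior draws")
      as.list(m$draws[sample.int(nrow(m$draws), 1), ])
    } else {
      list(alpha = m$alpha, beta = m$beta, sigma0 = m$sigma0,
           sigma1 = m$sigma1)
    }
    s <- par$sigma0 + par$sigma1 * true_ages
    out <- par$alpha + par$beta * true_ages
    if (any(s > 0)) {
      out <- out + stats::rnorm(length(true_ages), 0, s)
    }
    if (floor) pmax(out, 0) else out
  }
  if (is.null(seed)) run() else withr::with_seed(seed, run())
}

#' Unbiased surrogate implied by a training-set size
#'
#' Builds the homoscedastic surrogate used in population-level power
#' calculations: `alpha = 0`, `beta = 1` and measurement SD equal to the
#' predicted individual-level RMSE at `n_train` from the fitted
#' RMSE-versus-training-size power law ([fit_power_law()] or [power_law()]).
#'
#' @param fit A `power_law_fit`.
#' @param n_train Training-set size, >= 1.
#' @return A `surrogate_model` with `sigma0 = predicted_rmse(fit, n_train)`.
#' @export
surrogate_from_training_size <- function(fit, n_train) {
  surrogate(alpha = 0, beta = 1,
            sigma0 = predicted_rmse(fit, n_train), sigma1 = 0)
}
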