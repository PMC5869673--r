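#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Plot a learning curve with its quantile band
#'
#' Median test RMSE per training size with the 25%/75% quantile ribbon;
#' optionally overlays a fitted RMSE-versus-size power law.
#'
#' @param object A `learning_curve`.
#' @param power_law_fit Optional `power_law_fit` to overlay.
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot learning_curve
#' @export
autoplot.learning_curve <- function(object, power_law_fit = NULL, ...) {
  s <- object$summary
  p <- ggplot2::ggplot(s, ggplot2::aes(x = .data$size, y = .data$median_rmse)) +
    ggplot2::geom_ribbon(
      ggplot2::aes(ymin = .data$q25, ymax = .data$q75),
      fill = "steelblue", alpha = 0.25
    ) +
    ggplot2::geom_point(colour = "steelblue") +
    ggplot2::geom_line(colour = "steelblue") +
    ggplot2::labs(
      x = "Mosquitoes in training set",
      y = "Test RMSE (days)"
    ) +
    ggplot2::theme_minimal()
  if (!is.null(power_law_fit)) {
    gr <- tibble::tibble(size = seq(min(s$size), max(s$size), length.out = 200))
    gr$fit <- predicted_rmse(power_law_fit, gr$size)
    p <- p + ggplot2::geom_line(
      data = gr, ggplot2::aes(y = .data$fit),
      colour = "grey30", linetype = 2
    )
  }
  p
}

#' Plot the fitted power law on its data
#'
#' @param object A `power_law_fit` (must carry fitted data).
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot power_law_fit
#' @export
autoplot.power_law_fit <- function(object, ...) {
  if (is.null(object$data)) stop("power law has no attached data to plot")
  gr <- tibble::tibble(
    size = seq(min(object$data$size), max(object$data$size), length.out = 200)
  )
  gr$fit <- predicted_rmse(object, gr$size)
  ggplot2::ggplot(object$data,
                  ggplot2::aes(x = .data$size, y = .data$median_rmse)) +
    ggplot2::geom_point() +
    ggplot2::geom_line(data = gr, ggplot2::aes(y = .data$fit),
                       colour = "steelblue") +
    ggplot2::labs(x = "Mosquitoes in training set",
                  y = "Median RMSE (days)") +
    ggplot2::theme_minimal()
}

#' Plot a surrogate model's mean line and 95% band over age
#'
#' Shows the heteroscedastic funnel: mean `alpha + beta * age` with the
#' +/- 1.96 sigma(age) band, optionally over a scatter of observed
#' (true, predicted) pairs.
#'
#' @param object A `surrogate_model`.
#' @param true_ages,predicted_ages Optional scatter to underlay.
#' @param age_max Age range to draw when no scatter is given.
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot surrogate_model
#' @export
autoplot.surrogate_model <- function(object, true_ages = NULL,
                                     predicted_ages = NULL, age_max = 25,
                                     ...) {
  amax <- if (!is.null(true_ages)) max(true_ages) else age_max
  gr <- tibble::tibble(age = seq(0, amax, length.out = 200))
  gr$mu <- object$alpha + object$beta * gr$age
  gr$s <- object$sigma0 + object$sigma1 * gr$age
  p <- ggplot2::ggplot(gr, ggplot2::aes(x = .data$age, y = .data$mu)) +
    ggplot2::geom_ribbon(
      ggplot2::aes(ymin = pmax(.data$mu - 1.96 * .data$s, 0),
                   ymax = .data$mu + 1.96 * .data$s),
      fill = "steelblue", alpha = 0.25
    ) +
    ggplot2::geom_line(colour = "steelblue") +
    ggplot2::geom_abline(slope = 1, intercept = 0,
                         colour = "darkorange", linetype = 2) +
    ggplot2::labs(x = "True age (days)", y = "Predicted age (days)") +
    ggplot2::theme_minimal()
  if (!is.null(true_ages) && !is.null(predicted_ages)) {
    sc <- tibble::tibble(age = true_ages, mu = predicted_ages)
    p <- p + ggplot2::geom_point(data = sc, alpha = 0.3, size = 0.8)
  }
  p
}

#' Scatter of predicted versus true age with the identity line
#'
#' The standard accuracy/bias panel: individual age estimates against
#' truth, a smooth trend, and the ideal y = x line.
#'
#' @param true_ages,predicted_ages Paired ages (days).
#' @return A ggplot.
#' @export
plot_age_predictions <- function(true_ages, predicted_ages) {
  df <- tibble::tibble(true = true_ages, predicted = predicted_ages)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$true, y = .data$predicted)) +
    ggplot2::geom_point(alpha = 0.3, colour = "steelblue") +
    ggplot2::geom_smooth(method = "gam", formula = y ~ s(x),
                         colour = "black", se = FALSE) +
    ggplot2::geom_abline(slope = 1, intercept = 0, colour = "darkorange") +
    ggplot2::labs(x = "True age (days)", y = "Predicted age (days)") +
    ggplot2::theme_minimal()
}

#' Plot mean-age interval width against number of mosquitoes sampled
#'
#' Builds the population-level accuracy picture: for each sample size the
#' Monte-Carlo 95% interval of the estimated mean age, with and without
#' measurement noise.
#'
#' @param mean_age True mean age (days).
#' @param sizes Sample sizes to evaluate.
#' @param surrogate A `surrogate_model`.
#' @param replicates Monte-Carlo replicates per size.
#' @param seed Optional seed.
#' @return A ggplot; the underlying tibble is in `$data`.
#' @export
plot_population_intervals <- function(mean_age, sizes, surrogate,
                                      replicates = 4000, seed = NULL) {
  rows <- purrr::map_dfr(sizes, function(n) {
    d <- decompose_uncertainty(mean_age, n, surrogate,
                               replicates = replicates, seed = seed)
    tibble::tibble(
      n = n,
      sampling_half = d$sampling_width / 2,
      total_half = d$total_width / 2
    )
  })
  ggplot2::ggplot(rows, ggplot2::aes(x = .data$n)) +
    ggplot2::geom_ribbon(
      ggplot2::aes(ymin = mean_age - .data$total_half,
                   ymax = mean_age + .data$total_half),
      fill = "darkgreen", alpha = 0.25
    ) +
    ggplot2::geom_ribbon(
      ggplot2::aes(ymin = mean_age - .data$sampling_half,
                   ymax = mean_age + .data$sampling_half),
      fill = "steelblue", alpha = 0.35
    ) +
    ggplot2::geom_hline(yintercept = mean_age, linetype = 2) +
    ggplot2::labs(x = "Mosquitoes sampled", y = "Estimated mean age (days)") +
    ggplot2::theme_minimal()
}
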