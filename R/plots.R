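#' Plot a fitted quantal dose-response curve
#'
#' Shows the observed group proportions with exact binomial 95% confidence
#' intervals and the fitted curve; the BMD/BMDL pair for the given BMR is
#' drawn when requested.
#'
#' @param object A `quantal_fit`.
#' @param bmr Optional benchmark response to annotate with BMD and BMDL.
#' @param n_grid Number of curve evaluation points.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.quantal_fit <- function(object, bmr = NULL, n_grid = 200, ...) {
  d <- object$data
  ci <- purrr::map2(d$affected, d$n, function(x, n) {
    stats::binom.test(x, n)$conf.int
  })
  obs <- tibble(dose = d$dose, p = d$affected / d$n,
                lo = purrr::map_dbl(ci, 1), hi = purrr::map_dbl(ci, 2))
  grid <- tibble(dose = seq(0, max(d$dose), length.out = n_grid))
  grid$p <- predict_prob(object, grid$dose)
  gg <- ggplot2::ggplot(obs, ggplot2::aes(x = .data$dose, y = .data$p)) +
    ggplot2::geom_line(data = grid, colour = "steelblue") +
    ggplot2::geom_pointrange(ggplot2::aes(ymin = .data$lo, ymax = .data$hi)) +
    ggplot2::labs(x = "dose (mg/kg/day)", y = "proportion affected",
                  title = paste0(attr(d, "endpoint") %||% "quantal endpoint",
                                 " - ", object$model$name)) +
    ggplot2::theme_minimal()
  if (!is.null(bmr)) {
    bmd <- compute_bmd(object, bmr)
    bmdl <- compute_bmdl(object, bmr)
    gg <- gg +
      ggplot2::geom_vline(xintercept = c(bmdl, bmd), linetype = c(3, 2)) +
      ggplot2::annotate("text", x = bmd, y = 0.02, hjust = -0.1,
                        label = sprintf("BMD %.3g (BMDL %.3g)", bmd, bmdl))
  }
  gg
}

#' Plot a fitted continuous dose-response curve
#'
#' Group means with +/- SD bars and the fitted mean function.
#'
#' @param object A `continuous_fit`.
#' @param n_grid Number of curve evaluation points.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.continuous_fit <- function(object, n_grid = 200, ...) {
  d <- object$data
  obs <- tibble(dose = d$dose, m = d$mean, lo = d$mean - d$sd, hi = d$mean + d$sd)
  grid <- tibble(dose = seq(0, max(d$dose), length.out = n_grid))
  grid$m <- predict(object, grid$dose)
  ggplot2::ggplot(obs, ggplot2::aes(x = .data$dose, y = .data$m)) +
    ggplot2::geom_line(data = grid, colour = "steelblue") +
    ggplot2::geom_pointrange(ggplot2::aes(ymin = .data$lo, ymax = .data$hi)) +
    ggplot2::labs(x = "dose (mg/kg/day)", y = "response",
                  title = paste0(attr(d, "endpoint") %||% "continuous endpoint",
                                 " - ", object$model$name)) +
    ggplot2::theme_minimal()
}

#' Plot the probabilistic reference-dose chain distributions
#'
#' Densities of the median-human (`HD_M^50%`) and sensitive-human
#' (`HD_M^I`) dose distributions on a log scale, with the 5th percentile of
#' `HD_M^I` marked.
#'
#' @param object A `prfd_result` from [propagate()].
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.prfd_result <- function(object, ...) {
  df <- tidy(object)
  gg <- ggplot2::ggplot(df, ggplot2::aes(x = .data$value,
                                         y = .data$percentile,
                                         group = .data$distribution,
                                         colour = .data$distribution)) +
    ggplot2::geom_point() +
    ggplot2::geom_line(orientation = "y") +
    ggplot2::scale_x_log10() +
    ggplot2::geom_vline(xintercept = object$hd_I_p05, linetype = 2) +
    ggplot2::labs(x = "dose (mg/kg/day, log scale)", y = "percentile",
                  title = "human dose distributions",
                  subtitle = sprintf("P05(HD^%g%%) = %.3g; pRfD = %.2g",
                                     100 * object$incidence, object$hd_I_p05,
                                     object$prfd_reported)) +
    ggplot2::theme_minimal()
  gg
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
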