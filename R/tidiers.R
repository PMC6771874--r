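#' @importFrom generics tidy glance
#' @export
generics::tidy

#' @export
generics::glance

#' Tidy a quantal model fit
#'
#' @param x A `quantal_fit`.
#' @param ... Unused.
#' @return A tibble with one row per parameter (`term`, `estimate`,
#'   `at_bound`). Parameters are on the dose-normalized scale recorded in
#'   `glance()$dose_scale`.
#' @export
tidy.quantal_fit <- function(x, ...) {
  tibble(term = names(x$par), estimate = unname(x$par),
         at_bound = unname(x$at_bound))
}

#' @rdname tidy.quantal_fit
#' @export
glance.quantal_fit <- function(x, ...) {
  tibble(model = x$model$name, n_est = x$n_est, log_lik = x$log_lik,
         aic = x$aic, gof_statistic = x$gof_statistic, gof_df = x$gof_df,
         gof_p = x$gof_p, converged = x$converged, dose_scale = x$dmax)
}

#' @rdname tidy.quantal_fit
#' @export
tidy.continuous_fit <- function(x, ...) {
  tibble(term = c(names(x$par), names(x$var_par)),
         estimate = c(unname(x$par), unname(x$var_par)),
         at_bound = c(unname(x$at_bound), rep(FALSE, length(x$var_par))))
}

#' @rdname tidy.quantal_fit
#' @export
glance.continuous_fit <- function(x, ...) {
  tibble(model = x$model$name, variance = x$variance, n_est = x$n_est,
         log_lik = x$log_lik, aic = x$aic, gof_p = x$gof_p,
         converged = x$converged, dose_scale = x$dmax,
         response_scale = x$y_scale)
}

#' Tidy a model-selection result
#'
#' @param x A `bmd_estimate` from [select_model()].
#' @param ... Unused.
#' @return The per-model diagnostics table (`tidy`) or a one-row summary of
#'   the selected estimate (`glance`).
#' @export
tidy.bmd_estimate <- function(x, ...) x$models

#' @rdname tidy.bmd_estimate
#' @export
glance.bmd_estimate <- function(x, ...) {
  tibble(model = x$model_name, bmr = format(x$bmr),
         confidence = x$confidence, bmd = x$bmd, bmdl = x$bmdl,
         bmd_bmdl_ratio = x$bmd_bmdl_ratio, high_ratio = x$high_ratio,
         extrapolated = x$extrapolated)
}

#' Tidy a Bayesian model-average result
#'
#' @param x An `ma_bmd` from [model_average_bmd()].
#' @param ... Unused.
#' @return Per-model posterior weights (`tidy`) or the averaged estimate
#'   (`glance`).
#' @export
tidy.ma_bmd <- function(x, ...) {
  tibble(model = names(x$weights), posterior_weight = unname(x$weights))
}

#' @rdname tidy.ma_bmd
#' @export
glance.ma_bmd <- function(x, ...) {
  tibble(bmr = format(x$bmr), bmd_ma = x$bmd_ma, bmdl_ma = x$bmdl_ma,
         bmdu_ma = x$bmdu_ma, n_draws = x$n_draws, seed = x$seed,
         censored_fraction = x$censored_fraction)
}

#' Tidy a probabilistic reference-dose result
#'
#' @param x A `prfd_result` from [propagate()].
#' @param ... Unused.
#' @return Percentiles of the median-human and sensitive-human dose
#'   distributions (`tidy`) or the headline pRfD values (`glance`).
#' @export
tidy.prfd_result <- function(x, ...) {
  dplyr::bind_rows(
    tibble(distribution = "hd50", percentile = names(x$hd50_summary),
           value = unname(x$hd50_summary)),
    tibble(distribution = sprintf("hd_%g%%", 100 * x$incidence),
           percentile = names(x$hd_I_summary),
           value = unname(x$hd_I_summary))
  )
}

#' @rdname tidy.prfd_result
#' @export
glance.prfd_result <- function(x, ...) {
  tibble(incidence = x$incidence, hd_I_p05 = x$hd_I_p05, uf_d = x$uf_d,
         prfd_raw = x$prfd_raw, prfd_reported = x$prfd_reported,
         method = x$method, n_samples = x$n_samples, seed = x$seed)
}
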