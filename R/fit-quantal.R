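# Binomial log-likelihood of group incidences under fitted probabilities.
ll_binom <- function(p, x, n) {
  p <- pmin(pmax(p, 1e-12), 1 - 1e-12)
  sum(x * log(p) + (n - x) * log(1 - p))
}

#' Fit a quantal dose-response model by maximum likelihood
#'
#' Maximizes the binomial log-likelihood over the model's constrained
#' parameter box using multi-start local optimization: a method-of-moments
#' style seed plus Latin-hypercube starts, deterministic under `seed`.
#' Fitting is performed on the scaled dose `u = dose / max(dose)`; reported
#' parameters live on that scale (`dmax` is stored on the fit), which makes
#' BMD and BMDL exactly equivariant under rescaling of dose.
#'
#' Parameters that end on a constraint boundary are not counted as estimated;
#' `aic = -2 log L + 2 k` and the goodness-of-fit degrees of freedom use that
#' count, following the convention of the standard benchmark-dose software
#' family.
#'
#' @param data A [as_quantal_data()] dataset.
#' @param model A [quantal_model()] or a model name.
#' @param n_starts Number of optimizer starts (at least 10 recommended).
#' @param seed Integer seed making the start set reproducible.
#' @return A `quantal_fit` object.
#' @examples
#' fit <- fit_quantal(genx_fixture("cystic_focal_degeneration"), "weibull")
#' fit$aic
#' @export
fit_quantal <- function(data, model, n_starts = 10, seed = 1) {
  data <- as_quantal_data(data, endpoint = attr(data, "endpoint"))
  if (is.character(model)) model <- quantal_model(model)
  stopifnot(inherits(model, "quantal_model"))
  if (model$name == "multistage" && is.null(model$prob)) {
    model <- resolve_multistage(model, nrow(data))
  }
  dmax <- max(data$dose)
  if (dmax <= 0) abort("all doses are zero; nothing to model")
  u <- data$dose / dmax
  x <- data$affected
  n <- data$n

  nll <- function(th) {
    p <- model$prob(u, th)
    if (any(!is.finite(p))) return(1e10)
    -ll_binom(p, x, n)
  }

  starts <- make_starts(model, x, n, n_starts, seed)
  best <- NULL
  any_conv <- FALSE
  for (s in starts) {
    o <- tryCatch(nlminb(s, nll, lower = model$lower, upper = model$upper,
                         control = list(iter.max = 500, eval.max = 1000)),
                  error = function(e) NULL)
    if (is.null(o) || !is.finite(o$objective)) next
    if (o$convergence == 0) any_conv <- TRUE
    if (is.null(best) || o$objective < best$objective) best <- o
  }
  if (is.null(best)) {
    abort(paste0("all optimizer starts failed for model ", model$name))
  }
  # polish: re-start from the incumbent until no further improvement
  for (i in 1:3) {
    o <- tryCatch(nlminb(best$par, nll, lower = model$lower, upper = model$upper,
                         control = list(iter.max = 500, eval.max = 1000)),
                  error = function(e) NULL)
    if (is.null(o) || !is.finite(o$objective)) break
    if (o$objective < best$objective - 1e-12) best <- o else break
  }

  th <- setNames(best$par, model$par_names)
  p_hat <- model$prob(u, th)
  at_bound <- at_bounds(th, model$lower, model$upper)
  n_est <- sum(!at_bound)
  ll <- -best$objective
  gof <- pearson_gof(x, n, p_hat, n_est)

  structure(list(
    model = model,
    data = data,
    dmax = dmax,
    par = th,
    at_bound = at_bound,
    n_est = n_est,
    log_lik = ll,
    aic = -2 * ll + 2 * n_est,
    gof_statistic = gof$statistic,
    gof_df = gof$df,
    gof_p = gof$p,
    scaled_residuals = gof$residuals,
    fitted = p_hat,
    converged = any_conv,
    n_starts = n_starts,
    seed = seed
  ), class = "quantal_fit")
}

at_bounds <- function(th, lower, upper) {
  tol_lo <- 1e-6 * pmax(1, abs(lower))
  tol_hi <- 1e-6 * pmax(1, abs(upper))
  (th - lower) < tol_lo | (upper - th) < tol_hi
}

pearson_gof <- function(x, n, p_hat, n_est) {
  e <- n * p_hat
  v <- n * p_hat * (1 - p_hat)
  r <- ifelse(v > 0, (x - e) / sqrt(v), 0)
  stat <- sum(r^2)
  df <- length(x) - n_est
  p <- if (df > 0) pchisq(stat, df, lower.tail = FALSE) else NA_real_
  list(statistic = stat, df = df, p = p, residuals = r)
}

make_starts <- function(model, x, n, n_starts, seed) {
  lo <- model$lower
  hi <- model$upper
  box <- model$start_box
  g0 <- (x[1] + 0.5) / (n[1] + 1)
  seed_start <- (box$lo + box$hi) / 2
  gi <- which(model$par_names %in% c("g"))
  if (length(gi) == 1) seed_start[gi] <- min(max(g0, lo[gi]), 0.9)
  starts <- list(pmin(pmax(seed_start, lo), hi))
  n_lhs <- max(0, n_starts - 1)
  if (n_lhs > 0) {
    grid <- with_seed(seed, lhs::randomLHS(n_lhs, length(lo)))
    for (i in seq_len(n_lhs)) {
      s <- numeric(length(lo))
      for (j in seq_along(lo)) {
        if (isTRUE(box$log[j])) {
          s[j] <- exp(log(box$lo[j]) + grid[i, j] * (log(box$hi[j]) - log(box$lo[j])))
        } else {
          s[j] <- box$lo[j] + grid[i, j] * (box$hi[j] - box$lo[j])
        }
      }
      starts[[i + 1]] <- pmin(pmax(s, lo), hi)
    }
  }
  starts
}

#' Fit the full quantal model suite
#'
#' @inheritParams fit_quantal
#' @param models A named list of [quantal_model()] objects, default the
#'   standard nine-model suite.
#' @return A named list of `quantal_fit` objects, class `quantal_fit_list`.
#' @export
fit_quantal_suite <- function(data, models = quantal_suite(), n_starts = 10,
                              seed = 1) {
  fits <- purrr::imap(models, function(m, nm) fit_quantal(data, m, n_starts, seed))
  structure(fits, class = "quantal_fit_list")
}

#' Fitted response probability and risk at a given dose
#'
#' `extra_risk()` returns `[P(d) - P(0)] / [1 - P(0)]`, the
#' background-corrected fraction of responders; `added_risk()` returns
#' `P(d) - P(0)`.
#'
#' @param fit A `quantal_fit`.
#' @param dose Dose(s) in the original units.
#' @return Risk fraction(s) in `[0, 1]`.
#' @examples
#' fit <- fit_quantal(genx_fixture("cystic_focal_degeneration"), "quantal_linear")
#' extra_risk(fit, 50)
#' @export
extra_risk <- function(fit, dose) {
  p0 <- predict_prob(fit, 0)
  if (p0 >= 1 - 1e-12) abort("background probability is 1; extra risk undefined")
  (predict_prob(fit, dose) - p0) / (1 - p0)
}

#' @rdname extra_risk
#' @export
added_risk <- function(fit, dose) {
  predict_prob(fit, dose) - predict_prob(fit, 0)
}

predict_prob <- function(fit, dose) {
  unname(fit$model$prob(dose / fit$dmax, fit$par))
}

#' @export
predict.quantal_fit <- function(object, dose = object$data$dose, ...) {
  predict_prob(object, dose)
}

#' Goodness of fit of a quantal model
#'
#' Pearson chi-square statistic over dose groups with degrees of freedom
#' `n_groups - n_estimated`, plus per-group scaled residuals
#' `(x - n p) / sqrt(n p (1 - p))`.
#'
#' @param fit A `quantal_fit`.
#' @return A list with `p_value`, `statistic`, `df` and a tibble `table` of
#'   per-group observed/expected counts and scaled residuals. `p_value` is
#'   `NA` for a saturated model (df <= 0).
#' @export
goodness_of_fit <- function(fit) {
  d <- fit$data
  list(
    p_value = fit$gof_p,
    statistic = fit$gof_statistic,
    df = fit$gof_df,
    table = tibble(
      dose = d$dose, n = d$n, observed = d$affected,
      expected = d$n * fit$fitted, fitted_p = fit$fitted,
      scaled_residual = fit$scaled_residuals
    )
  )
}

#' Benchmark dose from a fitted model
#'
#' The BMD is the dose at which the fitted model attains the benchmark
#' response. Closed forms are used for every suite model (the multistage
#' polynomial is solved exactly via its roots).
#'
#' @param fit A `quantal_fit` or `continuous_fit`.
#' @param bmr A [bmr_extra()]-style benchmark response.
#' @return BMD in mg/kg/day.
#' @examples
#' fit <- fit_quantal(genx_fixture("cystic_focal_degeneration"), "quantal_linear")
#' compute_bmd(fit, bmr_extra(0.10))
#' @export
compute_bmd <- function(fit, bmr = bmr_extra(0.10)) UseMethod("compute_bmd")

#' @export
compute_bmd.quantal_fit <- function(fit, bmr = bmr_extra(0.10)) {
  bmr <- as_bmr(bmr)
  if (!bmr$kind %in% c("extra_risk", "added_risk")) {
    abort("quantal BMDs require a risk-based BMR (extra or added risk)")
  }
  if (!fit$converged) abort("fit did not converge; no usable BMD")
  B <- fit$model$bmd_u(fit$par, bmr$level, bmr$kind)
  # a benchmark dose thousands of-fold beyond the tested range (flat slope)
  # is treated as unattainable
  if (!is.finite(B) || B <= 0 || B > 1e4) {
    abort(sprintf("model %s cannot attain %s", fit$model$name, format(bmr)),
          class = "bmdtox_no_bmd_error")
  }
  unname(B * fit$dmax)
}

#' Profile-likelihood lower confidence bound on the BMD
#'
#' One-sided lower bound: the smallest BMD for which the log-likelihood,
#' re-maximized over all remaining parameters with the BMD held fixed
#' (via slope substitution in the BMD-reparameterized model), stays within
#' `chi-square_1(1 - 2 alpha) / 2` of the global maximum (1.352771 nats at
#' the default 95% one-sided level).
#'
#' @inheritParams compute_bmd
#' @param conf One-sided confidence level (default 0.95).
#' @return BMDL in mg/kg/day. If the profile never drops below the
#'   threshold down to `1e-4 * BMD`, the bound is reported at that search
#'   floor with attribute `at_search_floor = TRUE`.
#' @export
compute_bmdl <- function(fit, bmr = bmr_extra(0.10), conf = 0.95) {
  UseMethod("compute_bmdl")
}

#' @export
compute_bmdl.quantal_fit <- function(fit, bmr = bmr_extra(0.10), conf = 0.95) {
  bmr <- as_bmr(bmr)
  bmd <- compute_bmd(fit, bmr)
  B_hat <- bmd / fit$dmax
  model <- fit$model
  u <- fit$data$dose / fit$dmax
  x <- fit$data$affected
  n <- fit$data$n
  prof <- model$profile
  warm <- new.env(parent = emptyenv())
  warm$phi <- fit$par[prof$free]

  pll <- function(B) {
    nllp <- function(phi) {
      th <- prof$mk(phi, B, bmr$level, bmr$kind)
      if (any(is.na(th)) || any(th < model$lower - 1e-12) ||
          any(th > model$upper + 1e-12)) {
        return(1e10)
      }
      p <- model$prob(u, th)
      if (any(!is.finite(p))) return(1e10)
      -ll_binom(p, x, n)
    }
    lo <- model$lower[prof$free]
    hi <- model$upper[prof$free]
    best <- NULL
    for (s in list(warm$phi,
                   pmin(pmax(warm$phi * 0.7 + 0.1 * lo_fin(lo), lo), hi))) {
      o <- tryCatch(nlminb(s, nllp, lower = lo, upper = hi,
                           control = list(iter.max = 300)),
                    error = function(e) NULL)
      if (is.null(o) || !is.finite(o$objective)) next
      if (is.null(best) || o$objective < best$objective) best <- o
    }
    if (is.null(best)) return(-Inf)
    warm$phi <- best$par
    -best$objective
  }

  ll_max <- max(fit$log_lik, pll(B_hat))
  crit <- ll_max - .chi2_drop(conf)
  # step down geometrically until the profile crosses the threshold
  floor_B <- B_hat * 1e-4
  B_lo <- NA_real_
  B_prev <- B_hat
  for (B in B_hat * 10^(-seq(0.05, 4, by = 0.05))) {
    if (B < floor_B) break
    if (pll(B) < crit) { B_lo <- B; break }
    B_prev <- B
  }
  if (is.na(B_lo)) {
    out <- floor_B * fit$dmax
    attr(out, "at_search_floor") <- TRUE
    warn("profile likelihood did not close above the search floor; BMDL reported at floor")
    return(out)
  }
  root <- tryCatch(
    uniroot(function(B) pll(B) - crit, lower = B_lo, upper = B_prev,
            tol = B_hat * 1e-7)$root,
    # warm-started profiles are only approximately deterministic; if the
    # bracket degrades on re-evaluation, report the conservative scan bound
    error = function(e) B_lo
  )
  min(root, B_hat) * fit$dmax
}

lo_fin <- function(lo) ifelse(is.finite(lo), pmax(lo, -5), -5)

#' Select the best-fitting quantal model and its BMD/BMDL
#'
#' Implements the conventional adequacy-then-parsimony protocol: fits with
#' goodness-of-fit p below `gof_min` (default 0.10), an undefined p
#' (saturated model), a scaled residual exceeding `resid_max` in absolute
#' value at the control group or at the group nearest the BMD, a failed
#' convergence flag, or no attainable BMD are discarded; among the survivors
#' the lowest AIC wins, with ties (within 0.1) broken by fewer estimated
#' parameters, then lower BMDL, then lower BMD. The BMD/BMDL ratio of the
#' winner is recorded and flagged when it exceeds 5 (high model uncertainty).
#'
#' @param fits A `quantal_fit_list` from [fit_quantal_suite()] (or any list
#'   of `quantal_fit` objects).
#' @inheritParams compute_bmdl
#' @param gof_min Minimum acceptable goodness-of-fit p-value.
#' @param resid_max Maximum acceptable |scaled residual| at the control and
#'   nearest-to-BMD groups.
#' @return A `bmd_estimate`: the selected model's BMD and BMDL plus a
#'   per-model diagnostics table (`$models`).
#' @examples
#' \donttest{
#' fits <- fit_quantal_suite(genx_fixture("cystic_focal_degeneration"))
#' select_model(fits, bmr_extra(0.10))
#' }
#' @export
select_model <- function(fits, bmr = bmr_extra(0.10), conf = 0.95,
                         gof_min = 0.10, resid_max = 2) {
  bmr <- as_bmr(bmr)
  rows <- purrr::imap(fits, function(f, nm) {
    bmd <- tryCatch(compute_bmd(f, bmr), error = function(e) NA_real_)
    near <- if (is.finite(bmd)) which.min(abs(f$data$dose - bmd)) else 1L
    resid_ok <- is.finite(bmd) &&
      abs(f$scaled_residuals[1]) <= resid_max &&
      abs(f$scaled_residuals[near]) <= resid_max
    viable <- f$converged && is.finite(bmd) &&
      !is.na(f$gof_p) && f$gof_p >= gof_min && resid_ok
    tibble(
      model = if (f$model$name == "multistage") {
        paste0("multistage", f$model$degree)
      } else f$model$name,
      n_est = f$n_est, log_lik = f$log_lik, aic = f$aic,
      gof_p = f$gof_p, max_abs_residual = max(abs(f$scaled_residuals)),
      bmd = bmd, viable = viable
    )
  })
  tab <- dplyr::bind_rows(rows)
  tab$bmdl <- NA_real_
  for (i in which(tab$viable)) {
    tab$bmdl[i] <- tryCatch(
      as.numeric(compute_bmdl(fits[[i]], bmr, conf)),
      error = function(e) NA_real_
    )
  }
  tab$viable <- tab$viable & is.finite(tab$bmdl)
  cand <- which(tab$viable)
  if (length(cand) == 0) {
    abort("no model passed the adequacy criteria; inspect the fits visually",
          class = "bmdtox_selection_error")
  }
  ctab <- tab[cand, ]
  tied <- which(ctab$aic <= min(ctab$aic) + 0.1)
  ord <- order(ctab$n_est[tied], signif(ctab$bmdl[tied], 4),
               ctab$bmd[tied], tied)
  pick <- cand[tied[ord[1]]]

  sel <- tab[pick, ]
  ratio <- sel$bmd / sel$bmdl
  structure(list(
    model_name = sel$model,
    fit = fits[[pick]],
    bmr = bmr,
    confidence = conf,
    bmd = sel$bmd,
    bmdl = sel$bmdl,
    bmd_bmdl_ratio = ratio,
    high_ratio = ratio > 5,
    extrapolated = sel$bmd > max(fits[[pick]]$data$dose),
    models = tab
  ), class = "bmd_estimate")
}

#' @export
print.bmd_estimate <- function(x, ...) {
  cat("<bmd_estimate>\n")
  cat(sprintf("  BMR: %s (one-sided %g%% lower bound)\n",
              format(x$bmr), 100 * x$confidence))
  cat(sprintf("  selected model: %s\n", x$model_name))
  cat(sprintf("  BMD  = %.4g mg/kg/day\n", x$bmd))
  cat(sprintf("  BMDL = %.4g mg/kg/day\n", x$bmdl))
  cat(sprintf("  BMD/BMDL ratio = %.3g%s\n", x$bmd_bmdl_ratio,
              if (x$high_ratio) "  [> 5: high model uncertainty]" else ""))
  if (x$extrapolated) cat("  note: BMD above the highest tested dose\n")
  invisible(x)
}

#' @export
print.quantal_fit <- function(x, ...) {
  cat("<quantal_fit>", x$model$name,
      if (x$model$name == "multistage") paste0("(degree ", x$model$degree, ")"),
      "\n")
  cat("  parameters (dose scaled by", format(x$dmax), "):\n")
  print(round(x$par, 6))
  cat(sprintf("  logLik %.4f | AIC %.3f (k = %d) | GOF p %s | converged: %s\n",
              x$log_lik, x$aic, x$n_est,
              ifelse(is.na(x$gof_p), "NA", sprintf("%.3f", x$gof_p)),
              x$converged))
  invisible(x)
}
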