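# Bayesian fitting of the quantal suite with Laplace-approximated marginal
# likelihoods and posterior-weight model averaging.
#
# Priors are placed on transformed parameters (logit scale for probabilities,
# log scale for slopes/powers, identity for location parameters) of the
# dose-normalized models, so a single dimensionless prior configuration
# applies to any dataset. The per-family prior parameters live in
# inst/extdata/bayes_priors.yaml and can be swapped without code change.

#' Default (or custom) prior configuration for Bayesian quantal fits
#'
#' @param path Optional path to a YAML file; default is the packaged
#'   configuration.
#' @return A named list of prior families, class `bayes_priors`.
#' @export
bayes_priors <- function(path = NULL) {
  path <- path %||% system.file("extdata", "bayes_priors.yaml", package = "bmdtox")
  cfg <- yaml::read_yaml(path)
  structure(cfg, class = "bayes_priors")
}

# map each model parameter to a prior family
prior_classes <- function(model) {
  k <- model$degree
  switch(model$name,
    logistic = ,
    probit = c("location", "log_rate"),
    log_logistic = ,
    log_probit = c("background_logit", "location", "log_slope"),
    gamma = ,
    weibull = c("background_logit", "log_power", "log_rate"),
    quantal_linear = c("background_logit", "log_rate"),
    multistage = c("background_logit", rep("log_beta", k)),
    dichotomous_hill = c("background_logit", "asymptote_logit", "location",
                         "log_slope")
  )
}

# z (unconstrained) -> theta (model scale)
z_to_theta <- function(z, trans) {
  th <- z
  th[trans == "logit"] <- plogis(z[trans == "logit"])
  th[trans == "log"] <- exp(z[trans == "log"])
  th
}
theta_to_z <- function(th, trans) {
  z <- th
  z[trans == "logit"] <- qlogis(pmin(pmax(th[trans == "logit"], 1e-12), 1 - 1e-12))
  z[trans == "log"] <- log(pmax(th[trans == "log"], 1e-12))
  z
}

#' Bayesian fit of one quantal model (MAP + Laplace approximation)
#'
#' Finds the posterior mode by multi-start optimization of the log posterior
#' and approximates the marginal likelihood by the Laplace method:
#' `log m = log post(MAP) + k/2 log(2*pi) - 1/2 log det H`, with `H` the
#' negative Hessian of the log posterior at the mode. A singular Hessian is
#' regularized through its eigenvalues and the fit flagged.
#'
#' @inheritParams fit_quantal
#' @param priors A [bayes_priors()] configuration.
#' @return A `bayesian_fit` with the MAP estimate (model scale), the Laplace
#'   covariance on the transformed scale, and `log_marginal`.
#' @export
fit_bayesian <- function(data, model, priors = bayes_priors(), n_starts = 10,
                         seed = 1) {
  data <- as_quantal_data(data, endpoint = attr(data, "endpoint"))
  if (is.character(model)) model <- quantal_model(model)
  if (model$name == "multistage" && is.null(model$prob)) {
    deg <- model$degree %||% 2L  # model-averaging convention
    model$degree <- deg
    model <- resolve_multistage(model, nrow(data))
  }
  dmax <- max(data$dose)
  u <- data$dose / dmax
  x <- data$affected
  n <- data$n
  trans <- model$trans
  pc <- prior_classes(model)
  pm <- vapply(pc, function(cl) priors[[cl]]$mean, numeric(1))
  ps <- vapply(pc, function(cl) priors[[cl]]$sd, numeric(1))

  neg_logpost <- function(z) {
    th <- z_to_theta(z, trans)
    p <- model$prob(u, th)
    if (any(!is.finite(p))) return(1e10)
    -(ll_binom(p, x, n) + sum(stats::dnorm(z, pm, ps, log = TRUE)))
  }

  k <- length(pm)
  starts <- list(pm)
  grid <- with_seed(seed + 211, lhs::randomLHS(max(1, n_starts - 1), k))
  for (i in seq_len(nrow(grid))) {
    starts[[i + 1]] <- pm + (grid[i, ] - 0.5) * 4 * ps
  }
  best <- NULL
  for (s in starts) {
    o <- tryCatch(nlminb(s, neg_logpost, lower = rep(-30, k), upper = rep(30, k),
                         control = list(iter.max = 500)),
                  error = function(e) NULL)
    if (is.null(o) || !is.finite(o$objective)) next
    if (is.null(best) || o$objective < best$objective) best <- o
  }
  if (is.null(best)) abort(paste0("Bayesian fit failed for ", model$name))
  z_map <- best$par
  lp_map <- -best$objective

  H <- pracma::hessian(neg_logpost, z_map)
  ev <- eigen((H + t(H)) / 2, symmetric = TRUE)
  singular <- any(ev$values < 1e-8)
  lam <- pmax(ev$values, 1e-8)
  log_det <- sum(log(lam))
  cov_z <- ev$vectors %*% diag(1 / lam, k) %*% t(ev$vectors)
  log_marginal <- lp_map + k / 2 * log(2 * pi) - 0.5 * log_det

  structure(list(
    model = model, data = data, dmax = dmax,
    prior = list(classes = pc, mean = pm, sd = ps),
    z_map = z_map, map = setNames(z_to_theta(z_map, trans), model$par_names),
    cov_z = cov_z, log_posterior = lp_map, log_marginal = log_marginal,
    singular_hessian = singular, seed = seed,
    posterior_weight = NA_real_
  ), class = "bayesian_fit")
}

#' Fit the Bayesian quantal suite and compute posterior model weights
#'
#' Weights are proportional to the Laplace-approximated marginal likelihoods
#' under a uniform prior over models; they sum to one.
#'
#' @inheritParams fit_bayesian
#' @param models Named list of [quantal_model()]s; the default suite uses a
#'   degree-2 multistage, the model-averaging convention.
#' @return A `bayesian_fit_list` whose elements carry `posterior_weight`.
#' @export
fit_bayesian_suite <- function(data, models = quantal_suite(degree = 2),
                               priors = bayes_priors(), n_starts = 10,
                               seed = 1) {
  fits <- purrr::map(models, function(m) {
    fit_bayesian(data, m, priors = priors, n_starts = n_starts, seed = seed)
  })
  set_posterior_weights(fits)
}

#' @rdname fit_bayesian_suite
#' @param fits A list of `bayesian_fit` objects.
#' @export
set_posterior_weights <- function(fits) {
  lm <- vapply(fits, function(f) f$log_marginal, numeric(1))
  w <- exp(lm - max(lm))
  w <- w / sum(w)
  for (i in seq_along(fits)) fits[[i]]$posterior_weight <- w[i]
  structure(fits, class = "bayesian_fit_list")
}

#' @rdname fit_bayesian_suite
#' @export
posterior_weights <- function(fits) {
  vapply(fits, function(f) f$posterior_weight, numeric(1))
}

# vectorized benchmark dose on the scaled-dose scale for a parameter matrix
bmd_u_matrix <- function(name, TH, level, kind, degree = NULL) {
  tf <- function(g) if (kind == "extra_risk") rep(level, length(g)) else level / (1 - g)
  out <- switch(name,
    logistic = {
      p0 <- plogis(TH[, 1])
      pt <- if (kind == "extra_risk") p0 + level * (1 - p0) else p0 + level
      ifelse(pt < 1, (qlogis(pt) - TH[, 1]) / TH[, 2], NA_real_)
    },
    probit = {
      p0 <- pnorm(TH[, 1])
      pt <- if (kind == "extra_risk") p0 + level * (1 - p0) else p0 + level
      ifelse(pt < 1, (qnorm(pt) - TH[, 1]) / TH[, 2], NA_real_)
    },
    log_logistic = {
      Ft <- tf(TH[, 1])
      ifelse(Ft < 1, exp((qlogis(pmin(Ft, 1 - 1e-12)) - TH[, 2]) / TH[, 3]), NA_real_)
    },
    log_probit = {
      Ft <- tf(TH[, 1])
      ifelse(Ft < 1, exp((qnorm(pmin(Ft, 1 - 1e-12)) - TH[, 2]) / TH[, 3]), NA_real_)
    },
    gamma = {
      Ft <- tf(TH[, 1])
      ifelse(Ft < 1, qgamma(pmin(Ft, 1 - 1e-12), shape = TH[, 2]) / TH[, 3], NA_real_)
    },
    weibull = {
      Ft <- tf(TH[, 1])
      ifelse(Ft < 1, (-log1p(-pmin(Ft, 1 - 1e-12)) / TH[, 3])^(1 / TH[, 2]), NA_real_)
    },
    quantal_linear = {
      Ft <- tf(TH[, 1])
      ifelse(Ft < 1, -log1p(-pmin(Ft, 1 - 1e-12)) / TH[, 2], NA_real_)
    },
    multistage = {
      Ft <- tf(TH[, 1])
      A <- ifelse(Ft < 1, -log1p(-pmin(Ft, 1 - 1e-12)), NA_real_)
      k <- degree
      if (k == 1) {
        A / TH[, 2]
      } else if (k == 2) {
        b1 <- TH[, 2]; b2 <- TH[, 3]
        ifelse(b2 > 1e-12,
               (-b1 + sqrt(b1^2 + 4 * b2 * A)) / (2 * b2),
               A / b1)
      } else {
        vapply(seq_len(nrow(TH)), function(i) {
          if (!is.finite(A[i])) return(NA_real_)
          ms_smallest_root(TH[i, -1], A[i])
        }, numeric(1))
      }
    },
    dichotomous_hill = {
      Ft <- tf(TH[, 1])
      w <- (TH[, 2] - TH[, 1]) / (1 - TH[, 1])
      ok <- is.finite(Ft) & Ft < w & w > 0
      res <- rep(NA_real_, nrow(TH))
      res[ok] <- exp((qlogis(Ft[ok] / w[ok]) - TH[ok, 3]) / TH[ok, 4])
      res
    }
  )
  out[!is.finite(out) | out <= 0] <- NA_real_
  out
}

#' Model-averaged BMD and BMDL by posterior mixture sampling
#'
#' Draws models in proportion to their posterior weights and parameters from
#' each model's Laplace Gaussian on the transformed scale, computes every
#' draw's benchmark dose, and summarizes the mixture: the model-averaged BMD
#' is the posterior median, the model-averaged BMDL the 5th percentile
#' (one-sided 95%). Draws whose benchmark response is unattainable are
#' censored at `ceiling_mult * max(dose)` and counted; more than 20%
#' censoring is an error.
#'
#' @param fits A `bayesian_fit_list` with posterior weights set.
#' @param bmr A risk-based benchmark response.
#' @param n_draws Number of mixture draws (>= 1e4).
#' @param seed Integer seed; results are reproducible bit-for-bit.
#' @param ceiling_mult Censoring ceiling as a multiple of the highest dose.
#' @param keep_draws Store the draw vector on the result.
#' @return An `ma_bmd` object with `bmd_ma`, `bmdl_ma`, weights, the
#'   censoring fraction, and optionally `draws`.
#' @export
model_average_bmd <- function(fits, bmr = bmr_extra(0.10), n_draws = 1e5,
                              seed = 1, ceiling_mult = 1000,
                              keep_draws = FALSE) {
  bmr <- as_bmr(bmr)
  if (!bmr$kind %in% c("extra_risk", "added_risk")) {
    abort("model averaging requires a risk-based BMR")
  }
  if (n_draws < 1e4) abort("n_draws must be at least 10^4")
  w <- posterior_weights(fits)
  if (any(is.na(w))) abort("posterior weights are unset; use fit_bayesian_suite()")
  dmax <- fits[[1]]$dmax
  ceiling_u <- ceiling_mult

  draws <- with_seed(seed, {
    counts <- drop(rmultinom(1, n_draws, w))
    out <- numeric(0)
    for (i in seq_along(fits)) {
      if (counts[i] == 0) next
      f <- fits[[i]]
      k <- length(f$z_map)
      ev <- eigen((f$cov_z + t(f$cov_z)) / 2, symmetric = TRUE)
      A <- ev$vectors %*% diag(sqrt(pmax(ev$values, 0)), k)
      Z <- matrix(rnorm(counts[i] * k), counts[i], k) %*% t(A)
      Z <- sweep(Z, 2, f$z_map, `+`)
      TH <- Z
      for (j in seq_len(k)) {
        TH[, j] <- switch(f$model$trans[j],
                          logit = plogis(Z[, j]),
                          log = exp(Z[, j]),
                          Z[, j])
      }
      b <- bmd_u_matrix(f$model$name, TH, bmr$level, bmr$kind,
                        degree = f$model$degree)
      out <- c(out, b)
    }
    out
  })
  censored <- !is.finite(draws) | draws > ceiling_u
  frac_cens <- mean(censored)
  if (frac_cens > 0.20) {
    abort(sprintf("%.0f%% of draws cannot attain the BMR; model average unreliable",
                  100 * frac_cens))
  }
  draws[censored] <- ceiling_u
  draws <- draws * dmax
  structure(list(
    bmd_ma = unname(quantile(draws, 0.5, type = 7)),
    bmdl_ma = unname(quantile(draws, 0.05, type = 7)),
    bmdu_ma = unname(quantile(draws, 0.95, type = 7)),
    weights = setNames(w, names(fits)),
    bmr = bmr, n_draws = n_draws, seed = seed,
    censored_fraction = frac_cens,
    draws = if (keep_draws) draws else NULL
  ), class = "ma_bmd")
}

#' @export
print.ma_bmd <- function(x, ...) {
  cat("<ma_bmd> model-averaged benchmark dose (", format(x$bmr), ")\n", sep = "")
  cat(sprintf("  BMD (posterior median) = %.4g mg/kg/day\n", x$bmd_ma))
  cat(sprintf("  BMDL (5th percentile)  = %.4g mg/kg/day\n", x$bmdl_ma))
  cat("  posterior weights:\n")
  print(round(x$weights, 4))
  invisible(x)
}
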