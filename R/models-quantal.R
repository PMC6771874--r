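# Quantal dose-response model registry.
#
# All models are parameterized on the *scaled* dose u = dose / max(dose), so
# parameter magnitudes are dimensionless and dose-scale equivariance of
# BMD/BMDL holds exactly. Each entry provides:
#   prob(u, theta)          response probability, non-decreasing in u under
#                           the default constraints
#   bmd_u(theta, bmr)       closed-form benchmark dose on the u scale
#   profile(bmr)            slope-substitution used for profile-likelihood
#                           bounds: free parameter indices plus mk(phi, B)
#                           rebuilding the full theta with BMD fixed at B
#   trans                   per-parameter transform for Bayesian fitting
# Background-parameterized models share the form P = g + (1 - g) F(u), for
# which extra risk equals F(u) itself.

#' Quantal model specifications
#'
#' `quantal_model()` builds one member of the standard dichotomous suite;
#' `quantal_suite()` returns the default nine-model suite. With
#' `restricted = TRUE` (the conventional default) shape and log-dose-slope
#' parameters are bounded below by 1, which prevents supralinear behavior at
#' low dose.
#'
#' @param name One of `"logistic"`, `"log_logistic"`, `"probit"`,
#'   `"log_probit"`, `"gamma"`, `"weibull"`, `"multistage"`,
#'   `"quantal_linear"`, `"dichotomous_hill"`.
#' @param degree Polynomial degree for the multistage model. Default: number
#'   of dose groups minus one, capped at 3 (resolved at fit time when `NULL`).
#' @param restricted Apply the conventional lower bound of 1 on shape/slope
#'   parameters.
#' @return A `quantal_model` object.
#' @examples
#' quantal_model("weibull")
#' names(quantal_suite())
#' @export
quantal_model <- function(name = c("logistic", "log_logistic", "probit",
                                   "log_probit", "gamma", "weibull",
                                   "multistage", "quantal_linear",
                                   "dichotomous_hill"),
                          degree = NULL, restricted = TRUE) {
  name <- match.arg(name)
  slope_lo <- if (restricted) 1 else 1e-8
  power_lo <- if (restricted) 1 else 0.2
  m <- switch(name,
    logistic = list(
      par_names = c("a", "b"),
      lower = c(-18, 1e-8), upper = c(18, 1e3),
      start_box = list(lo = c(-4, 0.1), hi = c(2, 50), log = c(FALSE, TRUE)),
      trans = c("identity", "log"),
      prob = function(u, th) plogis(th[1] + th[2] * u),
      bmd_u = function(th, R, kind) {
        p0 <- plogis(th[1])
        pt <- target_p(p0, R, kind)
        (qlogis(pt) - th[1]) / th[2]
      },
      profile = list(free = 1L, mk = function(phi, B, R, kind) {
        p0 <- plogis(phi[1])
        c(phi[1], (qlogis(target_p(p0, R, kind)) - phi[1]) / B)
      })
    ),
    probit = list(
      par_names = c("a", "b"),
      lower = c(-18, 1e-8), upper = c(18, 1e3),
      start_box = list(lo = c(-3, 0.1), hi = c(1.5, 30), log = c(FALSE, TRUE)),
      trans = c("identity", "log"),
      prob = function(u, th) pnorm(th[1] + th[2] * u),
      bmd_u = function(th, R, kind) {
        p0 <- pnorm(th[1])
        (qnorm(target_p(p0, R, kind)) - th[1]) / th[2]
      },
      profile = list(free = 1L, mk = function(phi, B, R, kind) {
        p0 <- pnorm(phi[1])
        c(phi[1], (qnorm(target_p(p0, R, kind)) - phi[1]) / B)
      })
    ),
    log_logistic = list(
      par_names = c("g", "a", "b"),
      lower = c(1e-8, -40, slope_lo), upper = c(1 - 1e-6, 40, 18),
      start_box = list(lo = c(0.01, -10, max(slope_lo, 0.5)),
                       hi = c(0.6, 5, 6), log = c(FALSE, FALSE, FALSE)),
      trans = c("logit", "identity", "log"),
      prob = function(u, th) {
        ifelse(u <= 0, th[1], th[1] + (1 - th[1]) * plogis(th[2] + th[3] * log(u)))
      },
      bmd_u = function(th, R, kind) {
        Ft <- target_f(th[1], R, kind)
        if (Ft >= 1) return(NA_real_)
        exp((qlogis(Ft) - th[2]) / th[3])
      },
      profile = list(free = c(1L, 3L), mk = function(phi, B, R, kind) {
        Ft <- target_f(phi[1], R, kind)
        if (Ft >= 1) return(c(NA_real_, NA_real_, NA_real_))
        c(phi[1], qlogis(Ft) - phi[2] * log(B), phi[2])
      })
    ),
    log_probit = list(
      par_names = c("g", "a", "b"),
      lower = c(1e-8, -40, slope_lo), upper = c(1 - 1e-6, 40, 18),
      start_box = list(lo = c(0.01, -8, max(slope_lo, 0.5)),
                       hi = c(0.6, 4, 5), log = c(FALSE, FALSE, FALSE)),
      trans = c("logit", "identity", "log"),
      prob = function(u, th) {
        ifelse(u <= 0, th[1], th[1] + (1 - th[1]) * pnorm(th[2] + th[3] * log(u)))
      },
      bmd_u = function(th, R, kind) {
        Ft <- target_f(th[1], R, kind)
        if (Ft >= 1) return(NA_real_)
        exp((qnorm(Ft) - th[2]) / th[3])
      },
      profile = list(free = c(1L, 3L), mk = function(phi, B, R, kind) {
        Ft <- target_f(phi[1], R, kind)
        if (Ft >= 1) return(c(NA_real_, NA_real_, NA_real_))
        c(phi[1], qnorm(Ft) - phi[2] * log(B), phi[2])
      })
    ),
    gamma = list(
      par_names = c("g", "a", "b"),
      lower = c(1e-8, power_lo, 1e-8), upper = c(1 - 1e-6, 18, 1e4),
      start_box = list(lo = c(0.01, max(power_lo, 0.8), 0.05),
                       hi = c(0.6, 8, 500), log = c(FALSE, FALSE, TRUE)),
      trans = c("logit", "log", "log"),
      prob = function(u, th) th[1] + (1 - th[1]) * pgamma(th[3] * u, shape = th[2]),
      bmd_u = function(th, R, kind) {
        Ft <- target_f(th[1], R, kind)
        if (Ft >= 1) return(NA_real_)
        qgamma(Ft, shape = th[2]) / th[3]
      },
      profile = list(free = c(1L, 2L), mk = function(phi, B, R, kind) {
        Ft <- target_f(phi[1], R, kind)
        if (Ft >= 1) return(c(NA_real_, NA_real_, NA_real_))
        c(phi[1], phi[2], qgamma(Ft, shape = phi[2]) / B)
      })
    ),
    weibull = list(
      par_names = c("g", "a", "b"),
      lower = c(1e-8, power_lo, 1e-8), upper = c(1 - 1e-6, 18, 1e4),
      start_box = list(lo = c(0.01, max(power_lo, 0.8), 0.05),
                       hi = c(0.6, 8, 500), log = c(FALSE, FALSE, TRUE)),
      trans = c("logit", "log", "log"),
      prob = function(u, th) th[1] + (1 - th[1]) * (1 - exp(-th[3] * u^th[2])),
      bmd_u = function(th, R, kind) {
        Ft <- target_f(th[1], R, kind)
        if (Ft >= 1) return(NA_real_)
        (-log(1 - Ft) / th[3])^(1 / th[2])
      },
      profile = list(free = c(1L, 2L), mk = function(phi, B, R, kind) {
        Ft <- target_f(phi[1], R, kind)
        if (Ft >= 1) return(c(NA_real_, NA_real_, NA_real_))
        c(phi[1], phi[2], -log(1 - Ft) / B^phi[2])
      })
    ),
    quantal_linear = list(
      par_names = c("g", "b"),
      lower = c(1e-8, 1e-8), upper = c(1 - 1e-6, 1e4),
      start_box = list(lo = c(0.01, 0.05), hi = c(0.6, 500), log = c(FALSE, TRUE)),
      trans = c("logit", "log"),
      prob = function(u, th) th[1] + (1 - th[1]) * (1 - exp(-th[2] * u)),
      bmd_u = function(th, R, kind) {
        Ft <- target_f(th[1], R, kind)
        if (Ft >= 1) return(NA_real_)
        -log(1 - Ft) / th[2]
      },
      profile = list(free = 1L, mk = function(phi, B, R, kind) {
        Ft <- target_f(phi[1], R, kind)
        if (Ft >= 1) return(c(NA_real_, NA_real_))
        c(phi[1], -log(1 - Ft) / B)
      })
    ),
    multistage = list(
      # degree resolved at fit time; par_names/bounds built then
      par_names = NULL, lower = NULL, upper = NULL, start_box = NULL,
      trans = NULL, prob = NULL, bmd_u = NULL, profile = NULL
    ),
    dichotomous_hill = list(
      par_names = c("g", "v", "a", "b"),
      lower = c(1e-8, 1e-8, -40, slope_lo), upper = c(1 - 1e-6, 1 - 1e-6, 40, 18),
      start_box = list(lo = c(0.01, 0.3, -10, max(slope_lo, 0.5)),
                       hi = c(0.5, 0.99, 5, 6), log = c(FALSE, FALSE, FALSE, FALSE)),
      trans = c("logit", "logit", "identity", "log"),
      prob = function(u, th) {
        ifelse(u <= 0, th[1], th[1] + (th[2] - th[1]) * plogis(th[3] + th[4] * log(u)))
      },
      bmd_u = function(th, R, kind) {
        Ft <- target_f(th[1], R, kind)
        w <- (th[2] - th[1]) / (1 - th[1])
        if (!is.finite(Ft) || Ft >= w) return(NA_real_)
        exp((qlogis(Ft / w) - th[3]) / th[4])
      },
      profile = list(free = c(1L, 2L, 4L), mk = function(phi, B, R, kind) {
        Ft <- target_f(phi[1], R, kind)
        w <- (phi[2] - phi[1]) / (1 - phi[1])
        if (!is.finite(Ft) || Ft >= w || w <= 0) return(rep(NA_real_, 4))
        c(phi[1], phi[2], qlogis(Ft / w) - phi[3] * log(B), phi[3])
      })
    )
  )
  structure(c(m, list(name = name, degree = degree, restricted = restricted)),
            class = "quantal_model")
}

# target response probability / target F for risk-based BMRs
target_p <- function(p0, level, kind) {
  if (kind == "extra_risk") p0 + level * (1 - p0) else p0 + level
}
target_f <- function(g, level, kind) {
  if (kind == "extra_risk") level else level / (1 - g)
}

# materialize a multistage model of given degree
resolve_multistage <- function(model, n_groups) {
  k <- model$degree %||% max(1L, min(n_groups - 1L, 3L))
  model$degree <- k
  model$par_names <- c("g", paste0("b", seq_len(k)))
  model$lower <- c(1e-8, rep(0, k))
  model$upper <- c(1 - 1e-6, rep(1e4, k))
  model$start_box <- list(lo = c(0.01, rep(1e-3, k)), hi = c(0.6, rep(50, k)),
                          log = c(FALSE, rep(TRUE, k)))
  model$trans <- c("logit", rep("log", k))
  model$prob <- function(u, th) {
    s <- outer(u, seq_len(k), `^`) %*% th[-1]
    th[1] + (1 - th[1]) * (1 - exp(-drop(s)))
  }
  model$bmd_u <- function(th, R, kind) {
    Ft <- target_f(th[1], R, kind)
    if (Ft >= 1) return(NA_real_)
    A <- -log(1 - Ft)
    ms_smallest_root(th[-1], A)
  }
  model$profile <- list(
    free = c(1L, if (k >= 2) seq(3L, k + 1L)),
    mk = function(phi, B, R, kind) {
      Ft <- target_f(phi[1], R, kind)
      if (Ft >= 1) return(rep(NA_real_, k + 1))
      A <- -log(1 - Ft)
      rest <- if (k >= 2) phi[-1] else numeric(0)
      b1 <- (A - sum(rest * B^(seq_len(k)[-1]))) / B
      if (!is.finite(b1) || b1 < 0) return(rep(NA_real_, k + 1))
      c(phi[1], b1, rest)
    }
  )
  model
}

# smallest positive root of sum(beta_i u^i) = A, beta_i >= 0
ms_smallest_root <- function(beta, A) {
  if (all(beta <= 0)) return(NA_real_)
  r <- polyroot(c(-A, beta))
  r <- Re(r[abs(Im(r)) < 1e-8 * (1 + abs(Re(r)))])
  r <- r[r > 0]
  if (length(r) == 0) return(NA_real_)
  min(r)
}

#' @rdname quantal_model
#' @param models Character vector of model names to include.
#' @export
quantal_suite <- function(models = c("logistic", "log_logistic", "probit",
                                     "log_probit", "gamma", "weibull",
                                     "multistage", "quantal_linear",
                                     "dichotomous_hill"),
                          degree = NULL, restricted = TRUE) {
  setNames(lapply(models, quantal_model, degree = degree,
                  restricted = restricted), models)
}

#' @export
print.quantal_model <- function(x, ...) {
  cat("<quantal_model>", x$name,
      if (!is.null(x$degree)) paste0("(degree ", x$degree, ")"),
      if (x$restricted) "[restricted]" else "[unrestricted]", "\n")
  invisible(x)
}
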