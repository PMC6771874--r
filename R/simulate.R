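#' Specify a dose-response simulation design
#'
#' A design bundles a generating model with its true parameters, the dose
#' layout, group size, replicate count and seed, so that every fitting and
#' propagation stage can be exercised against known truth.
#'
#' `params` is interpreted on the *original* dose (and response) scale and
#' rescaled internally to the fitting scale. For continuous designs supply
#' a [continuous_model()], its parameters, and the residual `sigma`.
#'
#' @param model A [quantal_model()] or [continuous_model()].
#' @param params Named true parameter vector (original dose/response scale).
#' @param doses Dose vector (must satisfy the dataset invariants).
#' @param n_per_group Animals per dose group.
#' @param n_replicates Number of replicate datasets.
#' @param seed Integer seed.
#' @param sigma Residual SD (continuous designs, constant variance).
#' @param adverse_direction Continuous designs: `"increase"`/`"decrease"`.
#' @return A `simulation_design` object.
#' @export
simulation_design <- function(model, params, doses, n_per_group = 70,
                              n_replicates = 1, seed = 1, sigma = NULL,
                              adverse_direction = "decrease") {
  stopifnot(n_per_group >= 1, n_replicates >= 1)
  structure(list(model = model, params = params, doses = sort(doses),
                 n_per_group = n_per_group, n_replicates = n_replicates,
                 seed = seed, sigma = sigma,
                 adverse_direction = adverse_direction),
            class = "simulation_design")
}

# evaluate a quantal design's true response probabilities (original doses)
design_prob <- function(design) {
  model <- design$model
  if (model$name == "multistage" && is.null(model$prob)) {
    model <- resolve_multistage(model, length(design$doses))
  }
  dmax <- max(design$doses)
  # parameters are given on the original dose scale; rescale the dose-scale
  # parameters so the normalized-model probability matches
  th <- rescale_params_quantal(model, design$params, dmax)
  p <- model$prob(design$doses / dmax, th)
  if (any(p < -1e-12 | p > 1 + 1e-12) || any(!is.finite(p))) {
    abort("design parameters produce probabilities outside [0, 1]")
  }
  pmin(pmax(p, 0), 1)
}

# dose-scale parameters multiply by dmax^(power they carry)
rescale_params_quantal <- function(model, params, dmax) {
  th <- params
  switch(model$name,
    logistic = ,
    probit = th["b"] <- params["b"] * dmax,
    log_logistic = ,
    log_probit = th["a"] <- params["a"] + params["b"] * log(dmax),
    gamma = ,
    weibull = th["b"] <- params["b"] * dmax^params["a"],
    quantal_linear = th["b"] <- params["b"] * dmax,
    multistage = {
      k <- length(params) - 1
      th[-1] <- params[-1] * dmax^seq_len(k)
    },
    dichotomous_hill = th["a"] <- params["a"] + params["b"] * log(dmax)
  )
  th
}

#' Simulate quantal dose-response datasets from a known model
#'
#' Incidences are drawn binomially around the design model's response
#' probabilities; identical seeds give identical datasets.
#'
#' @param design A [simulation_design()] with a quantal model.
#' @return A list of [as_quantal_data()] datasets (length `n_replicates`).
#' @examples
#' des <- simulation_design(quantal_model("quantal_linear"),
#'                          c(g = 0.1, b = 0.02), c(0, 5, 20, 50),
#'                          n_per_group = 50, seed = 7)
#' simulate_quantal(des)[[1]]
#' @export
simulate_quantal <- function(design) {
  stopifnot(inherits(design, "simulation_design"))
  if (!inherits(design$model, "quantal_model")) {
    abort("design model must be a quantal_model")
  }
  p <- design_prob(design)
  with_seed(design$seed, {
    purrr::map(seq_len(design$n_replicates), function(r) {
      as_quantal_data(tibble(
        dose = design$doses,
        n = design$n_per_group,
        affected = rbinom(length(p), design$n_per_group, p)
      ), endpoint = sprintf("sim_%s_rep%d", design$model$name, r))
    })
  })
}

#' Simulate continuous dose-response summary datasets
#'
#' Individual responses are drawn normally around the design's mean function
#' with constant SD `sigma`, then reduced to per-group (n, mean, sd).
#'
#' @param design A [simulation_design()] with a continuous model and `sigma`.
#' @return A list of [as_continuous_data()] datasets.
#' @export
simulate_continuous <- function(design) {
  stopifnot(inherits(design, "simulation_design"))
  if (!inherits(design$model, "continuous_model")) {
    abort("design model must be a continuous_model")
  }
  if (is.null(design$sigma) || design$sigma <= 0) {
    abort("continuous designs need sigma > 0")
  }
  s <- if (identical(design$adverse_direction, "increase")) 1 else -1
  cm <- build_cmodel(design$model, s)
  dmax <- max(design$doses)
  mu <- cm$mean(design$doses / dmax, rescale_params_continuous(cm, design$params, dmax))
  with_seed(design$seed, {
    purrr::map(seq_len(design$n_replicates), function(r) {
      g <- purrr::map(mu, function(mi) rnorm(design$n_per_group, mi, design$sigma))
      as_continuous_data(tibble(
        dose = design$doses,
        n = design$n_per_group,
        mean = vapply(g, mean, numeric(1)),
        sd = vapply(g, sd, numeric(1))
      ), adverse_direction = design$adverse_direction,
        endpoint = sprintf("sim_%s_rep%d", design$model$name, r))
    })
  })
}

rescale_params_continuous <- function(cm, params, dmax) {
  th <- params
  switch(cm$name,
    linear = th["b"] <- params["b"] * dmax,
    polynomial = {
      k <- length(params) - 1
      th[-1] <- params[-1] * dmax^seq_len(k)
    },
    power = th["b"] <- params["b"] * dmax^params["p"],
    hill = th["kd"] <- params["kd"] / dmax,
    exponential_2 = th["b"] <- params["b"] * dmax,
    exponential_3 = ,
    exponential_5 = th["b"] <- params["b"] * dmax,
    exponential_4 = th["b"] <- params["b"] * dmax
  )
  th
}

#' Simulation design matching the 2-year bioassay layout
#'
#' Builds a quantal design on the bioassay's dose layout (0, 0.1, 1, 50
#' mg/kg/day; 70 per group) whose generating curve is the maximum-likelihood
#' quantal-linear fit to a packaged fixture, so expected incidences
#' approximate the fixture's observed proportions while the truth stays a
#' smooth monotone model with a well-defined, identified benchmark dose.
#' Used for coverage and consistency studies.
#'
#' @param endpoint A [genx_fixtures()] name.
#' @param n_per_group Group size (default 70, the bioassay's).
#' @param n_replicates Number of replicates.
#' @param seed Integer seed.
#' @return A `simulation_design` (quantal-linear truth).
#' @export
table1_like_design <- function(endpoint, n_per_group = 70, n_replicates = 1,
                               seed = 1) {
  fx <- genx_fixture(endpoint)
  fit <- fit_quantal(fx, quantal_model("quantal_linear"))
  # fitted parameters live on the dose/dmax scale; convert back
  params <- c(g = unname(fit$par["g"]), b = unname(fit$par["b"]) / fit$dmax)
  simulation_design(quantal_model("quantal_linear"), params,
                    fx$dose, n_per_group = n_per_group,
                    n_replicates = n_replicates, seed = seed)
}
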