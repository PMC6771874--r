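# shared helpers: hand-built datasets and fit objects with known structure

flat_quantal <- function(p = 0.2, n = 50, doses = c(0, 1, 10, 50)) {
  as_quantal_data(data.frame(dose = doses, n = n, affected = round(p * n)))
}

# a quantal_fit with parameters set by hand (original-dose-scale params are
# converted onto the fitted scale), for closed-form checks
fake_quantal_fit <- function(name, par_raw, doses = c(0, 1, 10, 50),
                             degree = NULL) {
  model <- quantal_model(name, degree = degree)
  if (name == "multistage" && is.null(model$prob)) {
    model <- resolve_multistage_test(model, length(doses))
  }
  dmax <- max(doses)
  th <- bmdtox:::rescale_params_quantal(model, par_raw, dmax)
  p <- model$prob(doses / dmax, th)
  data <- as_quantal_data(data.frame(dose = doses, n = 1000,
                                     affected = round(1000 * p)))
  structure(list(model = model, data = data, dmax = dmax,
                 par = setNames(th, model$par_names),
                 at_bound = rep(FALSE, length(th)),
                 n_est = length(th), log_lik = 0, aic = 0,
                 gof_p = 1, gof_df = 1, gof_statistic = 0,
                 scaled_residuals = rep(0, length(doses)),
                 fitted = p, converged = TRUE),
            class = "quantal_fit")
}

resolve_multistage_test <- function(model, n_groups) {
  bmdtox:::resolve_multistage(model, n_groups)
}

# independent grid-search oracle for the binomial log-likelihood
grid_loglik <- function(data, model, grids) {
  dmax <- max(data$dose)
  u <- data$dose / dmax
  x <- data$affected
  n <- data$n
  best <- -Inf
  grid <- expand.grid(grids)
  for (i in seq_len(nrow(grid))) {
    th <- as.numeric(grid[i, ])
    p <- pmin(pmax(model$prob(u, th), 1e-12), 1 - 1e-12)
    ll <- sum(x * log(p) + (n - x) * log(1 - p))
    if (ll > best) best <- ll
  }
  best
}

rand_quantal_dataset <- function() {
  k <- sample(3:5, 1)
  doses <- c(0, sort(runif(k - 1, 0.5, 100)))
  n <- sample(20:60, 1)
  p <- sort(runif(k, 0.02, 0.9))
  as_quantal_data(data.frame(dose = doses, n = n,
                             affected = rbinom(k, n, p)))
}
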