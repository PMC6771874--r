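cystic_bayes <- NULL
get_cystic_bayes <- function() {
  if (is.null(cystic_bayes)) {
    cystic_bayes <<- fit_bayesian_suite(genx_fixture("cystic_focal_degeneration"))
  }
  cystic_bayes
}

test_that("posterior model weights are proper and symmetric", {
  fits <- get_cystic_bayes()
  w <- posterior_weights(fits)
  expect_equal(sum(w), 1, tolerance = 1e-9)
  expect_true(all(w > 0))
  # a suite of one model carries all the weight
  one <- set_posterior_weights(fits["weibull"])
  expect_equal(posterior_weights(one), c(weibull = 1))
  # two identical models split the weight evenly
  two <- set_posterior_weights(list(a = fits$weibull, b = fits$weibull))
  expect_equal(unname(posterior_weights(two)), c(0.5, 0.5), tolerance = 1e-12)
})

test_that("with flat priors and much data the MAP approaches the MLE", {
  flat <- structure(list(
    background_logit = list(mean = 0, sd = 50),
    asymptote_logit = list(mean = 0, sd = 50),
    location = list(mean = 0, sd = 50),
    log_slope = list(mean = 0, sd = 50),
    log_power = list(mean = 0, sd = 50),
    log_rate = list(mean = 0, sd = 50),
    log_beta = list(mean = 0, sd = 50)
  ), class = "bayes_priors")
  des <- simulation_design(quantal_model("weibull"),
                           c(g = 0.1, a = 1.4, b = 0.05),
                           doses = c(0, 5, 15, 30, 50), n_per_group = 5000,
                           seed = 13)
  d <- simulate_quantal(des)[[1]]
  mle <- fit_quantal(d, "quantal_linear")
  map <- fit_bayesian(d, "quantal_linear", priors = flat)
  expect_equal(unname(map$map), unname(mle$par), tolerance = 0.01)
})

test_that("a point-mass Laplace posterior averages to the deterministic BMD", {
  fits <- get_cystic_bayes()
  f <- fits$log_logistic
  f$cov_z[] <- 0
  one <- set_posterior_weights(list(log_logistic = f))
  ma <- model_average_bmd(one, n_draws = 1e4, seed = 2)
  bmd_map <- bmdtox:::bmd_u_matrix("log_logistic", matrix(f$map, 1),
                                   0.10, "extra_risk") * f$dmax
  expect_equal(ma$bmd_ma, as.numeric(bmd_map), tolerance = 1e-9)
  expect_equal(ma$bmdl_ma, ma$bmd_ma, tolerance = 1e-9)
})

test_that("mixture draws are reproducible and stable in the draw count", {
  fits <- get_cystic_bayes()
  ma1 <- model_average_bmd(fits, n_draws = 2e4, seed = 5)
  ma2 <- model_average_bmd(fits, n_draws = 2e4, seed = 5)
  expect_identical(ma1$bmd_ma, ma2$bmd_ma)
  expect_identical(ma1$bmdl_ma, ma2$bmdl_ma)
  ma4 <- model_average_bmd(fits, n_draws = 4e4, seed = 6)
  expect_lt(abs(ma4$bmd_ma - ma1$bmd_ma) / ma1$bmd_ma, 0.03)
  expect_lte(ma1$bmdl_ma, ma1$bmd_ma)
  expect_error(model_average_bmd(fits, n_draws = 100), "10\\^4")
})

test_that("model-averaged BMD and BMDL are dose-scale equivariant", {
  d <- genx_fixture("cystic_focal_degeneration")
  d2 <- as_quantal_data(transform(as.data.frame(d), dose = dose * 4))
  fits1 <- fit_bayesian_suite(d, models = quantal_suite(
    c("quantal_linear", "weibull"), degree = 2))
  fits2 <- fit_bayesian_suite(d2, models = quantal_suite(
    c("quantal_linear", "weibull"), degree = 2))
  ma1 <- model_average_bmd(fits1, n_draws = 1e4, seed = 9)
  ma2 <- model_average_bmd(fits2, n_draws = 1e4, seed = 9)
  expect_equal(ma2$bmd_ma, 4 * ma1$bmd_ma, tolerance = 1e-6)
  expect_equal(ma2$bmdl_ma, 4 * ma1$bmdl_ma, tolerance = 1e-6)
})
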