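test_that("flat incidence data fit to background with zero slope", {
  d <- flat_quantal(p = 0.2, n = 50)
  f <- fit_quantal(d, "quantal_linear")
  expect_equal(unname(f$par["g"]), 0.2, tolerance = 1e-4)
  expect_lt(unname(f$par["b"]), 1e-5)
  # likelihood equals the constant model's
  ll_const <- sum(10 * log(0.2) + 40 * log(0.8)) * 4
  expect_equal(f$log_lik, ll_const, tolerance = 1e-6)
  # a BMD does not exist when the slope is flat
  expect_error(compute_bmd(f), class = "bmdtox_no_bmd_error")
})

test_that("optimizer matches a brute-force grid oracle on small models", {
  d <- genx_fixture("cystic_focal_degeneration")
  m_ql <- quantal_model("quantal_linear")
  f_ql <- fit_quantal(d, m_ql)
  oracle_ql <- grid_loglik(d, m_ql, list(g = seq(0.05, 0.6, length.out = 120),
                                         b = exp(seq(log(0.01), log(50),
                                                     length.out = 200))))
  expect_gte(f_ql$log_lik, oracle_ql - 1e-3)

  m_ll <- quantal_model("log_logistic")
  f_ll <- fit_quantal(d, m_ll)
  oracle_ll <- grid_loglik(d, m_ll, list(g = seq(0.2, 0.45, length.out = 30),
                                         a = seq(-20, 5, length.out = 60),
                                         b = seq(1, 8, length.out = 40)))
  expect_gte(f_ll$log_lik, oracle_ll - 1e-3)
})

test_that("generating parameters are recovered from large synthetic samples", {
  # mean estimate across replicates vs generator truth (binomial noise at
  # n = 1e4/group leaves ~2% Monte Carlo error on the background)
  b <- 2; a <- -b * log(10)  # ED50 = 10
  des <- simulation_design(quantal_model("log_logistic"),
                           c(g = 0.05, a = a, b = b),
                           doses = c(0, 2, 5, 10, 20, 50),
                           n_per_group = 1e4, n_replicates = 4, seed = 7)
  fits <- lapply(simulate_quantal(des), fit_quantal, model = "log_logistic")
  est <- sapply(fits, function(f) {
    a_raw <- unname(f$par["a"] - f$par["b"] * log(f$dmax))
    c(g = unname(f$par["g"]), b = unname(f$par["b"]),
      ed50 = exp(-a_raw / unname(f$par["b"])))
  })
  est_mean <- rowMeans(est)
  expect_equal(est_mean[["g"]], 0.05, tolerance = 0.05)
  expect_equal(est_mean[["b"]], 2, tolerance = 0.05)
  expect_equal(est_mean[["ed50"]], 10, tolerance = 0.05)
})

test_that("a perfectly fitting model has zero chi-square and residuals", {
  # quantal-linear curve passing exactly through integer incidences
  g <- 0.2; bq <- 1
  doses <- c(0, log(4 / 3), log(2))  # P = 0.2, 0.4, 0.6
  d <- as_quantal_data(data.frame(dose = doses, n = 50,
                                  affected = c(10, 20, 30)))
  f <- fit_quantal(d, "quantal_linear")
  expect_equal(f$gof_statistic, 0, tolerance = 1e-6)
  expect_equal(max(abs(f$scaled_residuals)), 0, tolerance = 1e-3)
  g1 <- goodness_of_fit(f)
  expect_equal(g1$table$expected, d$affected, tolerance = 1e-3)
})

test_that("goodness-of-fit p is near-uniform when the model is true", {
  des <- simulation_design(quantal_model("quantal_linear"),
                           c(g = 0.15, b = 0.02),
                           doses = c(0, 5, 15, 30, 50), n_per_group = 100,
                           n_replicates = 150, seed = 99)
  ps <- vapply(simulate_quantal(des), function(d) {
    fit_quantal(d, "quantal_linear", n_starts = 5)$gof_p
  }, numeric(1))
  expect_gt(mean(ps), 0.40)
  expect_lt(mean(ps), 0.60)
})

test_that("degenerate incidence patterns fit at the parameter bounds, not by failure", {
  zero <- as_quantal_data(data.frame(dose = c(0, 1, 10, 50), n = 20, affected = 0))
  f0 <- fit_quantal(zero, "quantal_linear")
  expect_true(f0$converged)
  expect_lt(unname(f0$par["g"]), 1e-4)
  all1 <- as_quantal_data(data.frame(dose = c(0, 1, 10, 50), n = 20, affected = 20))
  f1 <- fit_quantal(all1, "quantal_linear")
  expect_true(f1$converged)
  expect_gt(predict(f1, 0), 0.999)
})

test_that("tidy and glance expose fit terms and summaries", {
  f <- fit_quantal(genx_fixture("cystic_focal_degeneration"), "weibull")
  td <- tidy(f)
  expect_named(td, c("term", "estimate", "at_bound"))
  expect_equal(td$term, c("g", "a", "b"))
  gl <- glance(f)
  expect_equal(gl$model, "weibull")
  expect_equal(gl$aic, -2 * gl$log_lik + 2 * gl$n_est)
})
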