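test_that("dose-flat continuous data fit with a null slope", {
  d <- as_continuous_data(data.frame(dose = c(0, 5, 20, 50), n = 20,
                                     mean = 100, sd = 8))
  f <- fit_continuous(d, "linear")
  b_raw <- unname(f$par["b"]) * f$y_scale / f$dmax
  expect_lt(abs(b_raw), 1e-4)
  expect_error(compute_bmd(f, bmr_sd()), class = "bmdtox_no_bmd_error")
})

test_that("the summary-statistic likelihood equals the individual-data likelihood", {
  set.seed(5)
  n <- c(8, 10, 12)
  mu <- c(100, 90, 70)
  sigma <- 6
  y <- lapply(seq_along(n), function(i) rnorm(n[i], mu[i], sigma))
  m <- vapply(y, mean, numeric(1))
  s2 <- vapply(y, var, numeric(1))
  mu_try <- c(99, 91, 72)
  ll_groups <- bmdtox:::ll_normal_groups(n, m, s2, mu_try, sigma^2)
  ll_indiv <- sum(unlist(lapply(seq_along(y), function(i) {
    dnorm(y[[i]], mu_try[i], sigma, log = TRUE)
  })))
  expect_equal(ll_groups, ll_indiv, tolerance = 1e-10)
})

test_that("generating parameters of an exponential curve are recovered", {
  des <- simulation_design(continuous_model("exponential_3"),
                           c(a = 100, b = 0.02, p = 1.5),
                           doses = c(0, 5, 10, 20, 40), n_per_group = 500,
                           n_replicates = 3, seed = 5, sigma = 5,
                           adverse_direction = "decrease")
  est <- sapply(simulate_continuous(des), function(d) {
    f <- fit_continuous(d, "exponential_3")
    c(a = unname(f$par["a"]) * f$y_scale,
      b = unname(f$par["b"]) / f$dmax,
      p = unname(f$par["p"]))
  })
  em <- rowMeans(est)
  expect_equal(em[["a"]], 100, tolerance = 0.05)
  expect_equal(em[["b"]], 0.02, tolerance = 0.05)
  expect_equal(em[["p"]], 1.5, tolerance = 0.05)
})

test_that("continuous BMDs follow their closed forms", {
  # linear mean 100 - 2 d, constant sigma: BMD_1SD = sigma/|b|, BMD_5% = 2.5
  set.seed(8)
  doses <- c(0, 2, 5, 10)
  d <- as_continuous_data(data.frame(dose = doses, n = 1000,
                                     mean = 100 - 2 * doses, sd = 4))
  f <- fit_continuous(d, "linear")
  b_raw <- abs(unname(f$par["b"])) * f$y_scale / f$dmax
  sigma_raw <- f$sigma_hat * f$y_scale
  expect_equal(compute_bmd(f, bmr_sd(1)), sigma_raw / b_raw, tolerance = 1e-6)
  expect_equal(compute_bmd(f, bmr_rel(0.05)), 0.05 * 100 / 2, tolerance = 0.01)
})

test_that("continuous BMDL stays below the BMD and scales with dose", {
  des <- simulation_design(continuous_model("power"),
                           c(a = 50, b = 0.4, p = 1.2),
                           doses = c(0, 5, 15, 40), n_per_group = 30,
                           seed = 21, sigma = 4,
                           adverse_direction = "increase")
  d <- simulate_continuous(des)[[1]]
  f <- fit_continuous(d, continuous_model("power"))
  bmd <- compute_bmd(f, bmr_sd())
  bmdl <- compute_bmdl(f, bmr_sd())
  expect_lte(as.numeric(bmdl), bmd)
  d2 <- as_continuous_data(transform(as.data.frame(d), dose = dose * 2),
                           adverse_direction = "increase")
  f2 <- fit_continuous(d2, continuous_model("power"))
  expect_equal(compute_bmd(f2, bmr_sd()), 2 * bmd, tolerance = 1e-7)
})

test_that("the 1-SD BMD is invariant to rescaling the response units", {
  des <- simulation_design(continuous_model("linear"),
                           c(a = 100, b = -1.5),
                           doses = c(0, 5, 15, 40), n_per_group = 50,
                           seed = 33, sigma = 6)
  d <- simulate_continuous(des)[[1]]
  f <- fit_continuous(d, "linear")
  d_scaled <- as_continuous_data(transform(as.data.frame(d),
                                           mean = mean * 17, sd = sd * 17))
  f_scaled <- fit_continuous(d_scaled, "linear")
  expect_equal(compute_bmd(f_scaled, bmr_sd()), compute_bmd(f, bmr_sd()),
               tolerance = 1e-7)
})

test_that("zero-variance groups are rejected before fitting", {
  expect_error(as_continuous_data(data.frame(dose = c(0, 1, 10), n = 10,
                                             mean = 1, sd = c(1, 0, 1))),
               class = "bmdtox_validation_error")
})
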