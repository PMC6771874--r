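test_that("every suite model is a monotone probability under default constraints", {
  set.seed(31)
  u <- seq(0, 1, length.out = 101)
  suite <- quantal_suite()
  suite$multistage <- bmdtox:::resolve_multistage(suite$multistage, 4)
  for (m in suite) {
    box <- m$start_box
    for (rep in 1:20) {
      th <- runif(length(m$lower), box$lo, box$hi)
      if (m$name == "dichotomous_hill") th[2] <- max(th[2], th[1] + 0.01)
      p <- m$prob(u, pmin(pmax(th, m$lower), m$upper))
      expect_true(all(p >= -1e-12 & p <= 1 + 1e-12))
      expect_true(all(diff(p) >= -1e-9),
                  label = paste(m$name, "non-decreasing"))
    }
  }
})

test_that("quantal-linear BMD has the closed form -log(1 - BMR)/beta, independent of background", {
  for (g in c(0.05, 0.2, 0.4)) {
    fit <- fake_quantal_fit("quantal_linear", c(g = g, b = 0.1))
    expect_equal(compute_bmd(fit, bmr_extra(0.10)), -log(0.9) / 0.1,
                 tolerance = 1e-10)
  }
  expect_equal(-log(0.9) / 0.1, 1.05361, tolerance = 1e-5)
})

test_that("extra risk matches its definition and limits", {
  # background 24/70 rising to 0.6 at dose 50: ER = (0.6 - p0)/(1 - p0)
  p0 <- 24 / 70
  er50 <- (0.6 - p0) / (1 - p0)
  b <- -log(1 - er50) / 50
  fit <- fake_quantal_fit("quantal_linear", c(g = p0, b = b))
  expect_equal(extra_risk(fit, 50), 0.3913, tolerance = 1e-3)
  expect_equal(extra_risk(fit, 0), 0)
  # saturating model: extra risk approaches 1
  expect_equal(extra_risk(fit, 1e7), 1, tolerance = 1e-6)
  # monotone non-decreasing in dose
  er <- extra_risk(fit, seq(0, 100, by = 1))
  expect_true(all(diff(er) >= 0))
  expect_equal(added_risk(fit, 50), 0.6 - p0, tolerance = 1e-9)
})

test_that("BMD and BMDL are exactly equivariant under dose rescaling", {
  d <- genx_fixture("cystic_focal_degeneration")
  for (mname in c("weibull", "quantal_linear")) {
    f1 <- fit_quantal(d, mname, seed = 4)
    d2 <- as_quantal_data(transform(as.data.frame(d), dose = dose * 3.7))
    f2 <- fit_quantal(d2, mname, seed = 4)
    expect_equal(compute_bmd(f2), 3.7 * compute_bmd(f1), tolerance = 1e-9)
    expect_equal(compute_bmdl(f2), 3.7 * compute_bmdl(f1), tolerance = 1e-6)
  }
})

test_that("multistage polynomial root solver finds the smallest positive root", {
  # b1 x + b2 x^2 = A with b = (0.1, 0.01), A = 0.2 -> x = 1.70156 (quadratic)
  b <- c(0.1, 0.01); A <- 0.2
  x <- bmdtox:::ms_smallest_root(b, A)
  expect_equal(b[1] * x + b[2] * x^2, A, tolerance = 1e-9)
  expect_equal(bmdtox:::ms_smallest_root(c(0.1, 0), A), 2, tolerance = 1e-9)
  expect_true(is.na(bmdtox:::ms_smallest_root(c(0, 0), A)))
})
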