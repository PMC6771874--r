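test_that("quantal simulation is deterministic under its seed", {
  des <- simulation_design(quantal_model("quantal_linear"),
                           c(g = 0.1, b = 0.02), c(0, 5, 20, 50),
                           n_per_group = 50, n_replicates = 3, seed = 77)
  a <- simulate_quantal(des)
  b <- simulate_quantal(des)
  expect_identical(lapply(a, as.data.frame), lapply(b, as.data.frame))
  # and does not disturb the caller's RNG stream
  set.seed(1); before <- runif(1)
  set.seed(1); invisible(simulate_quantal(des)); after <- runif(1)
  expect_identical(before, after)
})

test_that("a null response curve yields all-zero incidence", {
  des <- simulation_design(quantal_model("quantal_linear"),
                           c(g = 0, b = 0), c(0, 5, 20, 50),
                           n_per_group = 100, seed = 3)
  d <- simulate_quantal(des)[[1]]
  expect_true(all(d$affected == 0))
})

test_that("observed proportions approach the generating curve at large n", {
  des <- simulation_design(quantal_model("weibull"),
                           c(g = 0.08, a = 1.3, b = 0.02),
                           c(0, 5, 20, 50), n_per_group = 1e6, seed = 19)
  d <- simulate_quantal(des)[[1]]
  p_true <- bmdtox:::design_prob(des)
  expect_lt(max(abs(d$affected / d$n - p_true)), 0.002)
})

test_that("bad design parameters are rejected before sampling", {
  des_bad <- simulation_design(quantal_model("quantal_linear"),
                               c(g = 1.4, b = 0.1), c(0, 5, 20, 50), seed = 1)
  expect_error(simulate_quantal(des_bad), "outside")
})

test_that("continuous simulation reproduces its moments and validates sigma", {
  des <- simulation_design(continuous_model("linear"), c(a = 100, b = -0.8),
                           c(0, 10, 30, 60), n_per_group = 2e4, seed = 23,
                           sigma = 7)
  d <- simulate_continuous(des)[[1]]
  expect_s3_class(d, "continuous_data")
  expect_lt(max(abs(d$sd - 7)) / 7, 0.02)
  expect_lt(max(abs(d$mean - (100 - 0.8 * d$dose))), 0.5)
  a <- simulate_continuous(des)
  b <- simulate_continuous(des)
  expect_identical(lapply(a, as.data.frame), lapply(b, as.data.frame))
  des$sigma <- 0
  expect_error(simulate_continuous(des), "sigma")
})

test_that("the bioassay-layout design tracks the fixture's observed proportions", {
  des <- table1_like_design("cystic_focal_degeneration")
  expect_equal(des$doses, c(0, 0.1, 1, 50))
  expect_equal(des$n_per_group, 70)
  p <- bmdtox:::design_prob(des)
  fx <- genx_fixture("cystic_focal_degeneration")
  expect_lt(max(abs(p - fx$affected / fx$n)), 0.06)
  # generated replicates satisfy the dataset invariants by construction
  d <- simulate_quantal(des)[[1]]
  expect_s3_class(d, "quantal_data")
})

test_that("fitted BMDs stabilize when the design's group size is inflated", {
  des <- table1_like_design("cystic_focal_degeneration", n_per_group = 1e5,
                            n_replicates = 4, seed = 41)
  bmds <- vapply(simulate_quantal(des), function(d) {
    compute_bmd(fit_quantal(d, "quantal_linear", n_starts = 6))
  }, numeric(1))
  expect_lt(sd(bmds) / mean(bmds), 0.02)
})
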