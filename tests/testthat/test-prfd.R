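test_that("the animal-dose distribution reproduces its BMD/BMDL anchors", {
  ad <- ad_from_bmd(14.2, 6.4)
  expect_equal(ad$p50, 14.2)
  expect_equal(ad$sigma, log(14.2 / 6.4) / qnorm(0.95), tolerance = 1e-12)
  expect_equal(ad$sigma, 0.4846, tolerance = 1e-3)
  q <- quantile(ad, c(0.05, 0.5))
  expect_equal(unname(q), c(6.4, 14.2), tolerance = 1e-12)
  # equal limits give a point mass
  pm <- ad_from_bmd(5, 5)
  expect_equal(pm$sigma, 0)
  expect_error(ad_from_bmd(5, 6), "exceed")
})

test_that("a fully degenerate chain returns the BMDL input unchanged", {
  unit <- lognormal_uncertain(1, 1)
  ch <- prfd_chain(ad_from_bmd(14.2, 6.4), unit, unit, unit, uf_d = 1)
  res <- propagate(ch, method = "closed_form")
  expect_equal(res$prfd_raw, 6.4, tolerance = 1e-12)
})

test_that("Monte Carlo and closed-form evaluators agree", {
  af <- default_adjustment_factors(0.29)
  ch <- prfd_chain(ad_from_bmd(14.2, 6.4), af$af_bw, af$af_tktd, af$af_h,
                   n_samples = 2e5, seed = 42)
  res <- propagate(ch, method = "both")
  for (p in names(res$closed_form$hdI)) {
    expect_equal(res$monte_carlo$hdI[[p]], res$closed_form$hdI[[p]],
                 tolerance = 0.02, label = paste("hdI", p))
  }
  expect_equal(res$monte_carlo$hdI[["p5"]], res$closed_form$hdI[["p5"]],
               tolerance = 0.01)
  # percentile tables are monotone
  expect_true(all(diff(res$hd_I_summary) > 0))
  expect_true(all(diff(res$hd50_summary) > 0))
})

test_that("widening any single factor lowers the 5th percentile", {
  af <- default_adjustment_factors(0.29)
  base <- propagate(prfd_chain(ad_from_bmd(14.2, 6.4), af$af_bw, af$af_tktd,
                               af$af_h), method = "closed_form")
  for (nm in c("af_bw", "af_tktd", "af_h")) {
    af2 <- af
    af2[[nm]] <- lognormal_uncertain(af[[nm]]$p50, af[[nm]]$p95_over_p50 * 1.5)
    wide <- propagate(prfd_chain(ad_from_bmd(14.2, 6.4), af2$af_bw,
                                 af2$af_tktd, af2$af_h),
                      method = "closed_form")
    expect_lt(wide$hd_I_p05, base$hd_I_p05)
  }
})

test_that("the median of the median-human distribution is the exact quotient of medians", {
  af <- default_adjustment_factors(0.29)
  res <- propagate(prfd_chain(ad_from_bmd(14.2, 6.4), af$af_bw, af$af_tktd,
                              af$af_h), method = "closed_form")
  expect_equal(unname(res$hd50_summary["p50"]),
               14.2 / (af$af_bw$p50 * af$af_tktd$p50), tolerance = 1e-12)
})

test_that("a 50% target incidence degenerates the human-variability factor", {
  af <- default_adjustment_factors(0.29, incidence = 0.5)
  expect_equal(af$af_h$p50, 1)
  expect_equal(af$af_h$sigma, 0)
  res <- propagate(prfd_chain(ad_from_bmd(14.2, 6.4), af$af_bw, af$af_tktd,
                              af$af_h, incidence = 0.5),
                   method = "closed_form")
  expect_equal(unname(res$hd_I_summary), unname(res$hd50_summary))
})

test_that("the variance budget partitions the log-scale variance", {
  unit <- lognormal_uncertain(1, 1)
  only_ad <- prfd_chain(ad_from_bmd(14.2, 6.4), unit, unit, unit)
  vb <- variance_budget(only_ad)
  expect_equal(unname(vb["ad"]), 1)
  two <- prfd_chain(ad_from_bmd(14.2, 6.4), lognormal_uncertain(2, 14.2 / 6.4),
                    unit, unit)
  vb2 <- variance_budget(two)
  expect_equal(unname(vb2[c("ad", "af_bw")]), c(0.5, 0.5), tolerance = 1e-12)
  af <- default_adjustment_factors(0.29)
  full <- prfd_chain(ad_from_bmd(14.2, 6.4), af$af_bw, af$af_tktd, af$af_h)
  expect_equal(sum(variance_budget(full)), 1, tolerance = 1e-12)
  expect_warning(variance_budget(prfd_chain(ad_from_bmd(5, 5), unit, unit,
                                            unit)),
                 "degenerate")
})

test_that("chain construction guards its preconditions", {
  unit <- lognormal_uncertain(1, 1)
  ad <- ad_from_bmd(14.2, 6.4)
  expect_error(prfd_chain(ad, unit, unit, unit, n_samples = 100), "10\\^4")
  expect_error(prfd_chain(ad, unit, unit, unit, incidence = 0.7), "incidence")
  expect_error(lognormal_uncertain(1, 0.5))
})
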