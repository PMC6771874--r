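test_that("packaged bioassay fixtures carry the published incidences", {
  fx <- genx_fixture("cystic_focal_degeneration")
  expect_s3_class(fx, "quantal_data")
  expect_equal(fx$dose, c(0, 0.1, 1, 50))
  expect_equal(fx$n, rep(70L, 4))
  expect_equal(fx$affected, c(24, 24, 19, 42))
  expect_equal(genx_fixture("centrilobular_hypertrophy")$affected, c(0, 0, 0, 7))
  expect_equal(genx_fixture("centrilobular_necrosis")$affected, c(1, 0, 1, 5))
  # every fixture satisfies the dataset invariants (construction validates)
  for (nm in genx_fixtures()) {
    d <- genx_fixture(nm)
    expect_true(all(d$affected <= d$n))
    expect_true(all(diff(d$dose) > 0))
    expect_identical(d$dose[1], 0)
  }
  expect_error(genx_fixture("nope"), "available", class = "bmdtox_lookup_error")
})

test_that("quantal validation rejects malformed tables with informative errors", {
  ok <- data.frame(dose = c(0, 1, 10), n = 70, affected = c(1, 2, 3))
  expect_s3_class(as_quantal_data(ok), "quantal_data")
  expect_error(as_quantal_data(transform(ok, affected = c(1, 71, 3))),
               "exceeds group size", class = "bmdtox_validation_error")
  expect_error(as_quantal_data(data.frame(dose = c(0, 1, 1), n = 70,
                                          affected = 1)),
               "duplicate", class = "bmdtox_validation_error")
  expect_error(as_quantal_data(data.frame(dose = c(1, 2, 3), n = 70,
                                          affected = 1)),
               "control", class = "bmdtox_validation_error")
  expect_error(as_quantal_data(data.frame(dose = c(0, 1), n = 70, affected = 1)),
               "at least 3", class = "bmdtox_validation_error")
  expect_error(as_quantal_data(data.frame(dose = 0:2, x = 1)),
               "missing", class = "bmdtox_format_error")
  # rows are normalized by dose on input
  shuffled <- as_quantal_data(ok[c(3, 1, 2), ])
  expect_equal(shuffled$dose, c(0, 1, 10))
})

test_that("continuous validation enforces sd > 0 and n >= 2", {
  ok <- data.frame(dose = c(0, 1, 10), n = 10, mean = c(100, 95, 80), sd = 5)
  expect_s3_class(as_continuous_data(ok), "continuous_data")
  expect_error(as_continuous_data(transform(ok, sd = c(5, 0, 5))),
               "positive", class = "bmdtox_validation_error")
  expect_error(as_continuous_data(transform(ok, n = c(10, 1, 10))),
               "n >= 2", class = "bmdtox_validation_error")
})

test_that("delimited round trips are the identity and delimiters auto-detect", {
  d <- genx_fixture("cystic_focal_degeneration")
  path <- withr::local_tempfile(fileext = ".csv")
  write_dose_table(d, path)
  d2 <- read_quantal(path)
  expect_equal(as.data.frame(d2), as.data.frame(d), ignore_attr = TRUE)

  # tab-separated variant of the same table
  tsv <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("dose\tn\taffected",
               apply(as.data.frame(d), 1, paste, collapse = "\t")), tsv)
  expect_equal(read_quantal(tsv)$affected, d$affected)

  cd <- as_continuous_data(data.frame(dose = c(0, 1, 10), n = 10,
                                      mean = c(100, 95, 80), sd = 5))
  pc <- withr::local_tempfile(fileext = ".csv")
  write_dose_table(cd, pc)
  expect_equal(as.data.frame(read_continuous(pc)), as.data.frame(cd),
               ignore_attr = TRUE)
  expect_error(read_quantal(file.path(tempdir(), "missing-file.csv")), "no such")
})

test_that("benchmark response constructors validate their levels", {
  expect_equal(bmr_extra(0.1)$kind, "extra_risk")
  expect_error(bmr_extra(0))
  expect_error(bmr_extra(1))
  expect_error(bmr_rel(-0.05))
  expect_equal(format(bmr_sd()), "1 control SD")
})
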