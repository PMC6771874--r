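Package: bmdtox
Title: Benchmark Dose Modeling and Probabilistic Reference Dose Derivation
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com", role = c("aut", "cre"))
Description: Dose-response modeling tools for chemical risk assessment:
    maximum-likelihood fitting of the standard dichotomous and continuous
    benchmark-dose model suites with profile-likelihood lower confidence
    bounds (BMDL), Bayesian model averaging with Laplace-approximated
    posterior model weights, human-equivalent-dose conversion by allometric
    scaling, deterministic reference dose (RfD) derivation with half-log
    uncertainty factors, probabilistic RfD derivation by lognormal
    adjustment-factor propagation, and drinking-water guideline (MCLG)
    calculation. Ships the incidence tables of the 2-year GenX (HFPO-DA)
    rat bioassay as worked fixtures and a synthetic dose-response
    generator for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    lhs,
    pracma,
    purrr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
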