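Package: nomacost
Title: Economic and Social Cost-of-Illness Modelling for Noma
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools for estimating the economic and social burden of noma
    (cancrum oris) at country level. Implements a prevalence cascade from
    the population at risk through potential cases, cases receiving care
    and untreated deaths; a direct-cost ledger driven by a configurable
    unit-cost schedule; human-capital indirect costs (lost production,
    premature mortality valued over years of life lost, inability to
    marry); one-way and Monte-Carlo sensitivity analysis; and a synthetic
    country-profile generator with known ground truth. All head counts and
    dollar totals are computed with exact integer-ratio arithmetic so that
    published table values are reproduced to the unit. Ships fully
    specified country configurations for Burkina Faso and Niger (2018)
    together with the published table values for cell-by-cell validation.
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
    purrr,
    readr,
    rlang,
    tibble,
    tidyr,
    utils,
    withr,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
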