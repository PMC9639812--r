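Package: odelay
Title: Delay-Phase Analysis of Yeast Growth Curves Under Autotoxin Killing
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for quantitative analysis of optical-density (OD) growth
    curves from glucose-starved fission yeast cultures exposed to secreted
    autotoxins. Implements a two-compartment (living + dead) forward model in
    which dead-cell optical mass masks survivor regrowth and produces an
    apparent delay phase; estimation of the initial OD, steady growth rate and
    the doubling statistic tau from turbidimeter traces; inversion of the
    model to estimate kill fractions and comparison with viability-staining
    flow counts; dose-response critical-concentration estimation; prediction
    of two-label competition steady states from growth parameters; the
    conditioned-medium inhibitor-candidate screen; and a seeded synthetic-data
    generator emulating 1-minute OD traces, flow-cytometry count tables and
    compound presence tables.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    deSolve,
    jsonlite,
    stats,
    utils,
    withr,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
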