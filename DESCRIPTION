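Package: crcdisrupt
Title: Modelling Pandemic Disruptions to Colorectal Cancer Screening,
    Diagnosis and Treatment
Version: 0.1.0
Authors@R:
    person("Model", "Maintainers", email = "maintainers@example.org",
           role = c("aut", "cre"))
Description: A desk-scale pipeline for estimating the downstream burden of
    temporary disruptions to colorectal cancer (CRC) control: a synthetic
    natural-history generator producing screen-detected and symptomatic case
    streams that respond to screening-participation shocks, conversion of
    observed procedure-volume changes into capacity-multiplier timelines,
    stochastic (agent) and deterministic (aggregate) backlog queue engines
    yielding per-patient additional waits, translation of waits into excess
    mortality via a hazard ratio per four-week delay and into stage shifts
    via annual upstage rates, counterfactual scenario composition with
    capacity-mitigation options, and age-standardised rate reporting using
    the Segi world standard population.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    data.table,
    jsonlite,
    stats,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
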