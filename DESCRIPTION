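Package: thmrisk
Title: Probabilistic Multi-Pathway Cancer Risk from Trihalomethanes in
    Drinking Water
Version: 1.0.0
Authors@R: person("thmrisk", "developers", email = "thmrisk@example.org",
    role = c("aut", "cre"))
Description: Monte Carlo assessment of lifetime cancer risk from the four
    regulated trihalomethanes (TCM, BDCM, DBCM, TBM) in chlorinated tap
    water, via ingestion, dermal contact, and inhalation during showering.
    Implements triangular-distribution sampling of exposure factors, a
    single-compartment shower-stall volatilization model with a
    successive-shower accumulation rule for shared bathrooms, a
    heated-water trihalomethane formation adjustment, duration and
    ventilation sensitivity scans with trend fitting, and a calibrated
    synthetic water-quality generator standing in for site measurements.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
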