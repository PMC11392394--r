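Package: ventalloc
Title: Monte Carlo Simulation of Crisis-Standards-of-Care Ventilator Triage
Version: 0.1.0
Authors@R: person("Ventalloc", "Maintainers", email = "maintainers@ventalloc.org",
    role = c("aut", "cre"))
Description: Simulates capacity-constrained ventilator allocation under six
    crisis-standards-of-care triage protocols (lottery, age bands, pure SOFA,
    New York 2015 SOFA tiers, Maryland 2021 SOFA plus comorbidity points,
    Colorado 2020 SOFA plus age-adjusted Charlson points) using a pair-based
    Monte Carlo scarcity model. Provides encounter-cohort readers and a
    calibrated synthetic-cohort generator, comorbidity-adjusted remaining
    life-expectancy accounting from life tables, and survival, allocation,
    lives-saved, life-years-saved and age-standardized equity metrics with
    confidence intervals (including modified-gamma intervals for directly
    standardized rates).
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    parallel,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
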