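Package: ohtsim
Title: Discrete Event Simulation of Ocular Hypertension Monitoring and Treatment
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"), email = "author@example.org")
Description: Patient-level discrete event simulation of ocular hypertension
    (OHT) monitoring and treatment in a UK-style care pathway. Synthesizes OHT
    cohorts from published marginal statistics, models conversion to glaucoma
    and visual-field progression as competing time-to-event processes, and
    compares a risk-prediction treatment-initiation rule against a standard-care
    decision table in terms of lifetime discounted costs and QALYs, including
    one-way and probabilistic sensitivity analyses with cost-effectiveness
    acceptability curves.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
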