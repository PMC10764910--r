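Package: statinsim
Title: EMR-Based Statin-Intolerance Phenotyping and Simulation of Oral
    Lipid-Lowering Therapy Escalation
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Rule-based phenotyping of statin intolerance (absolute or
    partial) from longitudinal outpatient prescription records, assignment
    of 2019 ESC/EAS cardiovascular risk categories and LDL-C treatment
    targets, and a seeded Monte Carlo simulation of stepwise oral
    lipid-lowering therapy escalation (ezetimibe followed by bempedoic
    acid) with beta-distributed fractional LDL-C reductions aggregated by
    the median of per-run means.  Includes a synthetic electronic-medical-
    record cohort generator with planted intolerance patterns so the whole
    pipeline is testable without access to proprietary claims data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite,
    optparse
Config/testthat/edition: 3
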