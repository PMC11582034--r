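Package: rdmdea
Title: Range Directional DEA for Medication Efficiency Benchmarking
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Benchmarks decision-making units (drugs) with the range directional
    model (RDM), a data envelopment analysis variant built on the directional
    distance function that remains well-defined for negative data and treats
    undesirable outputs (e.g. mortality odds ratios) like inputs via their own
    improvement ranges. Solves the variable returns-to-scale envelopment linear
    program per unit, reports inefficiency scores, intensity weights, reference
    sets and two-phase slack diagnostics, ranks units with competition ranking,
    compares approval-era means, and generates synthetic drug-profile panels and
    planted-inefficiency instances for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    ggplot2,
    optparse,
    jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
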