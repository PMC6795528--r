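Package: cnaclonality
Title: Clonality Analysis of Tumor Pairs from Genome-Wide Copy Number Profiles
Version: 0.1.0
Authors@R: person("Package", "Maintainer", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Determines whether two tumors from one patient are clonally
    related (metastasis) or independent primaries by comparing their
    genome-wide copy number aberration (CNA) profiles. Implements a
    segmented-profile Pearson correlation statistic with a calibrated
    decision cut-off, a deterministic conclusive/inconclusive quality gate,
    cross-validated cut-off calibration on non-clonal reference pairs,
    Martini-Melamed and ACCP-2013 clinicopathological rule engines,
    concordance and McNemar comparison statistics, and a synthetic cohort
    generator for paired tumor CNA profiles.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    tools,
    graphics,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
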