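Package: refstab
Title: Reference-Gene Stability Validation for RT-qPCR with Efficiency
    Correction
Version: 0.1.0
Authors@R: person("refstab", "maintainers", email = "refstab@example.org",
    role = c("aut", "cre"))
Description: Validation of candidate reference (housekeeping) genes for
    RT-qPCR normalization from quantification-cycle (Cq) tables.
    Implements efficiency-corrected relative quantification, the four
    standard stability algorithms (geNorm M values with stepwise
    exclusion and pairwise-variation analysis, model-based NormFinder
    with intra-/intergroup variance decomposition, BestKeeper
    descriptive statistics and index correlation, and the comparative
    delta-Ct method), a comprehensive rank aggregator emulating
    raw-Cq web tools, tie-aware comparison of rankings between
    efficiency-corrected and uncorrected analyses, and a synthetic Cq
    data generator with known ground-truth stability structure.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
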