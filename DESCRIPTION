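Package: comboscreen
Title: Analysis of Pan-Cancer Drug-Combination Dose-Matrix Screens
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: End-to-end analysis of high-throughput drug-combination screens
    run as dose-concentration matrices across cancer cell line panels. Provides
    plate-level quality control (coefficient of variation, Z-factor, negative
    control ratios, replicate consistency), normalization of raw viability
    signal to a growth-inhibition scale, two-parameter logistic single-agent
    curve fitting, combination Emax extraction, Bliss-independence and
    Highest-Single-Agent synergy scoring at matrix and sliding-window level,
    an activity and cancer-type selectivity prioritization workflow,
    ANOVA-based biomarker discovery against binary multi-omics features with
    emergent combination-biomarker flagging, and a bootstrap enrichment
    statistic for pathway-pair categories. A synthetic-screen generator with
    planted ground truth supports calibration and recovery testing of the
    whole pipeline.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    tools,
    minpack.lm,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
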