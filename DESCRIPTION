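Package: rarobust
Title: Robustness Analysis of Retinoic Acid Signaling from Time-Course Expression Data
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools to quantify the robustness of retinoic acid (RA) signaling
    from treatment/control time-series expression data. Implements ternary
    discretization of dynamic expression patterns, the comparative matrix of
    pattern counts (COMPACT) for contrasting responses to increased versus
    decreased RA signaling, and a principal-curve trajectory analysis that
    summarizes each embryo clutch's deviation from control as a net absolute
    expression shift, enabling robustness ranking and efficiency-efficacy
    classification. Ships a synthetic-data generator emulating a multi-clutch
    pulse-chase design (RNA-seq plus high-throughput qPCR) with planted gene
    response classes and a clutch-level robustness trade-off, so the whole
    pipeline is testable end to end without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    limma,
    purrr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
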