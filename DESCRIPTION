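Package: ubiquant
Title: Label-Free Quantitative Differential Abundance for E3-Ligase Substrate Screens
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Peptide-level label-free quantification (LFQ) pipeline for
    identifying E3 ubiquitin-ligase substrates from mass-spectrometry
    intensity tables. Implements fraction summation of extracted ion
    chromatograms (XICs), technical-replicate merging, median-and-scale
    normalization, Tukey's-fences outlier removal, a peptide- and
    replicate-adjusted fixed-effects linear model with Benjamini-Hochberg
    false-discovery-rate control, condition-specific feature handling,
    threshold-based candidate selection, and integrative comparison of a
    proteome against diGly site-level and pan-ubiquitin protein-level
    ubiquitylomes. Ships a synthetic-data generator with known ground truth
    emulating the three screen designs, so every stage is testable against
    an oracle.
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
    nortest,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    tools,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
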