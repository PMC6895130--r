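Package: bbea
Title: Quantification and Quality Control for Bead-Based Epitope Assays
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Processing pipeline for multiplexed bead-array (Luminex xMAP)
    epitope immunoassay data: reads per-plate instrument exports, converts
    median fluorescence intensities to non-specific-binding-corrected binding
    scores on the log2 scale, applies bead-count quality control, estimates
    and removes plate (batch) effects with per-epitope linear or mixed models,
    attributes variance to experimental factors by principal variance
    component analysis (PVCA), quantifies reliability and reproducibility with
    two-way intraclass correlation coefficients, performs epitope detection
    and differential binding with empirical-Bayes moderated t-statistics, and
    implements the peptide-microarray robust z-score comparator. Includes a
    synthetic plate simulator with known ground truth so the whole pipeline is
    testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    lme4,
    ape,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    limma,
    optparse
Config/testthat/edition: 3
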