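Package: adaptscan
Title: Replicated Evolve-and-Resequence Analysis of Local Adaptation
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for detecting and classifying local adaptation in
    replicated two-environment experimental-evolution studies of outcrossing
    plants. Provides a forward-time simulator of a factorial greenhouse
    selection design (two soil types, herbivory, bee or hand pollination,
    replicated lines of 49 plants), allele-frequency-change inference via the
    Cochran-Mantel-Haenszel test with an optional drift-aware variance term,
    Benjamini-Hochberg FDR control and 2-kb window pruning, ridge-regression
    BLUP estimation of marker effects for a fitness-proxy trait, rule-based
    classification of markers into antagonistic pleiotropy and conditional
    neutrality, gene annotation within flanking windows, and linear
    mixed-model tests of genotype-by-environment local adaptation with
    local-versus-foreign and home-versus-away contrasts.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    vcfR,
    ape,
    lme4,
    car
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
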