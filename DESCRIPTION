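Package: mitoquant
Title: Quantitation of Mitophagy and Autophagy from Tandem mCherry-GFP Reporter Images
Version: 0.1.0
Authors@R: person("mitoquant", "maintainers", email = "maintainers@example.org", role = c("aut", "cre"))
Description: An end-to-end pipeline for quantifying mitophagy and
    macroautophagy from tandem mCherry-GFP fluorescence reporter
    micrographs (the mito-QC and auto-QC mouse reporters). Implements
    despeckle filtering, red/green ratio-image construction,
    double-threshold mitolysosome detection, autophagosome/autolysosome
    classification, cell-type-resolved normalization from immunolabel
    masks, object-based colocalization, mitophagic-cell classification
    via a trimmed-mean threshold, per-subject summarization with ANOVA
    and Tukey HSD group comparison, and a two-sample power calculation.
    Ships a synthetic scene generator that emulates the reporter's
    optics (PSF blur, Poisson/Gaussian noise, GFP quenching in acidic
    compartments) with per-object ground truth, so every stage is
    validated against a known oracle.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    stats,
    utils,
    tools,
    yaml,
    jsonlite
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
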