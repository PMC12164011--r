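Package: resectquant
Title: Quantitation of Roadblocked DNA End Resection from ssDNA-Specific
    Assays
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Analysis pipeline for experiments that attenuate DNA
    double-strand-break end resection with programmable protein roadblocks
    (catalytically dead Cas9) in budding yeast. Implements the
    ssDNA-specific qPCR resection-efficiency estimator with corrections
    for digestion efficiency and break-formation frequency, the two-stage
    normalization and blocking-efficiency statistic, Southern restriction
    fragment-size prediction, quantification of per-cell RPA-fluorescence
    intensity from z-stacks with a population relative-intensity
    statistic, canavanine-resistance mutation-frequency and
    mutation-spectrum analysis of bisulfite-mutagenized reporters, and a
    seeded forward stochastic simulator of roadblocked resection that
    generates every input the analysis functions consume.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    EBImage
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
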