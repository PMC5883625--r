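Package: pmaflux
Title: Constraint-Based Route Scanning and Metabolome Statistics for
    Polymalic Acid Fermentation
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools for analysing polymalic acid (PMA) production by
    Aureobasidium pullulans. Implements flux balance analysis over a
    packaged reduced central-carbon model, a robustness scan of the three
    malate synthesis routes (oxidative TCA, reductive TCA, glyoxylate
    shunt) under imposed route flux and growth, a GC-MS metabolome
    differential-analysis pipeline (internal-standard normalisation,
    unit-variance scaling, PCA, PLS-DA with VIP scores, pooled t tests
    with Benjamini-Hochberg FDR, Ward clustering), fermentation
    quantitation arithmetic (titer, yield, productivity, PMA/malic acid
    hydrolysis conversion, qPCR relative expression), and seeded
    synthetic-data generators for every pipeline stage.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    jsonlite,
    stats,
    utils
Suggests:
    mixOmics,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
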