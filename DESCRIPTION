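Package: cftannin
Title: Tannin Annotation, Molecular Networking and Spectrum-Effect
    Chemometrics for Chebulae Fructus
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: An integrative toolkit for profiling the phenolcarboxylic and
    hydrolyzable-tannin constituents of Chebulae Fructus (the dried ripe fruit
    of Terminalia chebula) from negative-mode LC-MS/MS data. Provides exact
    monoisotopic mass and adduct m/z arithmetic, a packaged in-house compound
    library with precursor and fragment search, classic molecular networking
    by modified-cosine spectral similarity, diagnostic-fragment classification
    of gallotannins, ellagitannins and chebulic ellagitannins, collision
    cross-section comparison for isomer discrimination, chromatographic
    fingerprint chemometrics (similarity, HCA, PCA, OPLS-DA with VIP marker
    selection), and spectrum-antioxidant correlation by Pearson analysis, grey
    relational analysis and DPPH peak-area-decrease scoring. Seeded synthetic
    generators emulate the multi-batch study design so every stage is testable
    without instrument data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    igraph,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
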