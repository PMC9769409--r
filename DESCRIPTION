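Package: pgpscreen
Title: Screening Analytics for Plant-Growth-Promoting and Antagonistic Microbial Isolates
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for analysing culturable-isolate screening campaigns of
    plant-growth-promoting (PGP) and biocontrol microbes. Reads and validates
    per-isolate trait tables (IAA, phosphate solubilization, ammonia,
    siderophore, plus binary enzyme/fixation traits with explicit not-detected
    semantics) and isolate-by-pathogen dual-culture inhibition matrices;
    implements the assay arithmetic (standard-curve calibration, percent
    mycelial inhibition, CAS siderophore percentage, seed germination rate,
    DMSO-extraction chlorophyll a/b equations); scores isolates on an additive
    41-point bonitur scale with dense ranking and an audit against published
    score tables; summarises campaigns (trait prevalence, antagonism spectrum,
    composition, value extremes); and analyses pot trials (mean +/- SE,
    log2 fold change, one-way ANOVA, correlation-matrix PCA). Seeded synthetic
    generators emulate whole campaigns and trials for testing.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
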