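Package: sproutval
Title: Marker Validation for Pre-Harvest Sprouting Resistance in Wheat
Version: 0.99.0
Authors@R:
    person("Package", "Author", email = "author@example.com",
           role = c("aut", "cre"))
Description: Tools for validating KASP markers for pre-harvest sprouting
    (PHS) resistance in multi-environment wheat trials. Computes the
    germination index from staged germination counts, fits within- and
    across-environment random-effects models by REML to obtain BLUPs,
    variance components and broad-sense heritability, screens genotyping
    assays (missing rate, heterozygosity, monomorphy, minor allele
    frequency, strand harmonization, complete-LD detection), estimates
    per-marker allelic effects on the germination index by single-marker
    regression with a cross-environment stability criterion, ranks all
    marker subsets by AIC, compares multi-locus haplotype classes with a
    mixed model and Tukey-Kramer grouping, and evaluates the selection
    efficiency of haplotypes against the best single marker. A synthetic
    trial generator with known ground truth makes the whole pipeline
    runnable and testable without external data.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    S4Vectors,
    SummarizedExperiment,
    lme4,
    emmeans,
    yaml
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
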