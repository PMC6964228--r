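Package: radsexing
Title: Sex-Linked Marker Discovery from RAD-Seq Presence/Absence and
    Molecular Sexing Statistics
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for discovering Y- (or W-) hemizygous markers from
    reduced-representation sequencing (ddRAD) presence/absence data via
    privacy rarefaction, a bootstrap subsampling procedure that separates
    genuinely sex-exclusive loci from missing-data artefacts. Includes
    cross-assembly consensus and ranking of candidate marker contigs,
    PCR sexing-assay call logic with positive-control handling and
    known-sex validation, exact two-sided binomial sex-ratio tests with
    median-split covariate analyses, the Loiselle pairwise kinship
    estimator for multi-allelic codominant genotypes, and a seeded
    synthetic-data generator that emulates dioecious cohorts with
    planted sex-linked loci for end-to-end validation.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    Biostrings
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
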