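Package: rdcnv
Title: Depth-of-Coverage CNV Calling, Filtering and Prioritisation for
    Heterogeneous Exome Cohorts
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for re-analysing heterogeneous exome sequencing cohorts for
    copy number variants (CNVs) from depth of coverage. Provides a synthetic
    cohort simulator with known ground truth (multiple enrichment kits,
    GC-dependent capture bias, negative-binomial count noise, spiked CNVs and
    trios), per-kit coverage preprocessing (GC-extreme target removal, sample
    coverage QC, windowing, GC and library-size correction, variance
    stabilisation), three depth-of-coverage callers (a copy-number
    log-likelihood maximum-subarray segmenter with coverage-profile
    clustering, an SVD/RPKM z-score caller with iterative batch QC, and a
    reference-matched beta-binomial caller with Bayes-factor scoring), and
    cohort-level triage: frequency filtering, gene-panel restriction,
    six-class categorisation, compound-heterozygous SNV/CNV double-hit
    matching, European Reference Network prioritisation rules, HGVS-style
    nomenclature and summary tables.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    MASS,
    IRanges,
    S4Vectors
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
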