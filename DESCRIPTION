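Package: epistab
Title: Epigenetic Instability Indices for DNA Methylation Arrays
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Analysis of DNA methylation dynamics at stem-cell loci on
    Infinium 27k-style beta-value arrays: derivation of locus sets methylated
    in embryonic stem cells (MESC) from strand-resolved bisulfite read
    counts, Polycomb-target (PCGT) and partially methylated domain (PMD)
    annotation, beta-value computation and quality control, covariate-
    adjusted per-CpG differential methylation with binomial skewness tests,
    baseline-matched Fisher enrichment, methylation-state discretization and
    the four transition-specific Epigenetic Instability Indices including
    the prognostic Demethylation Instability Index (DeMI), survival and ROC
    outcome analysis, TET anti-correlation enrichment, and a synthetic-data
    generator that emulates staged carcinogenesis cohorts for end-to-end
    testing.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    graphics,
    tools,
    survival,
    pROC,
    GenomicRanges,
    IRanges,
    yaml,
    jsonlite
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
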