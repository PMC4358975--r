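Package: clonechron
Title: Tumor Subclonality and Molecular Timing of Somatic Events from
    Deep Whole-Genome Sequencing
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Infers tumor purity, subclonal architecture and the molecular
    timing of chromosome-scale copy-number events from somatic variant
    allele fractions (VAF), germline heterozygous-site allele fractions and
    copy-number segments of a single deeply sequenced tumor biopsy.
    Provides normal-cell contamination estimation and correction of VAF and
    allelic copy number, lesser-allele-fraction estimation, integer
    allelic-state assignment with subclonal copy-number deconvolution,
    binomial-mixture VAF clustering with BIC model selection, mutation
    multiplicity assignment, closed-form molecular-time estimators for
    copy-neutral LOH, trisomy and whole-genome duplication, clone-tree
    assembly, and a fully seeded synthetic tumor-genome generator for
    validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    vcfR,
    ape,
    optparse
Config/testthat/edition: 3
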