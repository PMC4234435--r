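Package: cnvrforge
Title: Copy Number Variant Region Discovery, Consensus and Genotyping for
    SNP Genotyping Arrays
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: A reusable pipeline for genome-wide copy number variant (CNV)
    discovery from SNP genotyping array intensity data (Log R ratio and
    B allele frequency), aimed at multi-breed dog cohorts genotyped on
    arrays such as the CanineHD. Provides GC-wave correction and sample
    quality control, a five-state hidden Markov model segmentation engine
    run under two parameter profiles with Log Bayes factor scoring,
    dual-profile CNV-region (CNVR) consensus with a minimum-overlap rule,
    population genotyping of CNVRs with singleton removal and
    deletion/duplication classification, breed-frequency and gene/ortholog
    annotation including dosage-sensitive gene intersection, and
    delta-delta-Ct relative-quantification arithmetic for qPCR validation.
    A synthetic cohort generator with planted ground-truth CNVs makes the
    entire pipeline testable without array data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    GenomeInfoDb,
    GenomicRanges,
    IRanges,
    S4Vectors,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse
Config/testthat/edition: 3
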