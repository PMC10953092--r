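Package: dmmrkit
Title: Molecular Characterization of Mismatch-Repair-Deficient Colorectal Tumors
Version: 0.1.0
Authors@R: person("Package", "Maintainer", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Reusable implementations of the assays used to characterize
    sporadic mismatch-repair-deficient colorectal cancer in rhesus macaques:
    microsatellite-instability calling from paired electropherogram traces with
    MSS/MSI-low/MSI-high classification, MethyLight-style percent-methylation
    quantification from bisulfite qPCR plates with CpG-island-methylator-
    phenotype (CIMP) classification, tumor mutational burden, SBS96
    trinucleotide mutational spectra with cosine signature matching,
    cross-species hotspot codon mapping, methylation-aware DNA-shape profiling
    with percentile-envelope departure scoring, clinical cohort summaries with
    Spearman correlation, and seeded synthetic-data generators so the whole
    pipeline is testable without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    BiocGenerics,
    Biostrings,
    GenomeInfoDb,
    SummarizedExperiment,
    VariantAnnotation,
    jsonlite,
    methods,
    stats,
    tools,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
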