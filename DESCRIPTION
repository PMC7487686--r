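Package: aneudose
Title: Dosage-Compensation and Proteostasis Analysis for Aneuploid Yeast
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
                  role = c("aut", "cre"))
Description: An analysis pipeline for haploid aneuploid yeast strains:
    chromosome copy-number estimation from qPCR arm probes and from 1-kb
    windowed sequencing depth, RPKM quantification of mRNA-seq and ribosome
    footprint libraries with median-ratio normalization anchored on
    nonduplicated chromosomes, per-chromosome dosage-compensation summaries,
    stress-response gene-set signature scoring, hypergeometric enrichment
    with Bonferroni correction, cross-strain intersection of upregulated
    genes, variant-frequency filtering with coding-effect classification,
    and small-formula calculators for reporter and pulse-chase assays.
    A synthetic-data module generates every input with known ground truth
    so the whole pipeline is testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    tools,
    tibble,
    dplyr,
    withr,
    jsonlite,
    yaml,
    fgsea,
    Biostrings,
    GenomicRanges,
    IRanges,
    rtracklayer
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
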