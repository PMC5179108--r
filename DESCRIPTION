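Package: irdx
Title: Exome-Based Molecular Diagnosis of Inherited Retinal Dystrophies
Version: 0.99.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: A reusable, tested implementation of a whole-exome-sequencing
    diagnostic workflow for inherited retinal dystrophies (IRD): rare-variant
    prioritization (allele-frequency, consequence and consensus in-silico
    prediction filters), inheritance-model genotype selection with
    cosegregation checks, ACMG/AMP-style evidence derivation and class
    combination (including a VGUS class for disruptive alleles in genes of
    uncertain disease relevance), exon read-depth and MLPA copy-number
    evidence, trio-SNP hemizygosity-based deletion inference, and
    cohort-level diagnostic-yield and carrier-burden summaries. Ships a
    machine-readable encoding of a published 33-family IRD cohort and a
    synthetic-cohort simulator with known ground truth for end-to-end
    validation.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    S4Vectors,
    GenomicRanges,
    SummarizedExperiment,
    VariantAnnotation,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
biocViews: VariantAnnotation, GeneticVariability, SNP, CopyNumberVariation
RoxygenNote: 7.3.3
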